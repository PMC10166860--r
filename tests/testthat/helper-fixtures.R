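# Shared fixtures, memoized so expensive sessions are built once per run.

.fixtureEnv <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureEnv)) {
    assign(key, force(expr), envir = .fixtureEnv)
  }
  get(key, envir = .fixtureEnv)
}

# a default-condition synthetic session
refSession <- function(seed = 1) {
  memo(paste0("session", seed), simulateSession(sessionParams(seed = seed)))
}

# full pipeline results on a default session
refAnalysis <- function(seed = 1) {
  memo(paste0("analysis", seed),
       suppressWarnings(runPipeline(refSession(seed))))
}

# noiseless, kernel-free session (decoder round-trip conditions)
refCleanSession <- function(seed = 2) {
  memo(paste0("clean", seed),
       simulateSession(sessionParams(seed = seed, noiseSd = 0,
                                     calciumTauS = 1e-9,
                                     bleachFraction = 0)))
}

# phase decoded from the rendered signal against the ground-truth embedding
decodeTrue <- function(session) {
  e <- trueEmbedding(session)
  computePhase(sessionSignal(session)[roiIds(e), ], e)
}

# simple preprocessed trace matrix from a plain matrix
zTraces <- function(values, rate = 5, roi = NULL) {
  RoiTraces(values, rate = rate, roi = roi, preprocessed = TRUE)
}
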