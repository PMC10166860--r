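#' @include AllClasses.R rpcspace.R
NULL

# ring-quality score: 1 - coefficient of variation of the radii of the
# 2-D neuron-embedding projection
.ringQuality <- function(traces, ids) {
  if (length(ids) < 3) return(NA_real_)
  emb <- tryCatch(pcaNeuronEmbedding(traces[ids, ]), error = function(e) NULL)
  if (is.null(emb)) return(NA_real_)
  co <- sweep(emb$coords, 2, colMeans(emb$coords))
  radii <- sqrt(rowSums(co^2))
  1 - stats::sd(radii) / mean(radii)
}

#' Select ring candidates by anticorrelation
#'
#' Keeps every ROI whose minimum Pearson correlation with any other ROI is
#' at or below `threshold`; ring neurons have an anticorrelated partner at a
#' pi angle, so strongly negative pairwise correlations single them out.
#' With `scan = TRUE` the threshold is chosen from a grid over
#' [-0.75, -0.5] by maximizing the ring-quality score (1 - CV of the
#' PC-projection radii).
#'
#' @param traces a preprocessed [RoiTraces-class] (>= 8 ROIs).
#' @param threshold correlation threshold, conventionally in [-0.75, -0.5].
#' @param scan logical: scan the threshold grid instead of using `threshold`.
#' @param scanGrid thresholds tried when `scan = TRUE`.
#' @return a provisional [RingSelection-class].
#' @export
selectAnticorrelated <- function(traces, threshold = -0.6, scan = FALSE,
                                 scanGrid = seq(-0.75, -0.5, by = 0.05)) {
  if (nrow(traces) < 8) stop("need at least 8 ROIs")
  C <- stats::cor(t(traceValues(traces)))
  diag(C) <- NA
  minCor <- apply(C, 1, min, na.rm = TRUE)
  pick <- function(thr) rownames(C)[minCor <= thr]
  if (scan) {
    quals <- vapply(scanGrid, function(thr) .ringQuality(traces, pick(thr)),
                    numeric(1))
    if (all(is.na(quals))) {
      warning("no threshold in the scan grid yields a usable selection")
      threshold <- scanGrid[1]
    } else {
      threshold <- scanGrid[which.max(quals)]
    }
  }
  ids <- pick(threshold)
  if (length(ids) == 0) {
    warning(sprintf("no ROI pair is anticorrelated at threshold %.2f", threshold))
  }
  methods::new("RingSelection", selectedIds = ids, thresholdUsed = threshold,
               quality = .ringQuality(traces, ids),
               excludedIds = character(), exclusionReason = character())
}

#' Exclude ROIs that disrupt the sorted correlation matrix
#'
#' Automated surrogate for curation on the angle-sorted correlation matrix:
#' ROIs are sorted by their ring angle and an ROI is excluded when the
#' Pearson correlation between its row of the sorted correlation matrix and
#' the ideal ring template cos(alpha_i - alpha_j) falls below
#' `templateMinCorr`. Set `templateMinCorr = -1` to disable.
#'
#' @param traces a preprocessed [RoiTraces-class].
#' @param provisional a [RingSelection-class] from [selectAnticorrelated()].
#' @param alphaOrder named numeric: ring angle per selected ROI id.
#' @param templateMinCorr minimum template correlation to keep an ROI.
#' @return the refined [RingSelection-class], with exclusion reasons.
#' @export
excludeBySortedMatrix <- function(traces, provisional, alphaOrder,
                                  templateMinCorr = 0.5) {
  ids <- provisional@selectedIds
  if (length(ids) == 0) stop("provisional selection is empty")
  alpha <- alphaOrder[ids]
  ord <- order(alpha)
  ids <- ids[ord]
  alpha <- alpha[ord]
  C <- stats::cor(t(traceValues(traces[ids, ])))
  Tm <- cos(outer(alpha, alpha, "-"))
  n <- length(ids)
  rowCor <- vapply(seq_len(n), function(i) {
    stats::cor(C[i, -i], Tm[i, -i])
  }, numeric(1))
  drop <- which(rowCor < templateMinCorr)
  keepIds <- ids[setdiff(seq_len(n), drop)]
  exIds <- c(provisional@excludedIds, ids[drop])
  reasons <- c(provisional@exclusionReason,
               stats::setNames(sprintf("template correlation %.3f < %.2f",
                                       rowCor[drop], templateMinCorr),
                               ids[drop]))
  methods::new("RingSelection", selectedIds = keepIds,
               thresholdUsed = provisional@thresholdUsed,
               quality = .ringQuality(traces, keepIds),
               excludedIds = exIds, exclusionReason = reasons)
}
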