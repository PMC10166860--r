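#' @include AllClasses.R
NULL

.SWC_TYPES <- c("1" = "soma", "2" = "axon", "3" = "dendrite")

#' Construct a Skeleton from a node table
#'
#' Validates the tree: exactly one root (parent = -1), all parent references
#' valid, no cycles, fully connected.
#'
#' @param nodes data.frame with id, parent, x, y, z, radius and either a
#'   `compartment` column or an SWC `type` code column.
#' @param midlineX coronal midline coordinate, micrometres.
#' @param neuronId identifier.
#' @return a [Skeleton-class].
#' @export
Skeleton <- function(nodes, midlineX = 0, neuronId = "neuron") {
  if (!"compartment" %in% names(nodes)) {
    comp <- .SWC_TYPES[as.character(nodes$type)]
    comp[is.na(comp)] <- "unlabeled"
    nodes$compartment <- unname(comp)
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) == 0) stop("skeleton has no root (parent = -1)")
  if (length(roots) > 1) stop("skeleton has multiple roots")
  dangling <- setdiff(nodes$parent, c(-1, nodes$id))
  if (length(dangling)) {
    stop("dangling parent reference(s): ", paste(dangling, collapse = ", "))
  }
  # connectivity / cycle check by traversal from the root
  children <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  visited <- character()
  stack <- as.character(nodes$id[roots])
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur %in% visited) stop("cycle detected in skeleton")
    visited <- c(visited, cur)
    kids <- children[[cur]]
    if (!is.null(kids)) stack <- c(stack, as.character(kids))
  }
  if (length(visited) != nrow(nodes)) {
    stop("skeleton is not a connected tree (cycle or detached subtree)")
  }
  if (any(nodes$compartment == "unlabeled")) {
    message(sprintf("skeleton '%s': %d unlabeled node(s)", neuronId,
                    sum(nodes$compartment == "unlabeled")))
  }
  methods::new("Skeleton",
               nodes = nodes[, c("id", "parent", "x", "y", "z", "radius",
                                 "compartment")],
               midlineX = midlineX, neuronId = neuronId)
}

#' Read an SWC skeleton file
#'
#' Plain SWC (id type x y z radius parent, '#' comments), with compartment
#' labels taken from the SWC type codes (1 = soma, 2 = axon, 3 = dendrite)
#' or overridden by a sidecar table.
#'
#' @param path SWC file.
#' @param labels optional data.frame (id, compartment) overriding the codes.
#' @param midlineX coronal midline coordinate of the frame, micrometres.
#' @param neuronId identifier; default the file name.
#' @return a [Skeleton-class].
#' @export
readSwc <- function(path, labels = NULL, midlineX = 0,
                    neuronId = sub("\\.swc$", "", basename(path))) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (!is.null(labels)) {
    comp <- rep("unlabeled", nrow(tab))
    m <- match(tab$id, labels$id)
    comp[!is.na(m)] <- labels$compartment[m[!is.na(m)]]
    tab$compartment <- comp
  }
  Skeleton(tab, midlineX = midlineX, neuronId = neuronId)
}

#' Write a Skeleton to an SWC file
#'
#' @param skel a [Skeleton-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSwc <- function(skel, path) {
  codes <- c(soma = 1, axon = 2, dendrite = 3, unlabeled = 0)
  n <- skel@nodes
  tab <- data.frame(id = n$id, type = codes[n$compartment], x = n$x, y = n$y,
                    z = n$z, radius = n$radius, parent = n$parent)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# node ids with out-degree >= 2
.branchPoints <- function(skel) {
  tab <- table(skel@nodes$parent[skel@nodes$parent != -1])
  as.numeric(names(tab)[tab >= 2])
}

#' Compartment centroids and midline distances
#'
#' Branch points are nodes with at least two children; the centroid of a
#' compartment is the unweighted mean coordinate of its branch points, and
#' the midline distance is |x_centroid - midlineX|. If a compartment has no
#' branch point its centroid is NA (or, with `fallbackAllNodes = TRUE`, the
#' mean over all of its nodes).
#'
#' @param skel a [Skeleton-class].
#' @param fallbackAllNodes use all compartment nodes when no branch point
#'   exists.
#' @return one-row data.frame: neuron_id, dendrite/axon centroids (x, y, z),
#'   dendrite_midline_dist, axon_midline_dist, soma_ap.
#' @export
compartmentCentroids <- function(skel, fallbackAllNodes = FALSE) {
  nd <- skel@nodes
  bp <- .branchPoints(skel)
  one <- function(comp) {
    sel <- nd$id %in% bp & nd$compartment == comp
    if (!any(sel)) {
      if (!fallbackAllNodes) return(c(NA_real_, NA_real_, NA_real_))
      sel <- nd$compartment == comp
      if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
    }
    colMeans(nd[sel, c("x", "y", "z")])
  }
  dc <- one("dendrite")
  ac <- one("axon")
  somaY <- nd$y[nd$compartment == "soma"][1]
  data.frame(neuron_id = skel@neuronId,
             dendrite_x = dc[1], dendrite_y = dc[2], dendrite_z = dc[3],
             axon_x = ac[1], axon_y = ac[2], axon_z = ac[3],
             dendrite_midline_dist = abs(dc[1] - skel@midlineX),
             axon_midline_dist = abs(ac[1] - skel@midlineX),
             soma_ap = if (length(somaY)) somaY else NA_real_,
             row.names = NULL)
}

#' Morphometry correlations across neurons
#'
#' Pearson correlations of (a) dendrite vs axon midline distance and
#' (b) soma anteroposterior position vs dendrite midline distance.
#'
#' @param rows data.frame of [compartmentCentroids()] rows (>= 3).
#' @return list with r_dendrite_axon, r_soma_dendrite, n.
#' @export
morphometryCorrelations <- function(rows) {
  rows <- rows[stats::complete.cases(rows[, c("dendrite_midline_dist",
                                              "axon_midline_dist",
                                              "soma_ap")]), ]
  if (nrow(rows) < 3) stop("need at least 3 complete neurons")
  for (col in c("dendrite_midline_dist", "axon_midline_dist", "soma_ap")) {
    if (stats::var(rows[[col]]) == 0) stop("zero-variance column: ", col)
  }
  list(r_dendrite_axon = stats::cor(rows$dendrite_midline_dist,
                                    rows$axon_midline_dist),
       r_soma_dendrite = stats::cor(rows$soma_ap, rows$dendrite_midline_dist),
       n = nrow(rows))
}

#' Pairwise branch-point offset histogram
#'
#' For every branch point of every neuron, the signed offsets of all other
#' branch points (axons and dendrites pooled) along the frontal (x) and
#' sagittal (y) axes, binned into a 2-D count histogram.
#'
#' @param skels list of [Skeleton-class] objects.
#' @param binUm bin pitch, micrometres.
#' @return list with `counts` matrix, `frontal` and `sagittal` bin centers,
#'   and `nPoints`.
#' @export
branchpointDistanceProfile <- function(skels, binUm = 3.5) {
  if (methods::is(skels, "Skeleton")) skels <- list(skels)
  pts <- do.call(rbind, lapply(skels, function(s) {
    nd <- s@nodes
    nd[nd$id %in% .branchPoints(s), c("x", "y")]
  }))
  if (nrow(pts) < 2) stop("need at least 2 branch points")
  dx <- as.numeric(outer(pts$x, pts$x, "-"))
  dy <- as.numeric(outer(pts$y, pts$y, "-"))
  self <- as.logical(diag(nrow(pts)))
  dx <- dx[!self]
  dy <- dy[!self]
  bx <- .offsetBins(dx, binUm)
  by <- .offsetBins(dy, binUm)
  counts <- table(factor(bx$idx, levels = seq_along(bx$centers)),
                  factor(by$idx, levels = seq_along(by$centers)))
  list(counts = unclass(counts), frontal = bx$centers, sagittal = by$centers,
       nPoints = nrow(pts))
}

# symmetric signed-offset binning: bin k covers (centers[k] +- binUm/2)
.offsetBins <- function(d, binUm) {
  idxRel <- round(d / binUm)
  lo <- min(idxRel); hi <- max(idxRel)
  list(idx = idxRel - lo + 1, centers = seq(lo, hi) * binUm)
}

#' Two-dimensional spatial autocorrelation of pixel-bin activity
#'
#' Divides the masked region into square bins (default 3.5 um pitch),
#' averages the pixel traces per bin, z-scores each bin trace, computes the
#' Pearson correlation between every focal bin and all bins, and averages
#' the correlations sorted by the signed per-axis bin offsets.
#'
#' @param values pixels x frames matrix of fluorescence traces.
#' @param x,y pixel coordinates in micrometres (frontal, sagittal axes).
#' @param mask logical per pixel; FALSE pixels are ignored.
#' @param binUm bin pitch, micrometres.
#' @return list with `offsets` (data.frame dx, dy, mean_correlation,
#'   n_pairs), `map` (matrix over offset grid), `frontal`, `sagittal`
#'   (offset centers), `nBins`, `droppedBins`.
#' @export
dipnAutocorrelation <- function(values, x, y, mask = rep(TRUE, length(x)),
                                binUm = 3.5) {
  stopifnot(nrow(values) == length(x), length(x) == length(y))
  if (!any(mask)) stop("mask is empty")
  values <- values[mask, , drop = FALSE]
  bx <- floor(x[mask] / binUm)
  by <- floor(y[mask] / binUm)
  key <- paste(bx, by)
  ub <- !duplicated(key)
  binX <- bx[ub]; binY <- by[ub]
  lev <- key[ub]
  agg <- rowsum(values, group = factor(key, levels = lev), reorder = FALSE) /
    as.numeric(table(factor(key, levels = lev)))
  sds <- apply(agg, 1, stats::sd)
  dropped <- sum(sds == 0)
  keep <- sds > 0
  agg <- agg[keep, , drop = FALSE]
  binX <- binX[keep]; binY <- binY[keep]
  z <- (agg - rowMeans(agg)) / apply(agg, 1, stats::sd)
  C <- stats::cor(t(z))
  n <- nrow(z)
  dx <- as.numeric(outer(binX, binX, function(a, b) b - a)) * binUm
  dy <- as.numeric(outer(binY, binY, function(a, b) b - a)) * binUm
  cc <- as.numeric(C)
  off <- stats::aggregate(cc, by = list(dx = dx, dy = dy),
                          FUN = function(v) c(mean(v), length(v)))
  res <- data.frame(dx = off$dx, dy = off$dy,
                    mean_correlation = off$x[, 1], n_pairs = off$x[, 2])
  fx <- sort(unique(res$dx))
  fy <- sort(unique(res$dy))
  map <- matrix(NA_real_, length(fx), length(fy), dimnames = list(fx, fy))
  map[cbind(match(res$dx, fx), match(res$dy, fy))] <- res$mean_correlation
  list(offsets = res, map = map, frontal = fx, sagittal = fy,
       nBins = n, droppedBins = dropped)
}

# ---------------------------------------------------------------------------
# synthetic structural generators (labelled synthetic: no EM data ships with
# the package; these emulate the mirrored aHB -> dIPN projection geometry)
# ---------------------------------------------------------------------------

#' Generate a synthetic mirrored-projection skeleton population
#'
#' Builds simple skeletons that emulate the reciprocal aHB projection into
#' the dorsal interpeduncular neuropil: a neuron whose dendrite arborizes at
#' lateral offset d from the midline extends its axon to the contralateral
#' side at the complementary offset (lateral dendrite, medial axon and vice
#' versa), so the two midline-distance columns are exactly anticorrelated;
#' the soma anteroposterior position is linear in the dendrite offset.
#'
#' @param n neurons.
#' @param spreadUm range of dendrite midline offsets, micrometres.
#' @param jitterUm positional jitter of individual branch points (0 gives
#'   exactly complementary centroids).
#' @param branchesPerCompartment branch points per compartment.
#' @param somaSlope micrometres of soma AP shift per micrometre of dendrite
#'   offset.
#' @return list of [Skeleton-class] objects.
#' @export
makeMirroredSkeletons <- function(n = 19, spreadUm = c(4, 20), jitterUm = 0,
                                  branchesPerCompartment = 3,
                                  somaSlope = 2) {
  xs <- seq(spreadUm[1], spreadUm[2], length.out = n) *
    rep_len(c(1, -1), n)   # alternate sides
  lapply(seq_len(n), function(i) {
    xd <- xs[i]
    # contralateral axon at the complementary lateral offset
    xa <- -sign(xd) * (spreadUm[1] + spreadUm[2] - abs(xd))
    somaY <- 40 + somaSlope * abs(xd)
    b <- branchesPerCompartment
    mkBranch <- function(x0, y0, z0, idBase, parent, comp) {
      # a chain of `b` nodes, each with >= 2 children => b branch points
      df <- NULL
      for (k in seq_len(b)) {
        pid <- idBase + (k - 1) * 3 + 1
        xk <- x0 + if (jitterUm > 0) stats::rnorm(1, 0, jitterUm) else 0
        yk <- y0 + (k - 1) * 2
        df <- rbind(df,
          data.frame(id = pid, parent = parent, x = xk, y = yk, z = z0,
                     radius = 0.3, compartment = comp),
          data.frame(id = pid + 1, parent = pid, x = xk + 1, y = yk + 1,
                     z = z0, radius = 0.2, compartment = comp),
          data.frame(id = pid + 2, parent = pid, x = xk - 1, y = yk + 1,
                     z = z0, radius = 0.2, compartment = comp))
        parent <- pid
      }
      df
    }
    soma <- data.frame(id = 1, parent = -1, x = 0, y = somaY, z = 0,
                       radius = 2, compartment = "soma")
    dend <- mkBranch(xd, 0, -5, 1, 1, "dendrite")
    axon <- mkBranch(xa, 0, -5, 100, 1, "axon")
    Skeleton(rbind(soma, dend, axon), midlineX = 0,
             neuronId = sprintf("syn%02d", i))
  })
}

#' Generate synthetic neuropil frames with a mirrored traveling bump
#'
#' A Gaussian bump of activity random-walks along the frontal axis of a
#' pixel plane and a mirrored copy follows at a fixed lateral offset D,
#' emulating paired dendrite/axon signals; used to validate side-lobe
#' detection in the spatial autocorrelation.
#'
#' @param offsetUm mirror offset D, micrometres.
#' @param widthUm Gaussian bump sd, micrometres.
#' @param extentUm frontal extent of the plane.
#' @param sagittalUm sagittal extent.
#' @param pixelUm pixel pitch.
#' @param nFrames frames.
#' @param noiseSd additive noise.
#' @return list with `values` (pixels x frames), `x`, `y` coordinates.
#' @export
makeMirroredBumpFrames <- function(offsetUm = 14, widthUm = 3, extentUm = 56,
                                   sagittalUm = 14, pixelUm = 1.75,
                                   nFrames = 400, noiseSd = 0.02) {
  gx <- seq(0, extentUm - pixelUm, by = pixelUm)
  gy <- seq(0, sagittalUm - pixelUm, by = pixelUm)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  centers <- cumsum(stats::rnorm(nFrames, 0, 3)) %% (extentUm - offsetUm)
  values <- matrix(0, length(px), nFrames)
  for (t in seq_len(nFrames)) {
    c0 <- centers[t]
    values[, t] <- exp(-(px - c0)^2 / (2 * widthUm^2)) +
      exp(-(px - c0 - offsetUm)^2 / (2 * widthUm^2))
  }
  if (noiseSd > 0) {
    values <- values + matrix(stats::rnorm(length(values), 0, noiseSd),
                              nrow(values))
  }
  list(values = values, x = px, y = py)
}
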