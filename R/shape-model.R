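## Statistical shape model. The default estimator is projection-pursuit PCA
## in the Croux & Ruiz-Gazen style: candidate directions are the normalised
## centred observations (optionally augmented with pairwise differences);
## each component maximises a scale index (variance, MAD, or Qn) of the
## projected data over the candidates; the data are then deflated to the
## orthogonal complement and the search repeats. Classical PCA (exact
## eigen-decomposition) is available as a second method and serves as the
## independent cross-check. Components are capped at n - 1.

#' Construct a CorrespondedPopulation
#'
#' @param shapes n x 3m matrix of flattened shape-vectors
#'   (x1, y1, z1, ...), in mm.
#' @param ids per-shape identifiers (default shape_0001, ...).
#' @param templatePoints optional m x 3 template coordinates.
#' @param templateFaces optional 0-based faces.
#' @param labels optional per-point region tags.
#' @return a \linkS4class{CorrespondedPopulation}.
#' @export
correspondedPopulation <- function(shapes, ids = NULL,
                                   templatePoints = matrix(numeric(0), 0L, 3L),
                                   templateFaces = matrix(integer(0), 0L, 3L),
                                   labels = character(0)) {
  if (is.null(ids)) ids <- sprintf("shape_%04d", seq_len(nrow(shapes)))
  dimnames(shapes) <- NULL
  new("CorrespondedPopulation", shapes = shapes, ids = as.character(ids),
      templatePoints = templatePoints,
      templateFaces = matrix(as.integer(templateFaces), ncol = 3L),
      labels = as.character(labels))
}

.scaleIndex <- function(x, index) {
  switch(index,
         variance = stats::sd(x),
         mad = stats::mad(x),
         qn = .qnScale(x),
         stop("unknown projection index '", index, "'"))
}

## Croux--Ruiz-Gazen projection pursuit: returns list(directions, scales)
.ppPursuit <- function(Xc, K, index, pairwiseCandidates = FALSE) {
  n <- nrow(Xc); p <- ncol(Xc)
  Z <- Xc
  dirs <- matrix(0, p, 0L)
  scales <- numeric(0)
  for (k in seq_len(K)) {
    C <- Z
    if (pairwiseCandidates && n <= 200L) {
      idx <- utils::combn(n, 2L)
      C <- rbind(C, Z[idx[1L, ], , drop = FALSE] -
                    Z[idx[2L, ], , drop = FALSE])
    }
    nrm <- sqrt(rowSums(C * C))
    keep <- nrm > 1e-12
    if (!any(keep)) break
    C <- C[keep, , drop = FALSE] / nrm[keep]
    proj <- Xc %*% t(C)                     # n x candidates
    sc <- apply(proj, 2L, .scaleIndex, index = index)
    j <- which.max(sc)                      # first max: deterministic
    if (!is.finite(sc[j]) || sc[j] <= 1e-12) break
    a <- C[j, ]
    dirs <- cbind(dirs, a)
    scales <- c(scales, sc[j])
    Z <- Z - (Z %*% a) %*% t(a)             # deflate to orthogonal complement
  }
  dimnames(dirs) <- NULL
  list(directions = dirs, scales = scales)
}

#' Build a statistical shape model from a corresponded population
#'
#' @param pop a \linkS4class{CorrespondedPopulation} (n >= 2).
#' @param method \code{"pp_pca"} (projection-pursuit, default) or
#'   \code{"classical_pca"} (exact eigen-decomposition).
#' @param index projection index for ppPCA: \code{"variance"} (sample SD),
#'   \code{"mad"}, or \code{"qn"}. With a robust index the per-mode
#'   \code{sd} is that robust scale and variance fractions use its square.
#' @param K number of components; capped at n - 1 with a warning, default
#'   n - 1.
#' @param center \code{"mean"} (columnwise mean, default) or
#'   \code{"median"} (columnwise median, for the robust indices).
#' @param pairwiseCandidates augment the ppPCA candidate set with pairwise
#'   observation differences (O(n^2); only applied for n <= 200).
#' @return a \linkS4class{ShapeModel}. Components are sorted by
#'   non-increasing scale; a zero-variance population yields a degenerate
#'   model with all sd = 0.
#' @examples
#' set.seed(1)
#' shapes <- matrix(rnorm(20 * 30), 20, 30)
#' pop <- correspondedPopulation(shapes)
#' model <- buildShapeModel(pop, method = "classical_pca")
#' sum(model@varianceFractions)  # 1
#' @export
buildShapeModel <- function(pop, method = c("pp_pca", "classical_pca"),
                            index = c("variance", "mad", "qn"), K = NULL,
                            center = c("mean", "median"),
                            pairwiseCandidates = FALSE) {
  method <- match.arg(method)
  index <- match.arg(index)
  center <- match.arg(center)
  X <- pop@shapes
  n <- nrow(X)
  if (n < 2L) stop("at least 2 shapes are required to build a model")
  Kmax <- n - 1L
  if (is.null(K)) K <- Kmax
  if (K > Kmax) {
    warning("K = ", K, " exceeds n - 1 = ", Kmax, "; capping at n - 1")
    K <- Kmax
  }
  ctr <- if (center == "mean") colMeans(X) else apply(X, 2L, stats::median)
  Xc <- sweep(X, 2L, ctr)
  totalSpread <- sum(Xc * Xc)
  if (totalSpread < 1e-18) {
    ## identical shapes: degenerate model, uniform fractions, flagged
    modes <- matrix(0, ncol(X), 0L)
    mod <- new("ShapeModel", mean = ctr, modes = modes, sd = numeric(0),
               varianceFractions = numeric(0), nTrain = as.integer(n),
               method = method, index = index,
               templateFaces = pop@templateFaces, labels = pop@labels,
               degenerate = TRUE)
    return(mod)
  }
  if (method == "classical_pca") {
    sv <- svd(Xc, nu = 0L, nv = K)
    keep <- seq_len(min(K, sum(sv$d > 1e-10 * sv$d[1L])))
    modes <- sv$v[, keep, drop = FALSE]
    scales <- sv$d[keep] / sqrt(n - 1)
  } else {
    pp <- .ppPursuit(Xc, K, index, pairwiseCandidates)
    modes <- pp$directions
    scales <- pp$scales
  }
  ord <- order(scales, decreasing = TRUE)
  modes <- modes[, ord, drop = FALSE]
  scales <- scales[ord]
  fr <- scales^2 / sum(scales^2)
  new("ShapeModel", mean = ctr, modes = modes, sd = scales,
      varianceFractions = fr, nTrain = as.integer(n), method = method,
      index = index, templateFaces = pop@templateFaces,
      labels = pop@labels, degenerate = FALSE)
}

#' Select the components that carry more than a fraction of the variation
#'
#' Components whose variance fraction exceeds the threshold (default 5\%,
#' the cut below which variation is on the order of imaging noise) are
#' retained for further analysis.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param threshold retention threshold in (0, 1); \code{0} retains all
#'   components.
#' @return integer vector of retained component indices, in order.
#' @export
selectComponents <- function(model, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold < 1)
  which(model@varianceFractions > threshold)
}

#' Synthesise a shape from the model
#'
#' Returns \code{mean + sum_k weights_k * sd_k * mode_k} reshaped to m
#' points. Unspecified weights are zero. Weights beyond 10 SD trigger a
#' warning (far outside any plausible population) but are still computed.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param weights per-component offsets in SD units; either a plain vector
#'   over leading components or a named/indexed assignment via \code{pc}.
#' @param pc optional component indices matching \code{weights}.
#' @return a \linkS4class{PointSet} (labels carried from the model).
#' @export
synthesizeShape <- function(model, weights = numeric(0), pc = NULL) {
  K <- ncol(model@modes)
  b <- numeric(K)
  if (!is.null(pc)) {
    stopifnot(length(pc) == length(weights), all(pc >= 1), all(pc <= K))
    b[pc] <- weights
  } else {
    if (length(weights) > K)
      stop("more weights than model components")
    b[seq_along(weights)] <- weights
  }
  if (any(abs(b) > 10))
    warning("weights beyond 10 SD are far outside the population")
  v <- model@mean + as.numeric(model@modes %*% (b * model@sd))
  pointSet(.unflattenShape(v), labels = model@labels, id = "synthesized")
}

#' Mean shape of a model
#'
#' @param model a \linkS4class{ShapeModel}.
#' @return the mean \linkS4class{PointSet}.
#' @export
meanShape <- function(model) {
  pointSet(.unflattenShape(model@mean), labels = model@labels, id = "mean")
}

#' Leave-one-out generalisability of the shape model
#'
#' For each shape: rebuild the model on the remaining n - 1 shapes, fit the
#' left-out shape-vector by least-squares projection onto the retained
#' modes, and record the per-point Euclidean residuals. The per-fold RMSE
#' is the root mean squared point residual; the overall RMSE pools point
#' residuals over all folds.
#'
#' @param pop a \linkS4class{CorrespondedPopulation} (n >= 3).
#' @param method,index passed to \code{\link{buildShapeModel}}.
#' @param modesUsed \code{"all"} (default) or an integer: number of leading
#'   modes used in the reconstruction.
#' @return a list with \code{perFold} (numeric RMSE per fold, mm) and
#'   \code{overall} (pooled RMSE, mm).
#' @export
looRMSE <- function(pop, method = "classical_pca", index = "variance",
                    modesUsed = "all") {
  X <- pop@shapes
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out analysis needs at least 3 shapes")
  perFold <- numeric(n)
  pooledSq <- 0
  m <- ncol(X) / 3L
  for (i in seq_len(n)) {
    sub <- correspondedPopulation(X[-i, , drop = FALSE],
                                  ids = pop@ids[-i])
    mod <- buildShapeModel(sub, method = method, index = index)
    M <- mod@modes
    if (!identical(modesUsed, "all")) {
      k <- min(as.integer(modesUsed), ncol(M))
      M <- M[, seq_len(k), drop = FALSE]
    }
    r <- X[i, ] - mod@mean
    if (ncol(M)) r <- r - as.numeric(M %*% crossprod(M, r))
    pn2 <- .pointNorms(r)^2
    perFold[i] <- sqrt(mean(pn2))
    pooledSq <- pooledSq + sum(pn2)
  }
  list(perFold = perFold, overall = sqrt(pooledSq / (n * m)))
}

#' Fit the model to a partially observed shape
#'
#' Estimates mode weights minimising the squared distance between
#' synthesised and observed points over the observed region (plus an
#' optional ridge penalty on the weights), then completes the shape. Used
#' for reconstructing missing or irregular anatomy from the regular
#' regions.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param observed either a \linkS4class{PointSet} whose points correspond
#'   to template indices \code{observedIdx}, or an m x 3 matrix with NA
#'   rows for unobserved points (then \code{observedIdx} may be omitted).
#' @param observedIdx template indices (1-based) of the observed points.
#' @param ridge non-negative ridge weight on the SD-unit weights; required
#'   positive when the observed region under-constrains the fit.
#' @param modesUsed \code{"all"} or an integer count of leading modes.
#' @return a list with \code{weights} (SD units), \code{completed}
#'   (\linkS4class{PointSet}) and \code{rms} (RMS distance on the observed
#'   region, mm).
#' @export
fitToPartial <- function(model, observed, observedIdx = NULL, ridge = 0,
                         modesUsed = "all") {
  if (is(observed, "PointSet")) observed <- shapePoints(observed)
  if (is.null(observedIdx)) {
    observedIdx <- which(stats::complete.cases(observed))
    observed <- observed[observedIdx, , drop = FALSE]
  }
  if (!length(observedIdx)) stop("observed point set is empty")
  stopifnot(nrow(observed) == length(observedIdx), ridge >= 0)
  K <- ncol(model@modes)
  if (!identical(modesUsed, "all")) K <- min(as.integer(modesUsed), K)
  coordIdx <- as.vector(rbind(3L * observedIdx - 2L, 3L * observedIdx - 1L,
                              3L * observedIdx))
  A <- model@modes[coordIdx, seq_len(K), drop = FALSE] *
    rep(model@sd[seq_len(K)], each = length(coordIdx))
  r <- .flattenShape(observed) - model@mean[coordIdx]
  if (3L * length(observedIdx) < K && ridge <= 0)
    stop("observed region under-constrains the fit; use ridge > 0")
  w <- solve(crossprod(A) + diag(ridge, K), crossprod(A, r))
  w <- as.numeric(w)
  completed <- synthesizeShape(model, weights = w,
                               pc = seq_len(K))
  res <- r - as.numeric(A %*% w)
  list(weights = w, completed = completed,
       rms = sqrt(mean(.pointNorms(res)^2)))
}
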