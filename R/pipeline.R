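## End-to-end orchestration of the four-stage pipeline: rigid alignment to
## a common reference, dense correspondence (subsample -> coarse non-rigid
## -> full-resolution local refinement), projection-pursuit PCA, component
## selection, distance maps and (optionally) leave-one-out analysis. All
## randomness flows from one root seed split per stage; the run's config
## snapshot is stored in the container so a run is reproducible
## bit-identically from the same inputs.

#' Pipeline run configuration
#'
#' @param rigid a \code{\link{rigidCPDParams}} bundle.
#' @param correspondence a \code{\link{correspondenceParams}} bundle.
#' @param method,index,center shape-model options (see
#'   \code{\link{buildShapeModel}}).
#' @param threshold component-retention threshold in (0, 1).
#' @param offsets SD offsets for the distance maps.
#' @param runLOO run leave-one-out analysis (slow for large n).
#' @param looModes \code{"all"} or an integer (see \code{\link{looRMSE}}).
#' @param seed root seed; per-stage seeds are derived from it.
#' @param referenceID id of the reference/template shape; default is the
#'   first id in sorted order.
#' @return a list of class \code{RunConfig}.
#' @export
runConfig <- function(rigid = rigidCPDParams(),
                      correspondence = correspondenceParams(),
                      method = "pp_pca", index = "variance",
                      center = "mean", threshold = 0.05,
                      offsets = c(-3, 3), runLOO = FALSE,
                      looModes = "all", seed = 1L, referenceID = NULL) {
  stopifnot(threshold > 0, threshold < 1, all(is.finite(offsets)))
  structure(list(rigid = rigid, correspondence = correspondence,
                 method = method, index = index, center = center,
                 threshold = threshold, offsets = offsets,
                 runLOO = runLOO, looModes = looModes,
                 seed = as.integer(seed), referenceID = referenceID),
            class = "RunConfig")
}

#' Run the full shape-modelling pipeline
#'
#' @param shapes list of \linkS4class{PointSet}s /
#'   \linkS4class{TriMesh}es (raw poses, arbitrary vertex order).
#' @param config a \code{\link{runConfig}}.
#' @return a \code{ModelContainer}: a list with the aligned population,
#'   per-shape transforms, the \linkS4class{CorrespondedPopulation}, the
#'   \linkS4class{ShapeModel}, retained component indices, distance maps,
#'   optional LOO results, a per-stage log, and the config snapshot.
#'   Stage failures leave a partial container with an \code{error} entry.
#' @export
runPipeline <- function(shapes, config = runConfig()) {
  stopifnot(length(shapes) >= 2L)
  log <- list()
  container <- list(config = config, stages = character(0))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      container$error <<- list(stage = name,
                               message = conditionMessage(res))
      NULL
    } else {
      container$stages <<- c(container$stages, name)
      res
    }
  }

  ## stage 1: rigid alignment
  reference <- NULL
  if (!is.null(config$referenceID)) {
    ids <- vapply(shapes, shapeID, "")
    j <- match(config$referenceID, ids)
    if (is.na(j)) stop("referenceID not found: ", config$referenceID)
    reference <- shapes[[j]]
  }
  al <- stage("rigid_alignment",
              alignPopulation(shapes, reference = reference,
                              params = config$rigid))
  if (is.null(al)) return(container)
  container$transforms <- lapply(al$transforms, transformToRecord)
  log$rigid <- list(nFailures = length(al$failures),
                    failures = al$failures)

  ## stage 2+3: subsampled coarse + full-resolution fine correspondence
  cpar <- config$correspondence
  cpar$seed <- .stageSeed(config$seed, "correspondence")
  pop <- stage("correspondence",
               correspondPopulation(al$reference, al$aligned,
                                    params = cpar))
  if (is.null(pop)) return(container)
  container$population <- pop
  log$correspondence <- list(failures = attr(pop, "failures"))

  ## stage 4: projection-pursuit PCA + component selection
  model <- stage("shape_model",
                 buildShapeModel(pop, method = config$method,
                                 index = config$index,
                                 center = config$center))
  if (is.null(model)) return(container)
  retained <- selectComponents(model, config$threshold)
  container$model <- model
  container$retained <- retained
  container$varianceTable <- data.frame(
    pc = seq_along(model@varianceFractions),
    variance_fraction = model@varianceFractions,
    cumulative = cumsum(model@varianceFractions),
    retained = seq_along(model@varianceFractions) %in% retained)

  container$distanceMaps <- stage("distance_maps",
                                  makePCDistanceMaps(model, retained,
                                                     config$offsets))
  if (isTRUE(config$runLOO)) {
    container$loo <- stage("loo", looRMSE(pop, method = config$method,
                                          index = config$index,
                                          modesUsed = config$looModes))
    if (!is.null(container$loo))
      log$loo <- list(overall = container$loo$overall)
  }
  log$elapsed <- proc.time()[["elapsed"]] - t0
  container$log <- log
  class(container) <- "ModelContainer"
  container
}

#' Save / load a model container
#'
#' The container is stored as a single uncompressed RDS file (named-array
#' serialisation, byte-deterministic for identical runs) and round-trips
#' losslessly.
#'
#' @param container a \code{ModelContainer}.
#' @param path output file.
#' @return \code{path} / the container.
#' @export
saveModelContainer <- function(container, path) {
  saveRDS(container, path, compress = FALSE)
  invisible(path)
}

#' @rdname saveModelContainer
#' @export
readModelContainer <- function(path) readRDS(path)

#' Write the pipeline report tables
#'
#' Writes the variance-fraction table (separate and cumulative variation
#' per component, with retention flags) and, when present, LOO results as
#' CSV files in \code{dir}.
#'
#' @param container a \code{ModelContainer}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePipelineReport <- function(container, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(container$varianceTable,
                   file.path(dir, "variance_fractions.csv"),
                   row.names = FALSE)
  if (!is.null(container$loo))
    utils::write.csv(data.frame(fold = seq_along(container$loo$perFold),
                                rmse_mm = container$loo$perFold),
                     file.path(dir, "loo_rmse.csv"), row.names = FALSE)
  tf <- do.call(rbind, container$transforms)
  if (!is.null(tf)) {
    df <- as.data.frame(tf)
    names(df) <- c(paste0("m", rep(1:3, each = 3), rep(1:3, 3)),
                   "tx", "ty", "tz")
    utils::write.csv(cbind(shape = seq_len(nrow(df)), df),
                     file.path(dir, "transforms.csv"), row.names = FALSE)
  }
  invisible(dir)
}
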