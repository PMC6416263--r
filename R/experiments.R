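.spacingString <- function(spacing) paste(signif(spacing, 6), collapse = "x")

.featureRow <- function(mesh, provenance) {
  fv <- computeFeatures(mesh, provenance = provenance)
  cbind(
    as.data.frame(provenance, stringsAsFactors = FALSE),
    as.data.frame(fv),
    data.frame(error = NA_character_, stringsAsFactors = FALSE)
  )
}

.failureRow <- function(provenance, msg) {
  vals <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(featureNames())), featureNames()
  )))
  cbind(
    as.data.frame(provenance, stringsAsFactors = FALSE), vals,
    data.frame(error = msg, stringsAsFactors = FALSE)
  )
}

#' Long-format feature table for a phantom suite
#'
#' Runs the acquisition emulation for every model — rasterize at `spacing`,
#' optionally resample to `resampleGrid`, optionally equalize all volumes
#' to the mean isosurface (M1) volume — then reconstructs a surface with
#' each requested method and computes the nine shape features.  Failures
#' of individual cells are recorded in the `error` column and do not stop
#' the run.
#'
#' @param suite a [PhantomSuite-class].
#' @param spacing voxel spacing in mm, default `c(0.68, 0.68, 2)`.
#' @param methods subset of `c("M1","M2","M3","M4")`.
#' @param equalize equalize volumes across the suite (default `TRUE`).
#' @param resample resample masks to `resampleGrid` before equalization
#'   (default `FALSE`).
#' @param resampleGrid grid for `resample`, default `c(1, 1, 1)` mm.
#' @param isovalue,quantity,targetEdge meshing parameters (defaults 0.9,
#'   5, 2).
#' @return data.frame with provenance columns (`model_d`, `method`,
#'   `spacing`, `resampled`, `fraction`), the nine features, and `error`.
#' @export
suiteFeatureTable <- function(suite, spacing = c(0.68, 0.68, 2),
                              methods = c("M1", "M2", "M3"),
                              equalize = TRUE, resample = FALSE,
                              resampleGrid = c(1, 1, 1), isovalue = 0.9,
                              quantity = 5, targetEdge = 2) {
  stopifnot(is(suite, "PhantomSuite"))
  methods <- match.arg(methods, c("M1", "M2", "M3", "M4"),
                       several.ok = TRUE)
  d <- spiculationValues(suite)
  masks <- lapply(suiteMeshes(suite), voxelize, spacing = spacing)
  if (resample) masks <- lapply(masks, resampleMask, newSpacing = resampleGrid)
  if (equalize) masks <- equalizeVolumes(masks, isovalue = isovalue)

  rows <- list()
  for (i in seq_along(masks)) {
    for (m in methods) {
      prov <- list(
        model_d = d[i], method = m, spacing = .spacingString(spacing),
        resampled = resample, fraction = 1
      )
      rows[[length(rows) + 1L]] <- tryCatch(
        .featureRow(meshMask(masks[[i]], m, isovalue = isovalue,
                             quantity = quantity, targetEdge = targetEdge),
                    prov),
        error = function(e) .failureRow(prov, conditionMessage(e))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of every shape feature with spiculatedness
#'
#' The full pipeline of the correlation experiment: rasterize the suite,
#' equalize volumes to the mean isosurface volume, mesh with each method,
#' extract features, and correlate each of the eight non-volume features
#' with the spiculatedness parameter `d` (treated as an ordinal variable;
#' ascending `d` means less spiculated).  Surface area, surface-to-volume
#' and spherical disproportion decrease with `d`; the compactness family,
#' sphericity and fractional concavity increase.
#'
#' @inheritParams suiteFeatureTable
#' @return data.frame with columns `feature`, `method`, `rho`, `ci_lo`,
#'   `ci_hi`, `p`; the full feature table is attached as attribute
#'   `"featureTable"`.
#' @export
runCorrelationExperiment <- function(suite, spacing = c(0.68, 0.68, 2),
                                     methods = c("M1", "M2", "M3"),
                                     isovalue = 0.9, quantity = 5,
                                     targetEdge = 2) {
  if (length(suite) < 10L) {
    stop("need at least 10 models for meaningful rank correlations")
  }
  tab <- suiteFeatureTable(suite, spacing = spacing, methods = methods,
                           equalize = TRUE, isovalue = isovalue,
                           quantity = quantity, targetEdge = targetEdge)
  feats <- setdiff(featureNames(), "volume")
  rows <- list()
  for (m in unique(tab$method)) {
    sub <- tab[tab$method == m & is.na(tab$error), , drop = FALSE]
    for (f in feats) {
      s <- spearmanRho(sub[[f]], sub$model_d)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, method = m, rho = s$rho, ci_lo = s$ci[1],
        ci_hi = s$ci[2], p = s$p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "featureTable") <- tab
  out
}

#' Pairwise Spearman correlations among the shape features
#'
#' Correlation matrix of the eight non-volume features across the models
#' of a feature table, one matrix per meshing method.  Entries undefined
#' because a feature is constant are returned as `NA`.
#'
#' @param featureTable a table from [suiteFeatureTable()].
#' @return a named list (one symmetric matrix with unit diagonal per
#'   method), or a single matrix when only one method is present.
#' @export
featureCorrelationMatrix <- function(featureTable) {
  feats <- setdiff(featureNames(), "volume")
  out <- lapply(split(featureTable, featureTable$method), function(sub) {
    sub <- sub[is.na(sub$error), , drop = FALSE]
    if (nrow(sub) < 3L) stop("need at least 3 models")
    m <- matrix(NA_real_, length(feats), length(feats),
                dimnames = list(feats, feats))
    for (i in seq_along(feats)) {
      for (j in seq_len(i)) {
        m[i, j] <- m[j, i] <- tryCatch(
          spearmanRho(sub[[feats[i]]], sub[[feats[j]]])$rho,
          error = function(e) NA_real_
        )
      }
      m[i, i] <- 1
    }
    m
  })
  if (length(out) == 1L) out[[1L]] else out
}

.summarisePC <- function(pc, by) {
  agg <- function(fun) stats::aggregate(pc$percent_change, by, fun)
  s <- agg(mean)
  s$min <- agg(min)$x
  s$max <- agg(max)$x
  names(s)[names(s) == "x"] <- "mean"
  s
}

#' Percent change of pipeline features against the STL reference
#'
#' Features computed directly from each model's source triangulation (the
#' STL reference, before any rasterization) are compared with features
#' computed through the full mask-and-mesh pipeline at the given spacing;
#' percent changes use the STL value as reference and are summarized as
#' mean/min/max over the suite.
#'
#' @inheritParams suiteFeatureTable
#' @return list with `perModel` (long data.frame of percent changes) and
#'   `summary` (mean/min/max per feature and method).
#' @export
runReferenceComparison <- function(suite, spacing = c(0.68, 0.68, 2),
                                   methods = c("M1", "M2", "M3"),
                                   isovalue = 0.9, quantity = 5,
                                   targetEdge = 2) {
  d <- spiculationValues(suite)
  ref <- lapply(suiteMeshes(suite), function(m) {
    featureValues(computeFeatures(m))
  })
  tab <- suiteFeatureTable(suite, spacing = spacing, methods = methods,
                           equalize = FALSE, isovalue = isovalue,
                           quantity = quantity, targetEdge = targetEdge)
  .percentChangeTable(tab, function(row) ref[[match(row$model_d, d)]],
                      comparison = "pipeline_vs_stl")
}

.percentChangeTable <- function(tab, refFun, comparison) {
  feats <- featureNames()
  rows <- list()
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, , drop = FALSE]
    if (!is.na(row$error)) next
    refv <- refFun(row)
    if (is.null(refv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = comparison, model_d = row$model_d, method = row$method,
      feature = feats,
      percent_change = percentChange(unlist(row[feats]), refv[feats]),
      stringsAsFactors = FALSE
    )
  }
  pc <- do.call(rbind, rows)
  rownames(pc) <- NULL
  summary <- .summarisePC(pc, list(feature = pc$feature, method = pc$method))
  list(perModel = pc, summary = summary)
}

#' Percent change of features between two slice thicknesses
#'
#' Features are extracted from native masks at both spacings without any
#' volume modification; percent changes take the coarse-slice arm as the
#' reference.
#'
#' @param suite a [PhantomSuite-class].
#' @param spacingFine fine-slice spacing, default `c(0.68, 0.68, 0.6)`.
#' @param spacingCoarse coarse-slice (reference) spacing, default
#'   `c(0.68, 0.68, 2)`.
#' @inheritParams suiteFeatureTable
#' @return list with `perModel` and `summary` as in
#'   [runReferenceComparison()].
#' @export
runSliceThicknessComparison <- function(suite,
                                        spacingFine = c(0.68, 0.68, 0.6),
                                        spacingCoarse = c(0.68, 0.68, 2),
                                        methods = c("M1", "M3"),
                                        isovalue = 0.9, quantity = 5,
                                        targetEdge = 2) {
  fine <- suiteFeatureTable(suite, spacing = spacingFine, methods = methods,
                            equalize = FALSE, isovalue = isovalue,
                            quantity = quantity, targetEdge = targetEdge)
  coarse <- suiteFeatureTable(suite, spacing = spacingCoarse,
                              methods = methods, equalize = FALSE,
                              isovalue = isovalue, quantity = quantity,
                              targetEdge = targetEdge)
  key <- function(t) paste(t$model_d, t$method)
  ck <- key(coarse)
  .percentChangeTable(fine, function(row) {
    i <- match(paste(row$model_d, row$method), ck)
    if (is.na(i) || !is.na(coarse$error[i])) return(NULL)
    unlist(coarse[i, featureNames()])
  }, comparison = "fine_vs_coarse_slice")
}

#' Sensitivity of features to volume versus spiculatedness
#'
#' For representative models, the volume is varied homothetically over
#' `fractions` of the original (by recomputing the voxel spacing) and the
#' resulting percent change of each feature (reference: unscaled volume)
#' is compared with the percent change between the most and least
#' spiculated models of the suite (reference: the most spiculated model)
#' under equalized volumes.  A feature is classified volume-robust when
#' its maximal volume-induced change stays below its spiculatedness
#' change.
#'
#' @param suite a [PhantomSuite-class] (must contain the requested `ds`
#'   and at least two models for the spiculatedness spread).
#' @param ds spiculatedness values of the representative models, default
#'   `c(11, 47, 92)`.
#' @param fractions volume fractions, default
#'   `c(0.25, 0.5, 0.75, 1, 1.25, 1.5)`.
#' @inheritParams suiteFeatureTable
#' @param method meshing method used throughout, default `"M3"`.
#' @return data.frame per feature with the spiculatedness spread, the
#'   per-model volume spreads, their maximum, and the `volume_robust`
#'   classification.
#' @export
runVolumeSensitivity <- function(suite, ds = c(11, 47, 92),
                                 fractions = c(0.25, 0.5, 0.75, 1, 1.25, 1.5),
                                 spacing = c(0.68, 0.68, 2), method = "M3",
                                 isovalue = 0.9, quantity = 5,
                                 targetEdge = 2) {
  stopifnot(is(suite, "PhantomSuite"), all(fractions > 0),
            1 %in% fractions)
  d <- spiculationValues(suite)
  if (!all(ds %in% d)) stop("suite does not contain all requested d values")
  masks <- lapply(suiteMeshes(suite), voxelize, spacing = spacing)
  masks <- equalizeVolumes(masks, isovalue = isovalue)

  featOf <- function(mask) {
    featureValues(computeFeatures(meshMask(
      mask, method, isovalue = isovalue, quantity = quantity,
      targetEdge = targetEdge
    )))
  }

  # spiculatedness spread: least vs most spiculated, volume-equalized
  fLow <- featOf(masks[[which.min(d)]])
  fHigh <- featOf(masks[[which.max(d)]])
  spic <- percentChange(fHigh, fLow)

  volSpread <- sapply(ds, function(dv) {
    m0 <- masks[[match(dv, d)]]
    base <- featOf(m0)
    spread <- rep(0, length(featureNames()))
    for (f in setdiff(fractions, 1)) {
      fv <- featOf(rescaleVolume(m0, f))
      spread <- pmax(spread, percentChange(fv, base))
    }
    spread
  })
  colnames(volSpread) <- paste0("volume_change_d", ds)

  out <- data.frame(
    feature = featureNames(),
    spiculatedness_change = as.numeric(spic[featureNames()]),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, volSpread)
  out$volume_change_max <- apply(volSpread, 1L, max)
  out$volume_robust <- out$volume_change_max < out$spiculatedness_change
  rownames(out) <- NULL
  out
}
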