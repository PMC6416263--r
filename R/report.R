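.log <- function(level, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARNING = 3L, ERROR = 4L)
  threshold <- getOption("spiculo.logLevel", "INFO")
  if (levels[[level]] >= levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# full-precision deterministic CSV writer
.writeCSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.17g", out[[j]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Run the complete phantom robustness study
#'
#' Generates the phantom suite and executes every experiment: the
#' correlation of each feature with spiculatedness, the STL-reference
#' comparison, the slice-thickness comparison (when two spacings are
#' configured), the grid-resampling comparison, the pairwise
#' feature-correlation matrix, and the volume-sensitivity classification.
#' Fully deterministic: identical configurations produce identical
#' tables.
#'
#' @param cfg a `spiculoConfig`, default [defaultConfig()].
#' @return an [ExperimentReport-class].
#' @export
reproduceAll <- function(cfg = defaultConfig()) {
  .validateConfig(cfg)
  op <- options(spiculo.logLevel = cfg$log_level)
  on.exit(options(op))
  num <- function(k) as.numeric(cfg[[k]])
  spacings <- configSpacings(cfg)
  methods <- configMethods(cfg)
  grid <- as.numeric(strsplit(cfg$resample_grid, "x")[[1L]])
  fractions <- as.numeric(strsplit(cfg$volume_fractions, ",")[[1L]])
  volModels <- as.numeric(strsplit(cfg$volume_models, ",")[[1L]])

  t0 <- Sys.time()
  .log("INFO", "generating phantom suite")
  suite <- generateSuite(
    dStart = num("d_start"), dStop = num("d_stop"), dStep = num("d_step"),
    degreeL = num("degree_l"), orderM = num("order_m"),
    amplitudeA = num("amplitude_a"), baseSize = num("base_mm"),
    nTheta = num("n_theta"), nPhi = num("n_phi")
  )
  .log("INFO", sprintf("suite of %d models (%.1fs)", length(suite),
                       as.numeric(Sys.time() - t0, units = "secs")))

  mainSpacing <- spacings[[1L]]
  .log("INFO", "correlation experiment")
  correlations <- runCorrelationExperiment(
    suite, spacing = mainSpacing, methods = methods,
    isovalue = num("isovalue"), quantity = num("smooth_quantity"),
    targetEdge = num("target_edge")
  )
  featureTable <- attr(correlations, "featureTable")

  .log("INFO", "STL reference comparison")
  refCmp <- runReferenceComparison(
    suite, spacing = mainSpacing, methods = methods,
    isovalue = num("isovalue"), quantity = num("smooth_quantity"),
    targetEdge = num("target_edge")
  )

  pcs <- list(stl_reference = refCmp)
  if (length(spacings) >= 2L) {
    .log("INFO", "slice thickness comparison")
    pcs$slice_thickness <- runSliceThicknessComparison(
      suite, spacingFine = spacings[[2L]], spacingCoarse = mainSpacing,
      methods = intersect(methods, c("M1", "M3")),
      isovalue = num("isovalue"), quantity = num("smooth_quantity"),
      targetEdge = num("target_edge")
    )
  }

  .log("INFO", "resampling comparison")
  pcs$resampling <- runResamplingComparison(
    suite, spacing = mainSpacing,
    methods = intersect(methods, c("M1", "M3")), resampleGrid = grid,
    isovalue = num("isovalue"), quantity = num("smooth_quantity"),
    targetEdge = num("target_edge")
  )

  .log("INFO", "volume sensitivity")
  volSens <- runVolumeSensitivity(
    suite, ds = volModels, fractions = fractions, spacing = mainSpacing,
    method = intersect(methods, c("M3", "M1"))[1L],
    isovalue = num("isovalue"), quantity = num("smooth_quantity"),
    targetEdge = num("target_edge")
  )
  pcs$volume_sensitivity <- volSens

  new("ExperimentReport",
    features = featureTable,
    correlations = as.data.frame(correlations),
    percentChanges = pcs,
    meta = list(
      config = cfg,
      package_version = as.character(utils::packageVersion("spiculo"))
    )
  )
}

#' Percent change of features after grid resampling
#'
#' Features from native masks are compared with features from the same
#' masks resampled onto an isotropic grid (default 1 mm^3); the original
#' (native) value is the reference.
#'
#' @inheritParams suiteFeatureTable
#' @return list with `perModel` and `summary`; the attribute
#'   `"rankPreserved"` reports, per feature and method, whether the
#'   ranking of the models was unchanged by the resampling.
#' @export
runResamplingComparison <- function(suite, spacing = c(0.68, 0.68, 2),
                                    methods = c("M1", "M3"),
                                    resampleGrid = c(1, 1, 1),
                                    isovalue = 0.9, quantity = 5,
                                    targetEdge = 2) {
  orig <- suiteFeatureTable(suite, spacing = spacing, methods = methods,
                            equalize = FALSE, isovalue = isovalue,
                            quantity = quantity, targetEdge = targetEdge)
  res <- suiteFeatureTable(suite, spacing = spacing, methods = methods,
                           equalize = FALSE, resample = TRUE,
                           resampleGrid = resampleGrid,
                           isovalue = isovalue, quantity = quantity,
                           targetEdge = targetEdge)
  ok <- function(t) t[is.na(t$error), , drop = FALSE]
  okey <- paste(orig$model_d, orig$method)
  out <- .percentChangeTable(res, function(row) {
    i <- match(paste(row$model_d, row$method), okey)
    if (is.na(i) || !is.na(orig$error[i])) return(NULL)
    unlist(orig[i, featureNames()])
  }, comparison = "resampled_vs_original")

  rank_ok <- list()
  for (m in methods) {
    o <- ok(orig[orig$method == m, , drop = FALSE])
    r <- ok(res[res$method == m, , drop = FALSE])
    o <- o[order(o$model_d), , drop = FALSE]
    r <- r[order(r$model_d), , drop = FALSE]
    if (!identical(o$model_d, r$model_d)) next
    rank_ok[[m]] <- vapply(featureNames(), function(f) {
      identical(rank(o[[f]]), rank(r[[f]]))
    }, logical(1))
  }
  attr(out, "rankPreserved") <- rank_ok
  out
}

#' Write an experiment report to disk
#'
#' Emits `features_long.csv`, `correlations.csv`, `percent_changes.csv`,
#' `volume_sensitivity.csv`, `summary.md`, a `config.txt` snapshot, and a
#' `manifest.json` with the configuration hash and the package version.
#' Column ordering is fixed and numeric columns are written at full
#' double precision, so writing the same report twice produces
#' byte-identical files.  Failed cells appear as explicit `NA` rows with
#' the failure reason in the `error` column.
#'
#' @param report an [ExperimentReport-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "ExperimentReport"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  .writeCSV(report@features, file.path(dir, "features_long.csv"))
  .writeCSV(report@correlations, file.path(dir, "correlations.csv"))

  pcs <- report@percentChanges
  longs <- list()
  for (nm in names(pcs)) {
    if (is.list(pcs[[nm]]) && !is.data.frame(pcs[[nm]]) &&
        !is.null(pcs[[nm]]$perModel)) {
      longs[[nm]] <- pcs[[nm]]$perModel
    }
  }
  if (length(longs)) {
    .writeCSV(do.call(rbind, longs), file.path(dir, "percent_changes.csv"))
  }
  if (!is.null(pcs$volume_sensitivity)) {
    .writeCSV(pcs$volume_sensitivity,
              file.path(dir, "volume_sensitivity.csv"))
  }

  cfg <- report@meta$config
  cfgPath <- file.path(dir, "config.txt")
  if (!is.null(cfg)) saveConfig(cfg, cfgPath)

  md <- c(
    "# Phantom robustness report", "",
    sprintf("- models: %d", length(unique(report@features$model_d))),
    sprintf("- methods: %s",
            paste(unique(report@features$method), collapse = ", ")),
    sprintf("- min |rho| vs spiculatedness (non-volume features): %.4f",
            min(abs(report@correlations$rho))),
    ""
  )
  writeLines(md, file.path(dir, "summary.md"))

  hash <- if (file.exists(cfgPath)) {
    unname(tools::md5sum(cfgPath))
  } else {
    ""
  }
  manifest <- c(
    "{",
    sprintf('  "config_md5": "%s",', hash),
    sprintf('  "package": "spiculo",'),
    sprintf('  "version": "%s"',
            as.character(report@meta$package_version)),
    "}"
  )
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf(
    "ExperimentReport: %d feature rows, %d correlation rows, comparisons: %s\n",
    nrow(object@features), nrow(object@correlations),
    paste(names(object@percentChanges), collapse = ", ")
  ))
  invisible(NULL)
})
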