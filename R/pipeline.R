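# Pipeline orchestration and the quantitative report.

.config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.ai_table <- function(cohort) {
  metrics <- cohortMetrics(cohort)
  ai <- data.frame(scan_id = cohort$scan_id, subject_id = cohort$subject_id,
                   group = cohort$group)
  for (m in metrics)
    ai[[paste0("ai_", m)]] <- asymmetryIndex(cohort[[paste0(m, "_lh")]],
                                             cohort[[paste0(m, "_rh")]])
  ai
}

#' Run the full biomarker pipeline
#'
#' Orchestrates every stage on a cohort table: asymmetry indices for all
#' side-paired metrics, normative volume model on the controls, HC
#' asymmetry limits, 3-SD classification with sensitivity/specificity/F1
#' and AUC on the unilateral-HS vs all-other-epilepsies contrast, SVM
#' feature ranking, test-retest robustness, and the quantitative report.
#' All outputs are written under `out_dir`; reruns with the same config
#' and seed give identical CSV content.
#'
#' @param config either a YAML file path or a list with elements
#'   `cohort_csv` (path) or `simulate = TRUE` (use the synthetic cohort
#'   generator), optional `seed` (default 1), optional `report_metric`
#'   (default `"sv_ratio"`).
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with the in-memory results (`cohort`, `ai`,
#'   `limits`, `classification`, `metrics`, `auc`, `ranking`,
#'   `robustness`, `paths`).
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("hippasym %s | R %s | config %s | seed %d",
          as.character(utils::packageVersion("hippasym")),
          paste(R.version$major, R.version$minor, sep = "."),
          .config_hash(config), seed)

  cohort <- if (isTRUE(config$simulate)) {
    generateMeasurementCohort(cohortConfig(seed = seed))
  } else {
    if (is.null(config$cohort_csv))
      stop("config is missing key 'cohort_csv' (or set simulate: true)")
    readCohortTable(config$cohort_csv)
  }
  logline("stage cohort: %d scans, %d subjects", nrow(cohort),
          length(unique(cohort$subject_id)))

  ai <- .ai_table(cohort)
  report_metric <- config$report_metric %||% "sv_ratio"
  if (!report_metric %in% cohortMetrics(cohort))
    stop("report metric '", report_metric, "' not present in cohort")

  # normative volume model (controls), applied to all scans
  model <- if ("volume" %in% cohortMetrics(cohort)) {
    m <- fitNormativeModel(cohort, "volume_lh")
    cohort$volume_lh_corrected <- correctVolume(cohort, m)
    m2 <- fitNormativeModel(cohort, "volume_rh")
    cohort$volume_rh_corrected <- correctVolume(cohort, m2)
    list(lh = m, rh = m2)
  } else NULL

  # limits + classification per metric
  conv <- c(volume = "loss", sv_ratio = "gain")
  limits <- list()
  classification <- data.frame(scan_id = ai$scan_id, group = ai$group)
  metrics_out <- list()
  auc_out <- list()
  for (m in intersect(names(conv), cohortMetrics(cohort))) {
    aim <- ai[[paste0("ai_", m)]]
    lim <- fitNormativeLimits(aim[ai$group == "HC"], metric = m)
    limits[[m]] <- lim
    pred <- classifyByAsymmetry(aim, lim, level = "3SD",
                                convention = conv[[m]])
    classification[[paste0(m, "_label")]] <- pred
    metrics_out[[m]] <- binaryMetrics(pred, ai$group)
    uni <- ai$group %in% c("HS-left", "HS-right", "EPI-other")
    auc_out[[m]] <- rocAuc(abs(aim[uni]),
                           ai$group[uni] %in% c("HS-left", "HS-right"))
    logline("stage biomarker[%s]: F1 %.3f, AUC %.3f", m,
            metrics_out[[m]]$f1, auc_out[[m]])
  }

  # feature ranking on the AI of every side-paired metric
  ranking <- NULL
  pat <- ai$group %in% c("HS-left", "HS-right", "EPI-other")
  feat_cols <- grep("^ai_", names(ai), value = TRUE)
  if (length(feat_cols) >= 2) {
    ranking <- rankShapeFeatures(ai[pat, feat_cols, drop = FALSE],
                                 ai$group[pat] %in% c("HS-left", "HS-right"),
                                 ai$subject_id[pat], seed = seed)
    logline("stage ranking: top feature %s", ranking$table$feature[1])
  }

  robustness <- robustnessSummary(cohort)
  logline("stage robustness: %d sessions", robustness$n_sessions[1])

  paths <- list(
    features = file.path(out_dir, "features.csv"),
    ai = file.path(out_dir, "asymmetry.csv"),
    limits = file.path(out_dir, "limits.json"),
    classification = file.path(out_dir, "classification.csv"),
    ranking = file.path(out_dir, "ranking.csv"),
    robustness = file.path(out_dir, "robustness.csv"),
    report = file.path(out_dir, "report.png"),
    report_coords = file.path(out_dir, "report_coordinates.csv"))
  write.csv(cohort, paths$features, row.names = FALSE)
  write.csv(ai, paths$ai, row.names = FALSE)
  jsonlite::write_json(lapply(limits, function(l) list(
    metric = l@metric, hc_mean_ai = l@hc_mean_ai, hc_sd_ai = l@hc_sd_ai,
    n_hc = l@n_hc, thresholds = l@thresholds)),
    paths$limits, auto_unbox = TRUE, digits = NA)
  write.csv(classification, paths$classification, row.names = FALSE)
  if (!is.null(ranking))
    write.csv(ranking$table, paths$ranking, row.names = FALSE)
  write.csv(robustness, paths$robustness, row.names = FALSE)
  coords <- renderReport(cohort, limits[[report_metric]],
                         metric = report_metric, path = paths$report)
  write.csv(coords, paths$report_coords, row.names = FALSE)
  logline("done: %d outputs", length(paths))
  invisible(list(cohort = cohort, ai = ai, limits = limits,
                 classification = classification, metrics = metrics_out,
                 auc = auc_out, ranking = ranking, robustness = robustness,
                 model = model, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the quantitative report
#'
#' Scatter of the left (x) vs right (y) measure, one point per scan, with
#' the identity diagonal and the 2-SD and 3-SD asymmetry limits drawn as
#' constant-AI loci - rays through the origin with slope
#' `(1 - a) / (1 + a)` for limit `a`, since the AI is a ratio. Healthy
#' scans cluster on the diagonal; left-abnormal scans fall on one side of
#' the band, right-abnormal on the other.
#'
#' @param cohort cohort data.frame with `<metric>_lh` / `<metric>_rh`.
#' @param limits an [AsymmetryLimits-class] for the metric.
#' @param metric metric base name, default `"sv_ratio"`.
#' @param path output image path (PNG); `NULL` skips the image.
#' @param highlight scan_ids to annotate.
#' @return data.frame of per-scan coordinates and flags: `scan_id`,
#'   `group`, `lh`, `rh`, `ai`, `outside_2sd`, `outside_3sd`, `label`.
#' @export
renderReport <- function(cohort, limits, metric = "sv_ratio", path = NULL,
                         highlight = character()) {
  stopifnot(is(limits, "AsymmetryLimits"))
  lh <- cohort[[paste0(metric, "_lh")]]
  rh <- cohort[[paste0(metric, "_rh")]]
  if (is.null(lh) || is.null(rh) || anyNA(lh) || anyNA(rh))
    stop("metric '", metric, "' not present for all scans")
  ai <- asymmetryIndex(lh, rh)
  conv <- if (metric == "volume") "loss" else "gain"
  lab <- classifyByAsymmetry(ai, limits, level = "3SD", convention = conv)
  th2 <- limits@thresholds[["2SD"]]
  th3 <- limits@thresholds[["3SD"]]
  coords <- data.frame(scan_id = cohort$scan_id, group = cohort$group,
                       lh = lh, rh = rh, ai = ai,
                       outside_2sd = ai < th2[1] | ai > th2[2],
                       outside_3sd = ai < th3[1] | ai > th3[2],
                       label = lab)
  if (!is.null(path)) {
    slope <- function(a) (1 - a) / (1 + a)  # rh = slope(a) * lh on AI = a
    p <- ggplot2::ggplot(coords, ggplot2::aes(x = lh, y = rh,
                                              colour = group)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
      ggplot2::geom_abline(slope = slope(th2[1]), intercept = 0,
                           linetype = "dashed", colour = "grey55") +
      ggplot2::geom_abline(slope = slope(th2[2]), intercept = 0,
                           linetype = "dashed", colour = "grey55") +
      ggplot2::geom_abline(slope = slope(th3[1]), intercept = 0,
                           linetype = "dotted", colour = "grey30") +
      ggplot2::geom_abline(slope = slope(th3[2]), intercept = 0,
                           linetype = "dotted", colour = "grey30") +
      ggplot2::geom_point(alpha = 0.7, size = 1.6) +
      ggplot2::labs(x = paste("left", metric), y = paste("right", metric),
                    title = "Hippocampal asymmetry report",
                    subtitle = "dashed: 2 SD, dotted: 3 SD normative AI limits") +
      ggplot2::theme_minimal()
    if (length(highlight)) {
      hi <- coords[coords$scan_id %in% highlight, ]
      p <- p + ggplot2::geom_point(data = hi, shape = 1, size = 4,
                                   colour = "black") +
        ggplot2::geom_text(data = hi, ggplot2::aes(label = scan_id),
                           vjust = -1, size = 3, colour = "black")
    }
    grDevices::png(path, width = 1400, height = 1200, res = 200)
    print(p)
    grDevices::dev.off()
  }
  coords
}
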