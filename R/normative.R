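# Normative volume model: hippocampal volume corrected for head size and
# age by an OLS fit on healthy controls with z-scored covariates, then
# applied to all subjects. Sex is deliberately not a covariate.

#' Fit a normative volume model on healthy controls
#'
#' Ordinary least squares of `metric` on z-scored eTIV and age. The
#' z-scoring constants (mean and sample SD) are computed from the HC rows
#' themselves and stored in the model so the correction can later be
#' applied to all subjects on the same scale.
#'
#' @param cohort cohort data.frame (see [readCohortTable()]); rows with
#'   `group != "HC"` are ignored.
#' @param metric name of the volume column to model, e.g. `"volume_lh"`.
#' @return A [NormativeModel-class].
#' @export
fitNormativeModel <- function(cohort, metric = "volume_lh") {
  if (!metric %in% names(cohort)) stop("no column '", metric, "' in cohort")
  hc <- cohort[cohort$group == "HC" &
                 complete.cases(cohort[, c(metric, "etiv", "age")]), ]
  if (nrow(hc) < 10L) stop("need at least 10 HC records, got ", nrow(hc))
  mu <- c(etiv = mean(hc$etiv), age = mean(hc$age))
  sds <- c(etiv = sd(hc$etiv), age = sd(hc$age))
  if (any(sds <= 0)) stop("constant covariate among HC records")
  ze <- (hc$etiv - mu["etiv"]) / sds["etiv"]
  za <- (hc$age - mu["age"]) / sds["age"]
  fit <- lm(hc[[metric]] ~ ze + za)
  cf <- coef(fit)
  new("NormativeModel", metric = metric,
      intercept = unname(cf[1]), beta_etiv = unname(cf["ze"]),
      beta_age = unname(cf["za"]), covariate_means = mu,
      covariate_sds = sds,
      residual_sd = sqrt(sum(fit$residuals^2) / fit$df.residual),
      n_hc = nrow(hc))
}

#' Apply the normative correction to scan records
#'
#' Removes the fitted covariate effect while retaining the intercept, so
#' corrected values stay in mm^3:
#' `corrected = observed - beta_etiv * z(eTIV) - beta_age * z(age)`,
#' with z-scores computed from the model's stored HC constants. A record
#' exactly at the HC covariate means is returned unchanged.
#'
#' @param cohort cohort data.frame (any groups).
#' @param model a [NormativeModel-class].
#' @return Numeric vector of corrected volumes (mm^3), one per row.
#' @export
correctVolume <- function(cohort, model) {
  stopifnot(is(model, "NormativeModel"))
  if (!model@metric %in% names(cohort))
    stop("no column '", model@metric, "' in cohort")
  if (anyNA(cohort$etiv) || anyNA(cohort$age))
    stop("missing covariate (etiv/age)")
  ze <- (cohort$etiv - model@covariate_means["etiv"]) /
    model@covariate_sds["etiv"]
  za <- (cohort$age - model@covariate_means["age"]) /
    model@covariate_sds["age"]
  unname(cohort[[model@metric]] - model@beta_etiv * ze - model@beta_age * za)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#' Convention for group effects: the patient group is passed first, so
#' volume loss in left HS yields a negative d against controls.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return List with `d`, `n1`, `n2`.
#' @examples
#' cohensD(c(2, 4, 6), c(5, 7, 9))$d  # -1.5
#' @export
cohensD <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  list(d = (mean(a) - mean(b)) / sqrt(sp2), n1 = n1, n2 = n2)
}

#' Serialize a normative model to JSON
#'
#' @param model a [NormativeModel-class].
#' @param path output path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
writeNormativeModel <- function(model, path = NULL) {
  x <- list(metric = model@metric, intercept = model@intercept,
            beta_etiv = model@beta_etiv, beta_age = model@beta_age,
            covariate_means = as.list(model@covariate_means),
            covariate_sds = as.list(model@covariate_sds),
            residual_sd = model@residual_sd, n_hc = model@n_hc)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
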