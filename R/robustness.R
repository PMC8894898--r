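# Test-retest robustness: re-scan sessions, session-wise MAPE, ICC(2,1)
# from the two-way random-effects ANOVA with absolute agreement, and
# paired t-tests between methods.

#' Group repeat scans into sessions
#'
#' Patients: scans of one subject acquired on the same calendar day form a
#' session. Healthy controls: greedy chronological chaining - a session
#' starts at the subject's earliest unassigned scan and absorbs all scans
#' within 365 days of that anchor. Only sessions with >= 2 scans are
#' returned.
#'
#' @param cohort cohort data.frame with `subject_id`, `scan_id`,
#'   `scan_date`, `group`.
#' @return data.frame with one row per scan in a session: `session_id`,
#'   `subject_id`, `scan_id`, `scan_date`, ordered by date (ties by
#'   scan_id) within session.
#' @export
buildSessions <- function(cohort) {
  stopifnot(all(c("subject_id", "scan_id", "scan_date", "group") %in%
                  names(cohort)))
  cohort <- cohort[order(cohort$subject_id, cohort$scan_date,
                         cohort$scan_id), ]
  rows <- list()
  sid <- 0L
  for (subj in unique(cohort$subject_id)) {
    sc <- cohort[cohort$subject_id == subj, ]
    if (nrow(sc) < 2L) next
    is_hc <- sc$group[1] == "HC"
    assigned <- rep(FALSE, nrow(sc))
    while (any(!assigned)) {
      anchor <- which(!assigned)[1]
      in_sess <- if (is_hc) {
        !assigned & as.numeric(sc$scan_date - sc$scan_date[anchor]) <= 365
      } else {
        !assigned & sc$scan_date == sc$scan_date[anchor]
      }
      assigned[in_sess] <- TRUE
      if (sum(in_sess) >= 2L) {
        sid <- sid + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          session_id = sprintf("S%03d", sid), subject_id = subj,
          scan_id = sc$scan_id[in_sess], scan_date = sc$scan_date[in_sess])
      }
    }
  }
  if (!length(rows))
    return(data.frame(session_id = character(), subject_id = character(),
                      scan_id = character(),
                      scan_date = as.Date(character())))
  do.call(rbind, rows)
}

.session_values <- function(sessions, values) {
  if (is.null(names(values))) stop("values must be named by scan_id")
  v <- values[sessions$scan_id]
  if (anyNA(v)) stop("missing metric value for some session scans")
  split(unname(v), sessions$session_id)
}

#' Session-wise mean absolute percentage error
#'
#' `MAPE = (100/N) * sum_i (1/n_i) * sum_t |m_it - mu_i| / mu_i`, where
#' `mu_i` is the within-session mean: each session contributes the mean
#' absolute deviation of its repeats from their own mean, relative to that
#' mean, and sessions are averaged with equal weight.
#'
#' @param sessions data.frame from [buildSessions()].
#' @param values named numeric vector of the metric, names = scan_id.
#' @return MAPE in percent.
#' @examples
#' s <- data.frame(session_id = c("a", "a", "b", "b"),
#'                 subject_id = "x", scan_id = as.character(1:4),
#'                 scan_date = Sys.Date())
#' mapeSessions(s, c("1" = 100, "2" = 110, "3" = 200, "4" = 200)) # 2.381
#' @export
mapeSessions <- function(sessions, values) {
  per <- sessionErrors(sessions, values)
  100 * mean(per)
}

#' Per-session mean absolute relative deviations
#'
#' The inner term of the session-wise MAPE, one value per session (as a
#' fraction, not percent); this is the session-level statistic the paired
#' method comparison operates on.
#'
#' @inheritParams mapeSessions
#' @return Named numeric vector, one entry per session.
#' @export
sessionErrors <- function(sessions, values) {
  groups <- .session_values(sessions, values)
  vapply(groups, function(m) {
    mu <- mean(m)
    if (mu == 0) stop("within-session mean is zero")
    mean(abs(m - mu)) / abs(mu)
  }, numeric(1))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Uses the first two scans of every session (earliest by date, ties by
#' scan_id). From the two-way ANOVA over n sessions x k = 2 occasions:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))` with MSR,
#' MSC, MSE the between-session, between-occasion and residual mean
#' squares.
#'
#' @inheritParams mapeSessions
#' @return ICC estimate (dimensionless).
#' @export
icc21 <- function(sessions, values) {
  groups <- .session_values(sessions, values)
  M <- t(vapply(groups, function(m) m[1:2], numeric(2)))
  icc21Matrix(M)
}

#' ICC(2,1) from an n x k measurement matrix
#'
#' @param M numeric matrix, rows = sessions (subjects), columns = repeated
#'   occasions.
#' @return ICC(2,1) estimate.
#' @export
icc21Matrix <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L) stop("need >= 2 sessions and >= 2 occasions")
  if (anyNA(M)) stop("missing values in measurement matrix")
  grand <- mean(M)
  rm_ <- rowMeans(M)
  cm_ <- colMeans(M)
  if (var(as.vector(M)) == 0) stop("zero total variance")
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- sweep(sweep(M, 1, rm_), 2, cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Paired comparison of per-session errors between methods
#'
#' Two-sided paired t-tests on the session-level mean absolute relative
#' deviations (see [sessionErrors()]) for every pair of methods. Sessions
#' must be aligned across methods. If the paired differences have zero
#' variance the p-value is 1 when they are all zero and 0 otherwise
#' (degenerate case, flagged by convention).
#'
#' @param errors named list: method -> numeric vector of per-session
#'   errors, all the same length and session order.
#' @return data.frame with `method_a`, `method_b`, `mean_diff`, `p_value`.
#' @export
compareMethodsPaired <- function(errors) {
  stopifnot(is.list(errors), length(errors) >= 2L)
  lens <- lengths(errors)
  if (length(unique(lens)) != 1L) stop("error vectors must be aligned")
  if (lens[1] < 3L) stop("need at least 3 sessions")
  methods <- names(errors)
  out <- list()
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    if (i >= j) next
    d <- errors[[i]] - errors[[j]]
    p <- if (sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else t.test(errors[[i]], errors[[j]], paired = TRUE)$p.value
    out[[length(out) + 1L]] <- data.frame(
      method_a = methods[i], method_b = methods[j],
      mean_diff = mean(d), p_value = p)
  }
  do.call(rbind, out)
}

#' Robustness summary of a cohort metric
#'
#' Convenience wrapper: builds sessions and reports MAPE and ICC(2,1) for
#' each side-specific metric column.
#'
#' @param cohort cohort data.frame.
#' @param metrics metric column names, default all `_lh`/`_rh` pairs.
#' @return data.frame with `metric`, `mape`, `icc`, `n_sessions`.
#' @export
robustnessSummary <- function(cohort, metrics = NULL) {
  sessions <- buildSessions(cohort)
  if (is.null(metrics)) {
    base <- cohortMetrics(cohort)
    metrics <- as.vector(t(outer(base, c("_lh", "_rh"), paste0)))
  }
  n_sess <- length(unique(sessions$session_id))
  do.call(rbind, lapply(metrics, function(m) {
    vals <- setNames(cohort[[m]], cohort$scan_id)
    data.frame(metric = m, mape = mapeSessions(sessions, vals),
               icc = icc21(sessions, vals), n_sessions = n_sess)
  }))
}
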