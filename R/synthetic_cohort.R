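# Measurement-level synthetic cohort generator.
#
# Emulates the study conditions the pipeline was designed for: 406 healthy
# control MRIs from 354 subjects and 126 patient MRIs from 105 subjects
# (18 HS-left / 19 HS-right / 3 HS-bilateral / 86 all-other-epilepsies
# scans), a small negative HC mean volume AI (slightly larger right
# hippocampus), group AI shifts planted as standardized effect sizes,
# volumes depending linearly on eTIV and age, and 41 re-scan sessions
# (same-day for patients, within a year for controls) whose scans share a
# subject's latent values plus multiplicative measurement noise.

#' Configuration for the measurement-level cohort generator
#'
#' Defaults encode the emulated study conditions. `sizes` are MRI counts
#' per group and `subjects` the subject counts; the difference is realised
#' as repeat scans concentrated in `n_sessions` re-scan sessions (same-day
#' pairs for patients, 3-4 scans within a year for controls). Group AI
#' shifts are planted as standardized effects (multiples of the total AI
#' SD), so the population pooled-SD Cohen's d of a group against HC equals
#' the planted value. Measurement noise is multiplicative per side and
#' scan; the subject-level AI spread is shrunk so the *total* per-scan AI
#' SD equals `ai_sd` (resp. `sv_ai_sd`).
#'
#' @param sizes named MRI counts (HC, HS-left, HS-right, HS-bilateral,
#'   EPI-other).
#' @param subjects named subject counts per group.
#' @param n_sessions total number of re-scan sessions.
#' @param hc_mean_ai healthy-control mean volume AI (default -0.007).
#' @param ai_sd total SD of the volume AI per scan.
#' @param vol_ai_effects standardized volume-AI shifts per patient group.
#' @param sv_ai_mean,sv_ai_sd,sv_ai_effects the same for the
#'   surface-to-volume-ratio AI; the default shift of +/- 2.088 total SDs
#'   makes the population AUC of the absolute S/V AI for unilateral HS vs
#'   all-other-epilepsies equal 0.87 under the folded-Gaussian model.
#' @param volume_mean,volume_resid_sd bilateral mean hippocampal volume and
#'   residual SD, mm^3.
#' @param beta_etiv,beta_age volume slopes, mm^3 per population SD of the
#'   covariate.
#' @param sv_mean,sv_sd bilateral mean surface-to-volume ratio (1/mm) and
#'   SD.
#' @param bilateral_volume_factor,bilateral_sv_factor symmetric scaling of
#'   both sides in bilateral HS.
#' @param etiv_mean,etiv_sd,age_mean,age_sd covariate distributions.
#' @param rescan_noise_pct multiplicative measurement noise SD per side, in
#'   percent, named `volume` and `sv_ratio`.
#' @param seed integer seed (mandatory; the generator is a pure function of
#'   the config).
#' @return A list of class `cohortConfig`.
#' @export
cohortConfig <- function(
    sizes = c("HC" = 406L, "HS-left" = 18L, "HS-right" = 19L,
              "HS-bilateral" = 3L, "EPI-other" = 86L),
    subjects = c("HC" = 354L, "HS-left" = 13L, "HS-right" = 17L,
                 "HS-bilateral" = 1L, "EPI-other" = 74L),
    n_sessions = 41L,
    hc_mean_ai = -0.007, ai_sd = 0.02,
    vol_ai_effects = c("HS-left" = -4.165, "HS-right" = 4.203,
                       "HS-bilateral" = 0, "EPI-other" = 0),
    sv_ai_mean = 0, sv_ai_sd = 0.02,
    sv_ai_effects = c("HS-left" = 2.088, "HS-right" = -2.088,
                      "HS-bilateral" = 0, "EPI-other" = 0),
    volume_mean = 3500, volume_resid_sd = 250,
    beta_etiv = 200, beta_age = -150,
    sv_mean = 0.42, sv_sd = 0.03,
    bilateral_volume_factor = 0.8, bilateral_sv_factor = 1.15,
    etiv_mean = 1.5e6, etiv_sd = 1.5e5, age_mean = 33, age_sd = 12,
    rescan_noise_pct = c(volume = 2.0, sv_ratio = 0.7),
    seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (any(cfg$sizes < 0) || any(cfg$subjects < 0))
    stop("group sizes must be non-negative")
  if (any(cfg$subjects > cfg$sizes))
    stop("subject counts cannot exceed MRI counts")
  if (cfg$ai_sd <= 0 || cfg$sv_ai_sd <= 0) stop("AI SDs must be positive")
  for (m in c("volume", "sv_ratio")) {
    tot <- if (m == "volume") cfg$ai_sd else cfg$sv_ai_sd
    if (tot^2 <= (cfg$rescan_noise_pct[[m]] / 100)^2 / 2)
      stop("rescan noise too large for the requested AI SD (", m, ")")
  }
  class(cfg) <- "cohortConfig"
  cfg
}

# allocate extra scans to re-scan subjects: patients get same-day pairs
# (one subject may absorb several extras if the group has more extras than
# subjects), controls split their extras over the remaining sessions
.session_plan <- function(cfg) {
  plan <- list()
  patient_groups <- setdiff(names(cfg$sizes), "HC")
  n_pat_sessions <- 0L
  for (g in patient_groups) {
    extra <- cfg$sizes[[g]] - cfg$subjects[[g]]
    if (extra <= 0) next
    m <- min(cfg$subjects[[g]], extra)
    per <- rep(floor(extra / m), m)
    if (extra %% m) per[seq_len(extra %% m)] <- per[seq_len(extra %% m)] + 1L
    plan[[g]] <- per
    n_pat_sessions <- n_pat_sessions + m
  }
  extra_hc <- cfg$sizes[["HC"]] - cfg$subjects[["HC"]]
  n_hc_sessions <- max(cfg$n_sessions - n_pat_sessions, 0L)
  if (extra_hc > 0 && n_hc_sessions > 0) {
    per <- rep(floor(extra_hc / n_hc_sessions), n_hc_sessions)
    r <- extra_hc %% n_hc_sessions
    if (r) per[seq_len(r)] <- per[seq_len(r)] + 1L
    plan[["HC"]] <- per
  }
  plan
}

#' Generate a measurement-level synthetic cohort
#'
#' Draws one row per scan with left/right hippocampal volume and
#' surface-to-volume ratio such that (i) the HC volume AI is
#' Normal(`hc_mean_ai`, `ai_sd`), (ii) patient groups are shifted by the
#' planted standardized effects, (iii) volumes depend linearly on eTIV and
#' age, and (iv) re-scan sessions share latent values perturbed by
#' multiplicative noise. Deterministic given the config seed.
#'
#' @param config a [cohortConfig()].
#' @return data.frame with columns `subject_id`, `scan_id`, `scan_date`,
#'   `group`, `age`, `etiv`, `volume_lh`, `volume_rh`, `sv_ratio_lh`,
#'   `sv_ratio_rh`.
#' @export
generateMeasurementCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  cfg <- config
  withr::with_seed(as.integer(cfg$seed), {
    plan <- .session_plan(cfg)
    prefix <- c("HC" = "HC", "HS-left" = "HSL", "HS-right" = "HSR",
                "HS-bilateral" = "HSB", "EPI-other" = "EPI")
    noise_vol <- cfg$rescan_noise_pct[["volume"]] / 100
    noise_sv <- cfg$rescan_noise_pct[["sv_ratio"]] / 100
    subj_ai_sd <- sqrt(cfg$ai_sd^2 - noise_vol^2 / 2)
    subj_sv_ai_sd <- sqrt(cfg$sv_ai_sd^2 - noise_sv^2 / 2)
    n_total <- sum(cfg$sizes)
    col_subject <- col_scan <- col_group <- character(n_total)
    col_date <- rep(as.Date("2015-01-01"), n_total)
    col_age <- col_etiv <- col_vlh <- col_vrh <- col_slh <- col_srh <-
      numeric(n_total)
    row <- 0L
    for (g in names(cfg$sizes)) {
      n_sub <- cfg$subjects[[g]]
      if (n_sub == 0) next
      extras <- plan[[g]]
      n_scans_per <- rep(1L, n_sub)
      if (!is.null(extras))
        n_scans_per[seq_along(extras)] <- 1L + extras
      mu_ai <- cfg$hc_mean_ai +
        (if (g == "HC") 0 else cfg$vol_ai_effects[[g]]) * cfg$ai_sd
      mu_sv_ai <- cfg$sv_ai_mean +
        (if (g == "HC") 0 else cfg$sv_ai_effects[[g]]) * cfg$sv_ai_sd
      vol_factor <- if (g == "HS-bilateral") cfg$bilateral_volume_factor else 1
      sv_factor <- if (g == "HS-bilateral") cfg$bilateral_sv_factor else 1
      for (i in seq_len(n_sub)) {
        age <- min(max(rnorm(1, cfg$age_mean, cfg$age_sd), 7), 90)
        etiv <- max(rnorm(1, cfg$etiv_mean, cfg$etiv_sd), 0.5 * cfg$etiv_mean)
        z_et <- (etiv - cfg$etiv_mean) / cfg$etiv_sd
        z_ag <- (age - cfg$age_mean) / cfg$age_sd
        v_base <- max(cfg$volume_mean + cfg$beta_etiv * z_et +
                        cfg$beta_age * z_ag +
                        rnorm(1, 0, cfg$volume_resid_sd), 500) * vol_factor
        ai <- rnorm(1, mu_ai, subj_ai_sd)
        sv_base <- max(rnorm(1, cfg$sv_mean, cfg$sv_sd), 0.05) * sv_factor
        sv_ai <- rnorm(1, mu_sv_ai, subj_sv_ai_sd)
        lh_v <- v_base * (1 + ai); rh_v <- v_base * (1 - ai)
        lh_s <- sv_base * (1 + sv_ai); rh_s <- sv_base * (1 - sv_ai)
        n_scans <- n_scans_per[i]
        base_date <- as.Date("2015-01-01") + sample.int(1500, 1)
        dates <- if (n_scans == 1L) base_date
          else if (g == "HC")
            base_date + c(0, sort(sample.int(300, n_scans - 1L)))
          else rep(base_date, n_scans)
        subj <- sprintf("%s%04d", prefix[[g]], i)
        idx <- row + seq_len(n_scans)
        row <- row + n_scans
        eps <- matrix(rnorm(4L * n_scans), ncol = 4)
        col_subject[idx] <- subj
        col_scan[idx] <- sprintf("%s_t%02d", subj, seq_len(n_scans))
        col_date[idx] <- dates
        col_group[idx] <- g
        col_age[idx] <- age
        col_etiv[idx] <- etiv
        col_vlh[idx] <- lh_v * (1 + noise_vol * eps[, 1])
        col_vrh[idx] <- rh_v * (1 + noise_vol * eps[, 2])
        col_slh[idx] <- lh_s * (1 + noise_sv * eps[, 3])
        col_srh[idx] <- rh_s * (1 + noise_sv * eps[, 4])
      }
    }
    data.frame(subject_id = col_subject, scan_id = col_scan,
               scan_date = col_date,
               group = factor(col_group, levels = .group_levels),
               age = col_age, etiv = col_etiv,
               volume_lh = col_vlh, volume_rh = col_vrh,
               sv_ratio_lh = col_slh, sv_ratio_rh = col_srh)
  })
}
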