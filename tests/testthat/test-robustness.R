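# sessions, MAPE, ICC(2,1), paired method comparison

toy_sessions <- function(values_by_session) {
  n <- lengths(values_by_session)
  data.frame(session_id = rep(names(values_by_session), n),
             subject_id = rep(names(values_by_session), n),
             scan_id = sprintf("scan%02d", seq_len(sum(n))),
             scan_date = as.Date("2020-01-01") + seq_len(sum(n)))
}

values_of <- function(sessions, values_by_session)
  setNames(unlist(values_by_session, use.names = FALSE), sessions$scan_id)

test_that("session building follows the patient and control rules", {
  co <- data.frame(
    subject_id = c("p1", "p1", "p1", "h1", "h1", "h1", "s1"),
    scan_id = sprintf("x%d", 1:7),
    scan_date = as.Date("2020-01-01") +
      c(0, 0, 30, 0, 200, 400, 0),
    group = c("HS-left", "HS-left", "HS-left", "HC", "HC", "HC", "HC"))
  s <- buildSessions(co)
  # patient: the two same-day scans form one session; day-30 scan is alone
  p_sess <- s[s$subject_id == "p1", ]
  expect_equal(length(unique(p_sess$session_id)), 1)
  expect_setequal(p_sess$scan_id, c("x1", "x2"))
  # HC: greedy chaining anchored at day 0 absorbs day 200 but not day 400
  h_sess <- s[s$subject_id == "h1", ]
  expect_equal(length(unique(h_sess$session_id)), 1)
  expect_setequal(h_sess$scan_id, c("x4", "x5"))
  # single-scan subject yields no session
  expect_false("s1" %in% s$subject_id)
})

test_that("MAPE reproduces the worked session examples exactly", {
  vs <- list(a = c(100, 110), b = c(200, 200))
  s <- toy_sessions(vs)
  v <- values_of(s, vs)
  expect_equal(mapeSessions(toy_sessions(vs["a"]), v[1:2]),
               100 * 10 / (2 * 105), tolerance = 1e-12)
  expect_equal(mapeSessions(s, v), (100 * 10 / (2 * 105) + 0) / 2,
               tolerance = 1e-12)
  expect_equal(mapeSessions(s, v), 2.380952, tolerance = 1e-6)
  # identical repeats give exactly zero
  vz <- list(a = c(5, 5, 5), b = c(9, 9))
  sz <- toy_sessions(vz)
  expect_equal(mapeSessions(sz, values_of(sz, vz)), 0)
  # scale invariance
  expect_equal(mapeSessions(s, 3.7 * v), mapeSessions(s, v))
  expect_error(mapeSessions(s, v * 0), "zero")
})

test_that("ICC(2,1) matches the independent ANOVA oracle", {
  M <- matrix(c(7, 5, 9, 3, 8, 5, 10, 3), ncol = 2)
  expect_equal(icc21Matrix(M), icc21_aov_oracle(M), tolerance = 1e-12)
  # perfect agreement
  expect_equal(icc21Matrix(cbind(c(1, 5, 9), c(1, 5, 9))), 1)
  expect_error(icc21Matrix(matrix(2, 3, 2)), "variance")
  for (case in 1:40) {
    withr::with_seed(case, {
      n <- sample(3:12, 1)
      M <- matrix(rnorm(2 * n, mean = rep(rnorm(n, sd = 2), 2)), ncol = 2)
    })
    expect_equal(icc21Matrix(M), icc21_aov_oracle(M), tolerance = 1e-10)
  }
})

test_that("ICC via sessions uses the first two scans by date", {
  vs <- list(a = c(7, 8, 99), b = c(5, 5), c = c(9, 10), d = c(3, 3))
  s <- toy_sessions(vs)
  v <- values_of(s, vs)
  M <- matrix(c(7, 5, 9, 3, 8, 5, 10, 3), ncol = 2)
  expect_equal(icc21(s, v), icc21Matrix(M), tolerance = 1e-12)
})

test_that("planted variance components are recovered by ICC(2,1)", {
  withr::with_seed(33, {
    n <- 2000
    b <- rnorm(n, 0, 3)                    # between-session SD 3
    M <- cbind(b + rnorm(n), b + rnorm(n)) # error SD 1 => ICC = 0.9
  })
  expect_equal(icc21Matrix(M), 0.9, tolerance = 0.02)
  # unbiasedness at study scale: n = 41, k = 2, planted ICC 0.5 and 0.9
  for (rho in c(0.5, 0.9)) {
    sigma_b <- sqrt(rho / (1 - rho))
    est <- sapply(1:200, function(s) {
      withr::with_seed(1000 * rho + s, {
        b <- rnorm(41, 0, sigma_b)
        icc21Matrix(cbind(b + rnorm(41), b + rnorm(41)))
      })
    })
    expect_lt(abs(mean(est) - rho), 0.05)
  }
})

test_that("paired method comparison behaves across degenerate cases", {
  withr::with_seed(21, e1 <- runif(41, 0.01, 0.03))
  # identical error vectors: p = 1 by convention
  expect_equal(compareMethodsPaired(list(a = e1, b = e1))$p_value, 1)
  # constant offset with tiny noise is highly significant
  withr::with_seed(22, e2 <- e1 + 1 + rnorm(41, 0, 1e-4))
  res <- compareMethodsPaired(list(a = e1, b = e2))
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mean_diff, -mean(e2 - e1), tolerance = 1e-12)
  # permuting sessions of both methods together leaves p unchanged
  perm <- withr::with_seed(23, sample.int(41))
  res2 <- compareMethodsPaired(list(a = e1[perm], b = e2[perm]))
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  expect_error(compareMethodsPaired(list(a = e1, b = e2[1:10])), "aligned")
})

test_that("the cohort robustness summary covers all paired metrics", {
  co <- generateMeasurementCohort(cohortConfig(seed = 3))
  rb <- robustnessSummary(co)
  expect_setequal(rb$metric, c("volume_lh", "volume_rh", "sv_ratio_lh",
                               "sv_ratio_rh"))
  expect_true(all(rb$mape >= 0))
  expect_true(all(rb$icc > 0.5))
  expect_equal(unique(rb$n_sessions), 41)
})
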