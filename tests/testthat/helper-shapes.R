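# fixture builders: all fixtures are generated in code

# centred coordinate arrays for a grid of n voxels per axis
coord_arrays <- function(n) {
  g <- lapply(n, function(k) seq_len(k) - 1 - (k - 1) / 2)
  list(X = array(g[[1]], n),
       Y = array(rep(g[[2]], each = n[1]), n),
       Z = array(rep(g[[3]], each = n[1] * n[2]), n))
}

ball_mask <- function(r, spacing = c(1, 1, 1), margin = 2) {
  n <- 2 * ceiling(r / spacing) + 2 * margin + 1
  cc <- coord_arrays(n)
  m <- (cc$X * spacing[1])^2 + (cc$Y * spacing[2])^2 +
    (cc$Z * spacing[3])^2 <= r^2
  BinaryMask(m, spacing = spacing)
}

ellipsoid_mask <- function(semi, spacing = c(1, 1, 1), margin = 2) {
  n <- 2 * ceiling(semi / spacing) + 2 * margin + 1
  cc <- coord_arrays(n)
  m <- (cc$X * spacing[1] / semi[1])^2 + (cc$Y * spacing[2] / semi[2])^2 +
    (cc$Z * spacing[3] / semi[3])^2 <= 1
  BinaryMask(m, spacing = spacing)
}

single_voxel_mask <- function(spacing = c(1, 1, 1)) {
  m <- array(FALSE, c(3, 3, 3))
  m[2, 2, 2] <- TRUE
  BinaryMask(m, spacing = spacing)
}

# orientation oracle: signed enclosed volume without the abs()
signed_mesh_volume <- function(mesh) {
  V <- meshVertices(mesh)
  F <- meshFaces(mesh)
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# brute-force AUC oracle: explicit pair counting with 0.5 for ties
auc_pair_counting <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# independent ICC(2,1) oracle: mean squares from aov(), then the
# two-way random-effects absolute-agreement formula
icc21_aov_oracle <- function(M) {
  n <- nrow(M); k <- ncol(M)
  d <- data.frame(y = as.vector(M),
                  row = factor(rep(seq_len(n), k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# minimal valid cohort data.frame for IO / model tests
make_cohort_df <- function(n_hc = 40, seed = 1) {
  withr::with_seed(seed, {
    age <- runif(n_hc, 20, 60)
    etiv <- rnorm(n_hc, 1.5e6, 1.5e5)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n_hc)),
      scan_id = sprintf("S%03d_t01", seq_len(n_hc)),
      scan_date = as.Date("2020-01-01") + seq_len(n_hc),
      group = "HC", age = age, etiv = etiv,
      volume_lh = rnorm(n_hc, 3400, 300),
      volume_rh = rnorm(n_hc, 3450, 300))
  })
}
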