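# Feature ranking with a repeated, patient-stratified, cross-validated
# linear SVM: identifies which of the 14 shape-feature asymmetry indices
# best separates unilateral HS from all other epilepsies. The classifier
# is used only to rank features, never as the diagnostic itself.

.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

# patient-level folds: all scans of one subject stay in one fold
.patient_folds <- function(subjects, n_folds, seed) {
  ids <- unique(subjects)
  ids <- ids[withr::with_seed(seed, sample.int(length(ids)))]
  fold_of <- rep(seq_len(n_folds), length.out = length(ids))
  setNames(fold_of, ids)[as.character(subjects)]
}

#' Rank shape features with a repeated cross-validated linear SVM
#'
#' For each of `n_repeats` x `n_folds` runs, fits a linear soft-margin SVM
#' (cost C = 1, the conventional default) on the training folds after
#' within-fold standardization, takes the absolute primal weights
#' normalized to sum 1 as the run's feature importances, and averages over
#' all runs. Folds are stratified by patient: all scans of a subject stay
#' in one fold. If a training fold misses a class the repeat's folds are
#' re-drawn with a derived seed. Deterministic given `seed`.
#'
#' @param features numeric matrix or data.frame, one row per scan, one
#'   column per feature (typically the AI of each of the 14 shape
#'   features).
#' @param labels logical or coercible, `TRUE` for HS scans.
#' @param subjects subject ID per scan (defines the stratification).
#' @param n_folds,n_repeats cross-validation protocol; defaults 5 and 20.
#' @param seed integer seed; same seed gives a bit-identical ranking.
#' @return List with `importance` (named, sums to 1), `rank` (named
#'   permutation of `1:ncol`), `table` (data.frame feature/importance/
#'   rank), `n_folds`, `n_repeats`.
#' @export
rankShapeFeatures <- function(features, labels, subjects, n_folds = 5L,
                              n_repeats = 20L, seed = 1L) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  subjects <- as.character(subjects)
  stopifnot(nrow(X) == length(y), nrow(X) == length(subjects))
  for (cl in levels(y))
    if (length(unique(subjects[y == cl])) < 2L)
      stop("need at least 2 patients per class")
  p <- ncol(X)
  total <- matrix(0, nrow = 0, ncol = p)
  for (rep_i in seq_len(n_repeats)) {
    draw <- 0L
    repeat {
      fold <- .patient_folds(subjects, n_folds,
                             .derive_seed(seed, rep_i * 100L + draw))
      ok <- all(vapply(seq_len(n_folds), function(f)
        length(unique(y[fold != f])) == 2L, logical(1)))
      if (ok) break
      draw <- draw + 1L
      if (draw > 50L) stop("could not draw folds with both classes present")
    }
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      mu <- colMeans(Xtr)
      sds <- apply(Xtr, 2, sd)
      sds[sds == 0] <- 1
      Xs <- scale(Xtr, center = mu, scale = sds)
      fit <- e1071::svm(Xs, y[tr], kernel = "linear", cost = 1,
                        scale = FALSE)
      w <- abs(as.vector(t(fit$coefs) %*% fit$SV))
      total <- rbind(total, w / sum(w))
    }
  }
  imp <- colMeans(total)
  names(imp) <- colnames(X)
  rk <- setNames(rank(-imp, ties.method = "first"), colnames(X))
  list(importance = imp, rank = rk,
       table = data.frame(feature = colnames(X),
                          importance = unname(imp),
                          rank = unname(rk))[order(rk), ],
       n_folds = n_folds, n_repeats = n_repeats)
}
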