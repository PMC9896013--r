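#' Affine-invariant geodesic distance between SPD matrices
#'
#' The Riemannian distance on the SPD cone,
#' \deqn{d(C_1, C_2) = \sqrt{\sum_i \log^2 \lambda_i},}
#' with \eqn{\lambda_i} the eigenvalues of
#' \eqn{C_1^{-1/2} C_2 C_1^{-1/2}}. Symmetric in its arguments, zero iff the
#' matrices are equal, and invariant under congruence
#' \eqn{C \mapsto A C A^\top} for any invertible `A`. Correlation matrices
#' can be near-singular, so `regularize = TRUE` adds the identity to both
#' matrices before the computation (the convention used for identification).
#'
#' @param c1,c2 SPD matrices (or [new_fc_matrix()] objects) of equal
#'   dimension.
#' @param regularize add `I` to both matrices first (default `FALSE`).
#' @param squared return the squared distance
#'   (`trace(log^2(C1^{-1/2} C2 C1^{-1/2}))`) instead of its square root.
#'   Predictions are unaffected since the square is monotone.
#' @return non-negative scalar.
#' @export
geodesic_distance <- function(c1, c2, regularize = FALSE, squared = FALSE) {
  m1 <- if (inherits(c1, "fc_matrix")) c1$values else c1
  m2 <- if (inherits(c2, "fc_matrix")) c2$values else c2
  if (!all(dim(m1) == dim(m2)))
    stop_invalid("matrices must have equal dimension")
  if (regularize) {
    m1 <- m1 + diag(nrow(m1))
    m2 <- m2 + diag(nrow(m2))
  }
  ch <- tryCatch(chol(m1), error = function(e) NULL)
  if (is.null(ch))
    stop_invalid("first matrix is not positive definite",
                 if (!regularize) " (consider regularize = TRUE)" else "")
  # with C1 = R'R (chol), eig(C1^{-1/2} C2 C1^{-1/2}) = eig(R^{-T} C2 R^{-1})
  a <- forwardsolve(t(ch), m2)        # R^{-T} C2
  w <- forwardsolve(t(ch), t(a))      # R^{-T} C2' R^{-1} = R^{-T} C2 R^{-1}
  w <- (w + t(w)) / 2
  lam <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam <= 0))
    stop_invalid("second matrix is not positive definite",
                 if (!regularize) " (consider regularize = TRUE)" else "")
  d2 <- sum(log(lam)^2)
  if (squared) d2 else sqrt(d2)
}

as_fc_values <- function(x) {
  if (inherits(x, "fc_matrix")) x$values else x
}

as_feature_vector <- function(x) {
  if (is.matrix(x) || inherits(x, "fc_matrix")) vectorize_upper(x)
  else as.numeric(x)
}

#' Aggregate a subject's training FC matrices
#'
#' Pairwise matchers (`pearson`, `geodesic`) compare the test matrix with
#' the elementwise mean of the training matrices (diagonal reset to 1); the
#' linear classifier uses every training matrix as an independent sample, so
#' aggregation is a pass-through.
#'
#' @param fcs list of [new_fc_matrix()] objects (or matrices / feature
#'   vectors) for one subject.
#' @param method `"pearson"`, `"geodesic"` or `"linear"`.
#' @return mean matrix (or mean feature vector) for the pairwise methods;
#'   the input list for `"linear"`.
#' @export
aggregate_training <- function(fcs, method = c("pearson", "geodesic",
                                               "linear")) {
  method <- match.arg(method)
  stopifnot(length(fcs) >= 1)
  if (method == "linear") return(fcs)
  first <- fcs[[1]]
  if (is.numeric(first) && !is.matrix(first)) {
    return(rowMeans(do.call(cbind, lapply(fcs, as.numeric))))
  }
  mats <- lapply(fcs, as_fc_values)
  m <- Reduce(`+`, mats) / length(mats)
  diag(m) <- 1
  m
}

# --- train/test resampling -------------------------------------------------

#' Draw one leave-one-out train/test split
#'
#' For every subject: one run is drawn as the test sample, then
#' `n_train_runs` of the remaining runs (all of them for `"all"`) are drawn
#' without replacement as training samples.
#'
#' @param fcs list per subject of per-run objects
#'   (`fcs[[subject]][[run]]`).
#' @param n_train_runs integer >= 1 or `"all"`.
#' @param seed RNG seed for this split.
#' @return list of class `train_test_split` with `test` (one object per
#'   subject) and `train` (list of objects per subject).
#' @export
sample_split <- function(fcs, n_train_runs = 1, seed = 1L) {
  subjects <- names(fcs)
  if (is.null(subjects)) subjects <- sprintf("s%02d", seq_along(fcs))
  n_runs <- vapply(fcs, length, integer(1))
  need <- if (identical(n_train_runs, "all")) 2L else n_train_runs + 1L
  short <- subjects[n_runs < need]
  if (length(short))
    stop_invalid("insufficient runs for subject(s): ",
                 paste(short, collapse = ", "))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  test <- vector("list", length(fcs))
  train <- vector("list", length(fcs))
  for (i in seq_along(fcs)) {
    k <- length(fcs[[i]])
    t_idx <- sample.int(k, 1L)
    rest <- setdiff(seq_len(k), t_idx)
    tr_idx <- if (identical(n_train_runs, "all")) rest else
      rest[sample.int(length(rest), n_train_runs)]
    test[[i]] <- fcs[[i]][[t_idx]]
    train[[i]] <- fcs[[i]][tr_idx]
  }
  names(test) <- subjects
  names(train) <- subjects
  structure(list(test = test, train = train, seed = seed),
            class = "train_test_split")
}

finalize_labels <- function(scores, subjects, maximize = TRUE) {
  # scores: n_test x n_subjects; deterministic lowest-index winner on ties,
  # detected with a relative tolerance so that numerically degenerate
  # scores (e.g. the infinite-shrinkage limit) are flagged
  if (!maximize) scores <- -scores
  pred <- integer(nrow(scores))
  ties <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    r <- scores[i, ]
    tol <- 1e-9 * max(1, max(abs(r[is.finite(r)]), 0))
    winners <- which(r >= max(r) - tol)
    pred[i] <- winners[1L]
    ties[i] <- length(winners) > 1L
  }
  out <- subjects[pred]
  attr(out, "ties") <- ties
  out
}

#' Identify subjects by Pearson matching of vectorized FC
#'
#' Each test matrix's upper-triangle vector is correlated with every
#' subject's aggregated (mean) training vector; the highest correlation
#' wins. Ties go to the lowest subject index and are flagged in the `"ties"`
#' attribute; zero-variance vectors score `-Inf`.
#'
#' @param split a [sample_split()].
#' @return character vector of predicted labels, one per test subject.
#' @export
identify_pearson <- function(split) {
  subjects <- names(split$train)
  refs <- vapply(subjects, function(s)
    aggregate_training(lapply(split$train[[s]], as_feature_vector),
                       "pearson"),
    numeric(length(as_feature_vector(split$test[[1]]))))
  tests <- vapply(split$test, as_feature_vector, numeric(nrow(refs)))
  ok_ref <- apply(refs, 2L, stats::sd) > 0
  ok_test <- apply(tests, 2L, stats::sd) > 0
  scores <- matrix(-Inf, ncol(tests), ncol(refs))
  if (any(ok_ref) && any(ok_test))
    scores[ok_test, ok_ref] <-
      stats::cor(tests[, ok_test, drop = FALSE],
                 refs[, ok_ref, drop = FALSE])
  finalize_labels(scores, subjects, maximize = TRUE)
}

#' Identify subjects by geodesic distance
#'
#' Argmin of the affine-invariant geodesic distance (computed with `+I`
#' regularization by default) between each test matrix and every subject's
#' mean training matrix. The squared distance gives identical predictions
#' (monotone transform).
#'
#' @param split a [sample_split()] whose objects are FC (or block-diagonal)
#'   matrices.
#' @param regularize,squared passed to [geodesic_distance()].
#' @return character vector of predicted labels with a `"ties"` attribute.
#' @export
identify_geodesic <- function(split, regularize = TRUE, squared = FALSE) {
  subjects <- names(split$train)
  refs <- lapply(subjects, function(s)
    aggregate_training(split$train[[s]], "geodesic"))
  tests <- lapply(split$test, as_fc_values)
  scores <- matrix(NA_real_, length(tests), length(refs))
  for (i in seq_along(tests))
    for (j in seq_along(refs))
      scores[i, j] <- geodesic_distance(refs[[j]], tests[[i]],
                                        regularize = regularize,
                                        squared = squared)
  finalize_labels(scores, subjects, maximize = FALSE)
}

#' Ridge linear classifier over vectorized FC matrices
#'
#' One-hot subject targets regressed on bias-augmented feature vectors with
#' an L2 penalty; closed-form solution (the dual form is used automatically
#' when there are fewer samples than features). Prediction takes the argmax
#' of the linear outputs.
#'
#' @param features numeric matrix, samples x features (or list of FC
#'   matrices / vectors).
#' @param labels subject label per sample.
#' @param ridge_lambda penalty (>= 0, default 1).
#' @return object of class `linear_classifier` with fields `weights`
#'   (features+1 x classes, bias last), `classes`, `ridge_lambda`.
#' @export
train_linear_classifier <- function(features, labels, ridge_lambda = 1) {
  if (ridge_lambda < 0) stop_invalid("`ridge_lambda` must be >= 0")
  if (is.list(features))
    features <- do.call(rbind, lapply(features, as_feature_vector))
  stopifnot(nrow(features) == length(labels))
  classes <- unique(labels)
  y <- outer(labels, classes, `==`) * 1
  x <- cbind(features, 1)
  n <- nrow(x)
  d <- ncol(x)
  w <- if (n < d) {
    crossprod(x, solve(tcrossprod(x) + ridge_lambda * diag(n), y))
  } else {
    solve(crossprod(x) + ridge_lambda * diag(d), crossprod(x, y))
  }
  structure(list(weights = w, classes = classes,
                 ridge_lambda = ridge_lambda),
            class = "linear_classifier")
}

#' @rdname train_linear_classifier
#' @param object a fitted `linear_classifier`.
#' @param newdata samples x features matrix (or list of FC objects).
#' @param ... unused.
#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  if (is.list(newdata))
    newdata <- do.call(rbind, lapply(newdata, as_feature_vector))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  scores <- cbind(newdata, 1) %*% object$weights
  finalize_labels(scores, object$classes, maximize = TRUE)
}

identify_linear <- function(split, ridge_lambda = 1) {
  subjects <- names(split$train)
  feats <- list()
  labs <- character(0)
  for (s in subjects) {
    feats <- c(feats, split$train[[s]])
    labs <- c(labs, rep(s, length(split$train[[s]])))
  }
  model <- train_linear_classifier(feats, labs, ridge_lambda)
  pred <- predict(model, split$test)
  # report in canonical subject order (classes follow training order here)
  pred
}

#' Combine several contrasts into one representation
#'
#' For vector-based methods (`pearson`, `linear`) the upper-triangle vectors
#' of the per-contrast FC matrices are concatenated (length
#' `k N (N - 1) / 2`). For the geodesic method the matrices are stacked
#' along the main diagonal into a block-diagonal `kN x kN` matrix, whose
#' spectrum is the union of the blocks' spectra — so it stays SPD and the
#' geodesic distance decomposes blockwise.
#'
#' @param fcs_by_contrast named list: contrast ->
#'   `fcs[[subject]][[run]]` ([new_fc_matrix()] objects).
#' @param method `"pearson"`, `"linear"` or `"geodesic"`.
#' @return list per subject of per-run combined objects (vectors or
#'   block-diagonal matrices).
#' @export
combine_contrasts <- function(fcs_by_contrast,
                              method = c("pearson", "geodesic", "linear")) {
  method <- match.arg(method)
  stopifnot(length(fcs_by_contrast) >= 1)
  dims <- lapply(fcs_by_contrast, function(f) dim(f[[1]][[1]]))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop_invalid("all contrasts must share dimension")
  subjects <- names(fcs_by_contrast[[1]])
  out <- lapply(subjects, function(s) {
    n_runs <- length(fcs_by_contrast[[1]][[s]])
    lapply(seq_len(n_runs), function(r) {
      pieces <- lapply(fcs_by_contrast, function(f) f[[s]][[r]])
      if (method == "geodesic")
        block_diag(lapply(pieces, as_fc_values))
      else
        unlist(lapply(pieces, vectorize_upper), use.names = FALSE)
    })
  })
  names(out) <- subjects
  out
}

#' Leave-one-out identification experiment
#'
#' Repeats the resampling protocol: per repetition, draw one test run and
#' `n_train_runs` training runs per subject (without overlap; `"all"` uses
#' every remaining run), classify every subject with each requested method,
#' and record `accuracy = 100 * correct / attempts`. Repetition seeds derive
#' from `seed` by counter, so a fixed seed gives an identical accuracy
#' sequence, and all methods passed in one call share the same draws.
#'
#' @param fcs `fcs[[subject]][[run]]` — [new_fc_matrix()] objects or
#'   combined representations from [combine_contrasts()].
#' @param methods subset of `"pearson"`, `"geodesic"`, `"linear"`.
#' @param n_train_runs integer >= 1 or `"all"`.
#' @param n_reps repetitions (default 300).
#' @param seed experiment seed.
#' @param ridge_lambda penalty for the linear method.
#' @return a single `id_result` (one method) or a named list of them:
#'   each has `method`, `accuracies` (percent, length `n_reps`),
#'   `predictions` (reps x subjects), `truth`, `tie_rate`.
#' @export
run_identification_experiment <- function(fcs, methods = "pearson",
                                          n_train_runs = 1, n_reps = 300,
                                          seed = 1L, ridge_lambda = 1) {
  methods <- match.arg(methods, c("pearson", "geodesic", "linear"),
                       several.ok = TRUE)
  subjects <- names(fcs)
  if (is.null(subjects)) {
    subjects <- sprintf("s%02d", seq_along(fcs))
    names(fcs) <- subjects
  }
  acc <- matrix(NA_real_, n_reps, length(methods),
                dimnames = list(NULL, methods))
  preds <- lapply(methods, function(m)
    matrix(NA_character_, n_reps, length(subjects)))
  names(preds) <- methods
  ties <- stats::setNames(numeric(length(methods)), methods)
  for (rep_i in seq_len(n_reps)) {
    split <- sample_split(fcs, n_train_runs, split_seed(seed, rep_i))
    for (m in methods) {
      p <- switch(m,
                  pearson = identify_pearson(split),
                  geodesic = identify_geodesic(split),
                  linear = identify_linear(split, ridge_lambda))
      acc[rep_i, m] <- 100 * mean(p == subjects)
      preds[[m]][rep_i, ] <- p
      ties[m] <- ties[m] + mean(attr(p, "ties"))
    }
  }
  results <- lapply(methods, function(m)
    structure(list(method = m, accuracies = acc[, m],
                   predictions = preds[[m]], truth = subjects,
                   n_repetitions = n_reps, tie_rate = ties[[m]] / n_reps,
                   n_train_runs = n_train_runs, seed = seed),
              class = "id_result"))
  names(results) <- methods
  if (length(results) == 1L) results[[1]] else results
}

#' @export
print.id_result <- function(x, ...) {
  cat(sprintf(
    "<id_result> %s, %s training run(s): accuracy %.1f (sd %.1f)%% over %d repetitions\n",
    x$method, as.character(x$n_train_runs), mean(x$accuracies),
    stats::sd(x$accuracies), x$n_repetitions))
  invisible(x)
}

#' Accuracy as a function of ROI-subset size
#'
#' For each requested size, draws random channel/ROI subsets (`n_roi_draws`
#' of them; a single draw when the size equals the full dimension), restricts
#' every FC matrix to the subset, and runs the 1-train/1-test identification
#' experiment. Mirrors the spatial-information analysis of the saturation
#' model.
#'
#' @param fcs `fcs[[subject]][[run]]` [new_fc_matrix()] objects.
#' @param sizes ROI counts (default `c(10, 20, 30, 40, 48)`).
#' @param n_roi_draws subset draws per size (default 10).
#' @param method identification method (default `"geodesic"`).
#' @param n_reps repetitions per draw (default 300).
#' @param seed experiment seed.
#' @param n_train_runs training runs (default 1).
#' @return data frame with one row per size: `size`, `mean_accuracy`,
#'   `sd_accuracy`, `n_draws`; per-draw means in attribute `"draw_means"`.
#' @export
roi_subsample_experiment <- function(fcs, sizes = c(10, 20, 30, 40, 48),
                                     n_roi_draws = 10, method = "geodesic",
                                     n_reps = 300, seed = 1L,
                                     n_train_runs = 1) {
  n_full <- nrow(fcs[[1]][[1]])
  if (any(sizes > n_full))
    stop_invalid("subset size exceeds available channels (", n_full, ")")
  rows <- list()
  draw_means <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    draws <- if (size == n_full) 1L else n_roi_draws
    accs <- numeric(0)
    dm <- numeric(draws)
    for (dr in seq_len(draws)) {
      dseed <- split_seed(seed, si * 100L + dr)
      old <- .Random.seed_save()
      set.seed(dseed)
      keep <- sort(sample.int(n_full, size))
      .Random.seed_restore(old)
      sub <- lapply(fcs, function(runs) lapply(runs, function(fc) {
        v <- as_fc_values(fc)[keep, keep, drop = FALSE]
        v
      }))
      res <- run_identification_experiment(sub, method, n_train_runs,
                                           n_reps,
                                           seed = split_seed(dseed, 1L))
      accs <- c(accs, res$accuracies)
      dm[dr] <- mean(res$accuracies)
    }
    rows[[si]] <- data.frame(size = size, mean_accuracy = mean(accs),
                             sd_accuracy = stats::sd(accs),
                             n_draws = draws)
    draw_means[[si]] <- dm
  }
  out <- do.call(rbind, rows)
  attr(out, "draw_means") <- draw_means
  out
}
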