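#' Select an autoregressive model order by BIC
#'
#' Fits AR(p) models for `p = 0, ..., max_order` by ordinary least squares
#' on the lagged design and returns the order minimizing
#' `BIC(p) = n log(sigma2_p) + p log(n)`, the Gaussian-profile form. All
#' candidate orders are fit on the common effective sample (conditioning on
#' the first `max_order` values) so the criteria are comparable; ties break
#' toward the smaller order.
#'
#' @param series numeric vector, length > `3 * max_order`.
#' @param max_order largest candidate order; default `min(30, n / 10)`.
#' @return selected order (integer >= 0). A constant series returns 0 with a
#'   warning.
#' @export
select_ar_order_bic <- function(series, max_order = NULL) {
  n_full <- length(series)
  if (is.null(max_order)) max_order <- min(30L, floor(n_full / 10))
  max_order <- as.integer(max_order)
  if (max_order < 0) stop_invalid("`max_order` must be >= 0")
  if (n_full <= 3 * max_order && max_order > 0)
    stop_invalid("series length must exceed 3 * max_order")
  if (stats::sd(series) == 0) {
    warning("constant series: AR order set to 0")
    return(0L)
  }
  if (max_order == 0L) return(0L)
  y_all <- series - mean(series)
  n <- n_full - max_order
  y <- y_all[(max_order + 1):n_full]
  lagmat <- sapply(seq_len(max_order), function(k)
    y_all[(max_order + 1 - k):(n_full - k)])
  xtx <- crossprod(lagmat)
  xty <- crossprod(lagmat, y)
  bic <- numeric(max_order + 1)
  bic[1] <- n * log(mean(y^2))
  for (p in seq_len(max_order)) {
    coef <- solve(xtx[1:p, 1:p, drop = FALSE], xty[1:p, , drop = FALSE])
    rss <- sum(y^2) - sum(coef * xty[1:p, ])
    bic[p + 1] <- n * log(max(rss / n, .Machine$double.xmin)) + p * log(n)
  }
  which.min(bic) - 1L  # which.min takes the first (smallest p) on ties
}

#' Remove temporal autocorrelation by AR prewhitening
#'
#' Fits an AR(`order`) model by least squares on the lagged (mean-centered)
#' design and returns the residual series of length `n - order`; the
#' residuals have (approximately) zero autocorrelation at lags up to
#' `order`, so downstream Pearson correlations have their nominal sampling
#' distribution. `order = 0` returns the mean-centered series unchanged.
#'
#' @param series numeric vector.
#' @param order AR order, `order < length(series) / 3`. `NULL` selects the
#'   order with [select_ar_order_bic()].
#' @return numeric residual vector with attributes `order` and
#'   `ar_coefficients`.
#' @export
prewhiten <- function(series, order = NULL) {
  n <- length(series)
  if (is.null(order)) order <- select_ar_order_bic(series)
  order <- as.integer(order)
  if (order < 0) stop_invalid("`order` must be >= 0")
  if (order >= n / 3) stop_invalid("`order` must be below length/3")
  y_all <- series - mean(series)
  if (order == 0L) {
    res <- y_all
    coef <- numeric(0)
  } else {
    y <- y_all[(order + 1):n]
    lagmat <- sapply(seq_len(order), function(k)
      y_all[(order + 1 - k):(n - k)])
    coef <- as.numeric(solve(crossprod(lagmat), crossprod(lagmat, y)))
    res <- y - as.numeric(lagmat %*% coef)
  }
  attr(res, "order") <- order
  attr(res, "ar_coefficients") <- coef
  res
}

#' Functional-connectivity matrix container
#'
#' A symmetric Pearson correlation matrix over channels/ROIs with unit
#' diagonal, tagged with subject, run and contrast.
#'
#' @param values square symmetric numeric matrix in \[-1, 1\] with unit
#'   diagonal.
#' @param labels channel/ROI labels.
#' @param subject_id,run_id,contrast metadata.
#' @param flagged_channels labels of zero-variance channels whose rows were
#'   zeroed (see [fc_matrix()]).
#' @return object of class `fc_matrix`.
#' @export
new_fc_matrix <- function(values, labels = NULL, subject_id = NA_character_,
                          run_id = NA_character_, contrast = NA_character_,
                          flagged_channels = character(0)) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_invalid("`values` must be a square matrix")
  if (max(abs(values - t(values))) > 1e-8)
    stop_invalid("`values` must be symmetric")
  if (any(abs(diag(values) - 1) > 1e-8))
    stop_invalid("`values` must have unit diagonal")
  if (any(values > 1 + 1e-8 | values < -1 - 1e-8))
    stop_invalid("correlations must lie in [-1, 1]")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  if (is.null(labels))
    labels <- sprintf("ch%02d", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = as.character(labels),
                 subject_id = subject_id, run_id = run_id,
                 contrast = contrast, flagged_channels = flagged_channels),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d, subject %s, run %s, contrast %s\n",
              nrow(x$values), ncol(x$values), x$subject_id, x$run_id,
              x$contrast))
  invisible(x)
}

#' @export
dim.fc_matrix <- function(x) dim(x$values)

#' Pearson functional-connectivity matrix of a run
#'
#' Prewhitens every channel independently (AR order selected per channel by
#' BIC unless fixed), truncates all residual series to the common minimum
#' length so samples are aligned, and computes the pairwise Pearson
#' correlation matrix. Channels whose residuals have zero variance get a
#' zero row/column (diagonal kept at 1) and are flagged.
#'
#' @param run a [ts_run()] with >= 2 channels and >= 3 samples.
#' @param prewhitened optional precomputed channels x samples residual
#'   matrix; when supplied, prewhitening is skipped.
#' @param max_order cap on the per-channel BIC order search (default
#'   `min(30, n/10)`).
#' @param ar_order fixed AR order for all channels (overrides selection);
#'   use 0 to disable prewhitening.
#' @return an [new_fc_matrix()] with attribute `"ar_orders"` (per-channel
#'   selected orders) unless `prewhitened` was supplied.
#' @export
fc_matrix <- function(run, prewhitened = NULL, max_order = NULL,
                      ar_order = NULL) {
  stopifnot(inherits(run, "ts_run"))
  if (n_channels(run) < 2 || n_samples(run) < 3)
    stop_invalid("need >= 2 channels and >= 3 samples")
  orders <- NULL
  if (is.null(prewhitened)) {
    res_list <- lapply(seq_len(n_channels(run)), function(c_idx) {
      y <- run$data[c_idx, ]
      p <- if (is.null(ar_order)) select_ar_order_bic(y, max_order) else
        ar_order
      prewhiten(y, p)
    })
    orders <- vapply(res_list, attr, integer(1), "order")
    len <- min(lengths(res_list))
    prewhitened <- do.call(rbind, lapply(res_list, function(r)
      r[(length(r) - len + 1):length(r)]))
  }
  sds <- apply(prewhitened, 1L, stats::sd)
  flagged <- run$channel_ids[sds == 0]
  vals <- matrix(0, nrow(prewhitened), nrow(prewhitened))
  ok <- sds > 0
  if (sum(ok) >= 2)
    vals[ok, ok] <- stats::cor(t(prewhitened[ok, , drop = FALSE]))
  diag(vals) <- 1
  vals[vals > 1] <- 1
  vals[vals < -1] <- -1
  out <- new_fc_matrix(vals, run$channel_ids, run$subject_id, run$run_id,
                       run$contrast, flagged)
  attr(out, "ar_orders") <- orders
  out
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Row-major upper triangle, diagonal excluded; length `N (N - 1) / 2`.
#' [devectorize_upper()] is the exact inverse (rebuilding a symmetric
#' unit-diagonal matrix).
#'
#' @param fc an [new_fc_matrix()] or a square symmetric matrix.
#' @return numeric vector.
#' @export
vectorize_upper <- function(fc) {
  v <- if (inherits(fc, "fc_matrix")) fc$values else fc
  tv <- t(v)
  tv[lower.tri(tv)]  # lower triangle of the transpose = row-major upper
}

#' @rdname vectorize_upper
#' @param x vector of length `N (N - 1) / 2`.
#' @param labels optional channel labels for the rebuilt matrix.
#' @export
devectorize_upper <- function(x, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(x))) / 2
  if (n != round(n))
    stop_invalid("length is not N(N-1)/2 for any integer N")
  n <- as.integer(n)
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- x
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- 1
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Compute FC matrices for every run and contrast of a cohort
#'
#' @param cohort a [simulate_cohort()]-style cohort (hemoglobin or BOLD
#'   modality).
#' @param contrasts contrasts to process (default: all present).
#' @param ... passed to [fc_matrix()] (e.g. `max_order`, `ar_order`).
#' @return nested list `fcs[[contrast]][[subject]][[run]]`, each an
#'   [new_fc_matrix()].
#' @export
cohort_fc <- function(cohort, contrasts = NULL, ...) {
  available <- names(cohort$runs[[1]][[1]])
  if (is.null(contrasts)) contrasts <- available
  if (!all(contrasts %in% available))
    stop_invalid("unknown contrast(s): ",
                 paste(setdiff(contrasts, available), collapse = ", "))
  out <- lapply(contrasts, function(ctr)
    lapply(cohort$runs, function(subj_runs)
      lapply(subj_runs, function(run_list) fc_matrix(run_list[[ctr]], ...))))
  names(out) <- contrasts
  out
}

#' Write / read an FC matrix as delimited text with a JSON sidecar
#'
#' @param fc an [new_fc_matrix()].
#' @param stem path without extension.
#' @return `write_fc` returns `stem` invisibly; `read_fc` an
#'   [new_fc_matrix()].
#' @export
write_fc <- function(fc, stem) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.table(fc$values, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = fc$labels)
  jsonlite::write_json(
    list(subject_id = fc$subject_id, run_id = fc$run_id,
         contrast = fc$contrast, flagged_channels = fc$flagged_channels),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_fc
#' @export
read_fc <- function(stem) {
  vals <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                      header = TRUE, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  new_fc_matrix(vals, colnames(vals), meta$subject_id, meta$run_id,
                meta$contrast,
                as.character(unlist(meta$flagged_channels)))
}
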