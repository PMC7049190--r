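# BIC across candidate subtype numbers and the minimum/elbow selection rule.

#' BIC for a fitted subtype number
#'
#' `log(MSE) * N + log(N) * K` where MSE is the mean-variant objective
#' (sum of squared log residuals divided by genes x samples), N the sample
#' count, and K the subtype number.
#'
#' @param mse_mean Positive mean-variant objective.
#' @param n_samples Number of samples (>= 2).
#' @param n_subtypes Number of cancer subtypes (>= 1).
#' @return Scalar BIC value.
#' @export
compute_bic <- function(mse_mean, n_samples, n_subtypes) {
  if (!is.finite(mse_mean) || mse_mean <= 0) {
    stop("mse_mean must be strictly positive; a numerically perfect fit has ",
         "no finite BIC - add measurement noise or report -Inf explicitly")
  }
  stopifnot(n_samples >= 2, n_subtypes >= 1)
  log(mse_mean) * n_samples + log(n_samples) * n_subtypes
}

#' Fit a range of subtype numbers and tabulate the BIC curve
#'
#' Runs [run_declust()] for each candidate K (the scaling-constant grid
#' search is performed once per K) and records the mean-variant objective
#' and BIC.
#'
#' @inheritParams run_declust
#' @param k_values Ordered candidate subtype numbers, default `1:10`.
#' @param keep_fits Keep the per-K fit objects (default `TRUE`).
#' @return An object of class `declust_bic_curve`: `k_values`, `mse_values`,
#'   `bic_values`, and (optionally) `fits`.
#' @export
bic_curve <- function(observed, markers, k_values = 1:10,
                      config = declust_control(), keep_fits = TRUE) {
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 1L)) stop("k_values must be >= 1")
  n <- ncol(observed)
  fits <- vector("list", length(k_values))
  mse <- bic <- numeric(length(k_values))
  for (i in seq_along(k_values)) {
    fit <- run_declust(observed, markers, k_values[i], config)
    mse[i] <- fit$mse_mean
    bic[i] <- compute_bic(fit$mse_mean, n, k_values[i])
    if (keep_fits) fits[[i]] <- fit
  }
  structure(list(k_values = k_values, mse_values = mse, bic_values = bic,
                 fits = if (keep_fits) fits else NULL),
            class = "declust_bic_curve")
}

#' Select the number of subtypes from a BIC curve
#'
#' Combines two readings of the curve: `k_min`, the K with minimum BIC
#' (ties toward smaller K), and `k_elbow`, the interior K maximizing the
#' discrete second forward difference `BIC(k-1) - 2 BIC(k) + BIC(k+1)`
#' (ties toward smaller K; with a monotone curve whose minimum sits at an
#' endpoint shared with the elbow, that endpoint wins). When the two
#' disagree, their midpoint is taken, half-values rounded down (toward fewer
#' subtypes).
#'
#' @param curve A `declust_bic_curve` (or list with `k_values` and
#'   `bic_values`), at least 3 points.
#' @return A list with `k` (the selection), `k_min`, and `k_elbow`.
#' @export
select_num_subtypes <- function(curve) {
  k <- curve$k_values
  b <- curve$bic_values
  if (length(k) < 3L) stop("BIC curve needs at least 3 points")
  k_min <- k[which.min(b)]
  d2 <- b[seq_len(length(b) - 2L)] - 2 * b[seq(2L, length(b) - 1L)] +
    b[seq(3L, length(b))]
  k_elbow <- k[1L + which.max(d2)]
  # a curve rising from its first point has both its minimum and its bend at
  # the start; treat the shared endpoint as the elbow
  if (k_min == k[1L] && all(diff(b) >= 0)) k_elbow <- k[1L]
  sel <- if (k_min == k_elbow) k_min else (k_min + k_elbow) %/% 2L
  list(k = as.integer(sel), k_min = as.integer(k_min),
       k_elbow = as.integer(k_elbow))
}

#' Fit over a K range and return the selected model
#'
#' Convenience wrapper: builds the BIC curve, applies
#' [select_num_subtypes()], and returns the fit at the chosen K.
#'
#' @inheritParams bic_curve
#' @return A list with `fit` (the `declust_fit` at the selected K),
#'   `selection` (see [select_num_subtypes()]), and `curve`.
#' @export
declust_select_k <- function(observed, markers, k_values = 1:10,
                             config = declust_control()) {
  curve <- bic_curve(observed, markers, k_values, config, keep_fits = TRUE)
  sel <- select_num_subtypes(curve)
  idx <- match(sel$k, curve$k_values)
  fit <- curve$fits[[idx]]
  if (is.null(fit)) fit <- run_declust(observed, markers, sel$k, config)
  list(fit = fit, selection = sel, curve = curve)
}

#' @export
print.declust_bic_curve <- function(x, ...) {
  print(data.frame(K = x$k_values, mse_mean = x$mse_values, BIC = x$bic_values),
        row.names = FALSE)
  invisible(x)
}
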