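# Group-level inference on network topology: squared-L2 discrepancy between
# group mean landscapes, and its permutation null distribution under
# exchangeable subject labels. One statistic per frequency band and homology
# dimension; `band_scan()` drives the full per-band pipeline.

# flatten a list of landscapes into a feature matrix (layer x grid values
# stacked per column) plus the trapezoid weight vector replicated per layer
.landscape_features <- function(subjects) {
  .check_landscape_compat(subjects)
  X <- vapply(subjects, function(l) as.numeric(l$values),
              numeric(length(subjects[[1]]$values)))
  w <- rep(.trap_weights(subjects[[1]]$grid),
           times = ncol(subjects[[1]]$values))
  list(X = as.matrix(X), w = w)
}

.discrepancy_from_features <- function(X, w, idx1) {
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, -idx1, drop = FALSE])
  sum(w * (m1 - m2)^2)
}

#' Landscape discrepancy statistic between two groups
#'
#' The squared L2 norm of the difference between group mean landscapes,
#' summed over layers: `T = integral || mean_1(t) - mean_2(t) ||^2 dt`, with
#' the integral taken over the landscape scale grid (one statistic per
#' frequency band and homology dimension). Equal to
#' `landscape_l2(mean_landscape(g1), mean_landscape(g2))^2`.
#'
#' @param group1,group2 non-empty lists of [landscape()] objects sharing one
#'   grid, layer count and homology dimension.
#' @return a non-negative number.
#' @export
landscape_discrepancy <- function(group1, group2) {
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be non-empty")
  feats <- .landscape_features(c(group1, group2))
  .discrepancy_from_features(feats$X, feats$w, seq_along(group1))
}

#' Permutation test on the landscape discrepancy
#'
#' Five-step procedure: compute the observed discrepancy, repeatedly permute
#' the group labels (resampling the pooled subjects without replacement into
#' groups of the original sizes), recompute the statistic, and compare. When
#' the number of distinct label assignments `choose(n1 + n2, n1)` does not
#' exceed `B`, the null distribution is enumerated exactly instead of
#' sampled. Reported are the add-one p-value
#' `(1 + #{null >= observed}) / (B + 1)` and the decision threshold `tau`,
#' the empirical `(1 - alpha)` quantile of the null sample.
#'
#' @inheritParams landscape_discrepancy
#' @param B number of permutations (Monte-Carlo unless enumeration is
#'   cheaper).
#' @param alpha test level for the threshold (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @return object of class `permutation_result` with fields `observed`,
#'   `null_samples`, `p_value`, `threshold`, `reject`, `B`, `alpha`, `seed`,
#'   `enumerated`.
#' @export
permutation_test <- function(group1, group2, B = 999, alpha = 0.05,
                             seed = NULL) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  if (B < 100) stop("`B` must be at least 100")
  feats <- .landscape_features(c(group1, group2))
  X <- feats$X; w <- feats$w
  n <- n1 + n2
  observed <- .discrepancy_from_features(X, w, seq_len(n1))
  n_total <- suppressWarnings(choose(n, n1))
  enumerated <- is.finite(n_total) && n_total <= B
  if (enumerated) {
    combs <- utils::combn(n, n1)
    null_samples <- apply(combs, 2L, function(idx)
      .discrepancy_from_features(X, w, idx))
  } else {
    draw <- function() {
      vapply(seq_len(B), function(i) {
        idx <- sample.int(n, n1)
        .discrepancy_from_features(X, w, idx)
      }, numeric(1))
    }
    null_samples <- if (is.null(seed)) draw() else
      withr::with_seed(seed, draw())
  }
  Bn <- length(null_samples)
  p_value <- (1 + sum(null_samples >= observed)) / (Bn + 1)
  threshold <- unname(stats::quantile(null_samples, 1 - alpha, type = 1))
  structure(
    list(observed = observed, null_samples = null_samples,
         p_value = p_value, threshold = threshold,
         reject = observed > threshold, B = Bn, alpha = alpha,
         seed = seed, n1 = n1, n2 = n2, enumerated = enumerated),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Landscape permutation test (n1 = %d, n2 = %d, B = %d%s)\n  T = %.6g, tau(%.3g) = %.6g, p = %.4g%s\n",
    x$n1, x$n2, x$B, if (x$enumerated) ", enumerated" else "",
    x$observed, x$alpha, x$threshold, x$p_value,
    if (x$reject) "  [reject]" else ""))
  invisible(x)
}

#' Per-band, per-dimension topological group comparison
#'
#' Runs the full pipeline for every band and homology dimension requested:
#' per subject, band coherence (smoothed periodogram), dependence distance
#' `1 - C`, Vietoris-Rips persistence, landscape; then the permutation test
#' on the landscape discrepancy. Raw p-values are reported per cell; Holm
#' adjustment across cells is available but off by default.
#'
#' @param group1,group2 lists of subject signal matrices (channels x time),
#'   or `simulated_series` objects.
#' @param sampling_rate sampling rate in Hz (required for plain matrices).
#' @param bands named list of `c(low, high)` bands; default [band_presets()].
#' @param dims homology dimensions to test, subset of 0:2.
#' @param span smoothing span in bins for the periodogram.
#' @param layers,grid_size,ceiling landscape parameters, see [landscape()].
#' @param B,alpha permutation-test parameters.
#' @param seed integer master seed; each band x dimension cell derives its
#'   own sub-seed.
#' @param holm also report Holm-adjusted p-values across cells.
#' @return data frame with one row per band x dimension: observed statistic,
#'   p-value, threshold, rejection flag.
#' @export
band_scan <- function(group1, group2, sampling_rate = NULL,
                      bands = band_presets(), dims = c(0, 1), span = 9,
                      layers = 5, grid_size = 256, ceiling = 1,
                      B = 999, alpha = 0.05, seed = 1, holm = FALSE) {
  stopifnot(all(dims %in% 0:2))
  max_dim <- max(dims)
  specs <- lapply(c(group1, group2), function(x)
    smoothed_periodogram(fourier_coeffs(x, sampling_rate), span = span))
  n1 <- length(group1)
  rows <- list()
  cell <- 0L
  for (bn in seq_along(bands)) {
    band <- bands[[bn]]
    pds <- lapply(specs, function(sp)
      vr_diagram(distance_matrix(coherence(sp, band)),
                 max_hom_dim = max_dim))
    for (k in dims) {
      cell <- cell + 1L
      ls_all <- lapply(pds, landscape, dimension = k, layers = layers,
                       grid_size = grid_size, ceiling = ceiling)
      res <- permutation_test(ls_all[seq_len(n1)], ls_all[-seq_len(n1)],
                              B = B, alpha = alpha,
                              seed = seed + 1000L * cell)
      band_name <- names(bands)[bn]
      if (is.null(band_name) || is.na(band_name) || !nzchar(band_name))
        band_name <- sprintf("band%d", bn)
      rows[[cell]] <- data.frame(
        band = band_name,
        low = band[1], high = band[2], dimension = k,
        observed = res$observed, p_value = res$p_value,
        threshold = res$threshold, reject = res$reject, B = res$B)
    }
  }
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
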