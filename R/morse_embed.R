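# Two univariate routes into persistent homology: the sub-level-set (Morse)
# filtration of a smoothed mean function, whose 0-dimensional bars encode the
# arrangement of local extrema, and the time-delay embedding that turns a
# scalar series into a point cloud for Vietoris-Rips analysis.

#' Moving-average smoothing of a univariate series
#'
#' Centered moving average with truncated (renormalised) windows at the
#' edges, used to recover the mean structure `mu(t)` of `y(t) = mu(t) + eps(t)`
#' before the sub-level filtration. Note that smoothing cannot distinguish a
#' slowly varying mean from low-frequency autocorrelated noise; conclusions
#' from the Morse filtration assume the additive-noise model holds.
#'
#' @param y numeric series.
#' @param window odd window length, at most `length(y)`; `window = 1` is the
#'   identity.
#' @return object of class `smoothed_function` with `grid` (time indices),
#'   `values`, `window`.
#' @export
smooth_series <- function(y, window = 21) {
  if (!is.numeric(y) || !all(is.finite(y))) stop("`y` must be finite numeric")
  n <- length(y)
  if (window %% 2 == 0) stop("`window` must be odd")
  if (window < 1 || window > n) stop("`window` must be in 1..length(y)")
  h <- (window - 1L) / 2L
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  structure(list(grid = seq_len(n),
                 values = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L),
                 window = window, method = "moving_average"),
            class = "smoothed_function")
}

#' Sub-level-set persistence of a sampled function
#'
#' Zero-dimensional persistence of the sub-level filtration
#' `f^{-1}((-Inf, a])` of the piecewise-linear interpolant of a sampled
#' function: a component is born at each local minimum and dies, by the
#' elder rule, at the local maximum where it merges into an older (lower
#' birth) component; the global minimum's component never dies. Ties in
#' function values are broken by index order, a generic-position convention
#' for non-Morse (degenerate) inputs.
#'
#' @param f a [smooth_series()] result or a numeric vector.
#' @param drop_zero drop zero-persistence bars (plateau artifacts).
#' @return a `persistence_diagram` with `dimension = 0` rows; exactly one has
#'   `death = Inf`.
#' @export
sublevel_pd <- function(f, drop_zero = TRUE) {
  v <- if (inherits(f, "smoothed_function")) f$values else as.numeric(f)
  if (!all(is.finite(v))) stop("values must be finite")
  n <- length(v)
  ord <- order(v, seq_len(n))       # value, ties by index
  parent <- integer(n)              # 0 = not yet added
  birth_of <- numeric(n)            # birth value carried by each root
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  births <- numeric(0); deaths <- numeric(0)
  for (i in ord) {
    parent[i] <- i
    birth_of[i] <- v[i]
    for (nb in c(i - 1L, i + 1L)) {
      if (nb < 1L || nb > n || parent[nb] == 0L) next
      ri <- find(i); rn <- find(nb)
      if (ri == rn) next
      # elder rule: the younger (higher-birth) component dies here
      if (birth_of[ri] > birth_of[rn] ||
          (birth_of[ri] == birth_of[rn] && ri > rn)) {
        young <- ri; old <- rn
      } else {
        young <- rn; old <- ri
      }
      births <- c(births, birth_of[young])
      deaths <- c(deaths, v[i])
      parent[young] <- old
    }
  }
  pd <- data.frame(dimension = 0L,
                   birth = c(births, min(v)),
                   death = c(deaths, Inf))
  if (drop_zero) pd <- pd[pd$death != pd$birth, , drop = FALSE]
  pd <- pd[order(pd$birth, pd$death), , drop = FALSE]
  rownames(pd) <- NULL
  structure(pd, n_vertices = n,
            class = c("persistence_diagram", "data.frame"))
}

#' Time-delay embedding of a univariate series
#'
#' Maps the series to the point cloud
#' `(y(s), y(s - lag), ..., y(s - (d-1) lag))` for all valid `s` in
#' increasing order, reconstructing the state-space geometry of the
#' generating dynamics (Takens). The cloud has `T - (d-1) * lag` points.
#'
#' @param y numeric series of length T.
#' @param dim embedding dimension `d >= 2`.
#' @param lag delay in samples `>= 1`.
#' @return object of class `point_cloud`: `points` (matrix, one point per
#'   row), `lag`, `dim`.
#' @export
time_delay_embed <- function(y, dim = 2, lag = 1) {
  n <- length(y)
  if (dim < 2) stop("`dim` must be at least 2")
  if (lag < 1) stop("`lag` must be at least 1")
  if (n <= (dim - 1) * lag) stop("series too short for this embedding")
  s <- ((dim - 1) * lag + 1):n
  pts <- vapply(0:(dim - 1), function(j) y[s - j * lag],
                numeric(length(s)))
  structure(list(points = as.matrix(pts), lag = lag, dim = dim),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Time-delay point cloud: %d points in dimension %d (lag %d)\n",
              nrow(x$points), x$dim, x$lag))
  invisible(x)
}

#' Euclidean distance matrix of a point cloud
#'
#' Small helper bridging [time_delay_embed()] to [vr_filtration()].
#'
#' @param cloud a `point_cloud`.
#' @return symmetric matrix of pairwise Euclidean distances.
#' @export
cloud_distances <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  as.matrix(stats::dist(cloud$points))
}
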