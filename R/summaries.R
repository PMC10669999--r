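# Persistence landscapes (tent-function transform of a diagram, supporting
# means and L2 norms) and exact bottleneck / Wasserstein distances between
# small persistence diagrams.

#' Persistence landscape of a diagram
#'
#' Each diagram point `(b, d)` contributes the tent function
#' `max(0, min(t - b, d - t))`; layer `j` of the landscape is the j-th
#' largest tent value at each grid point, so `lambda_1 >= lambda_2 >= ... >= 0`
#' everywhere. Infinite deaths are truncated at `ceiling` (for the
#' `1 - coherence` metric the natural ceiling is 1, the diameter of the
#' distance).
#'
#' @param pd a [persistence()] diagram.
#' @param dimension homology dimension to summarise; a dimension absent from
#'   the diagram yields all-zero layers.
#' @param layers number of layers retained (default 5); layers beyond the
#'   deepest non-zero one are zero.
#' @param grid_size number of uniform grid points on `[0, ceiling]`
#'   (default 256).
#' @param ceiling right end of the scale grid; must be at least the largest
#'   finite death in the chosen dimension.
#' @return object of class `persistence_landscape`: `grid` (scale points) and
#'   `values` (grid_size x layers matrix), plus the construction parameters.
#' @export
landscape <- function(pd, dimension = 1, layers = 5, grid_size = 256,
                      ceiling = 1) {
  stopifnot(inherits(pd, "persistence_diagram") || is.data.frame(pd))
  if (grid_size < 2) stop("`grid_size` must be at least 2")
  pts <- pd[pd$dimension == dimension, , drop = FALSE]
  fin <- pts$death[is.finite(pts$death)]
  if (length(fin) && ceiling < max(fin))
    stop("`ceiling` must be >= the largest finite death")
  grid <- seq(0, ceiling, length.out = grid_size)
  vals <- matrix(0, grid_size, layers)
  if (nrow(pts) > 0) {
    b <- pts$birth
    d <- pmin(pts$death, ceiling)
    tents <- pmin(outer(grid, b, "-"), outer(grid, d, function(t, dd) dd - t))
    tents[tents < 0] <- 0
    ranked <- apply(tents, 1L, function(row)
      sort(row, decreasing = TRUE)[seq_len(layers)])
    ranked[is.na(ranked)] <- 0
    vals <- t(matrix(ranked, nrow = layers))
  }
  structure(
    list(grid = grid, values = vals, dimension = dimension,
         layers = layers, ceiling = ceiling),
    class = "persistence_landscape")
}

#' @export
print.persistence_landscape <- function(x, ...) {
  cat(sprintf("Persistence landscape: dim %d, %d layers on %d grid points over [0, %.3g]; max lambda_1 = %.4g\n",
              x$dimension, x$layers, length(x$grid), x$ceiling,
              max(x$values[, 1])))
  invisible(x)
}

.check_landscape_compat <- function(ls) {
  g <- ls[[1]]$grid
  L <- ncol(ls[[1]]$values)
  for (l in ls) {
    if (length(l$grid) != length(g) || any(l$grid != g))
      stop("landscapes must share one scale grid")
    if (ncol(l$values) != L)
      stop("landscapes must share one layer count")
  }
  invisible(TRUE)
}

#' Pointwise mean of a group of landscapes
#'
#' Arithmetic mean per layer and grid point. The mean of ordered layer
#' vectors is ordered, so the layer invariant is preserved; values are
#' nevertheless re-sorted pointwise to guard against floating-point ties.
#'
#' @param group non-empty list of [landscape()] objects on one grid.
#' @return a `persistence_landscape`.
#' @export
mean_landscape <- function(group) {
  if (length(group) == 0) stop("`group` must be non-empty")
  .check_landscape_compat(group)
  mean_vals <- Reduce(`+`, lapply(group, `[[`, "values")) / length(group)
  mean_vals <- t(apply(mean_vals, 1L, sort, decreasing = TRUE))
  if (ncol(group[[1]]$values) == 1L) mean_vals <- t(mean_vals)
  out <- group[[1]]
  out$values <- mean_vals
  out
}

# trapezoid quadrature weights for a uniform grid
.trap_weights <- function(grid) {
  dt <- grid[2] - grid[1]
  w <- rep(dt, length(grid))
  w[c(1, length(grid))] <- dt / 2
  w
}

#' L2 distance between landscapes
#'
#' Square root of the sum over layers of the trapezoid-rule integral of the
#' squared pointwise difference. Tent functions are piecewise linear, so the
#' quadrature error is O(grid^-2).
#'
#' @param a,b [landscape()] objects on the same grid with equal layer counts.
#' @return a non-negative number.
#' @export
landscape_l2 <- function(a, b) {
  .check_landscape_compat(list(a, b))
  w <- .trap_weights(a$grid)
  sqrt(sum(w * rowSums((a$values - b$values)^2)))
}

# --- exact diagram metrics ---------------------------------------------------

# Min-cost perfect assignment on an n x n cost matrix by bitmask dynamic
# programming; `combine` is `+` for Wasserstein-type sums and `max` for
# bottleneck. Returns value and the column assigned to each row.
.assignment_dp <- function(cost, combine) {
  n <- nrow(cost)
  dp <- rep(Inf, 2^n)
  dp[1] <- if (identical(combine, max)) -Inf else 0
  masks <- 0:(2^n - 1)
  popct <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                  integer(1))
  for (m in masks[order(popct)]) {
    r <- popct[m + 1]
    if (r == n) next
    base <- dp[m + 1]
    if (base == Inf) next        # unreachable state
    for (j in seq_len(n)) {
      bit <- 2^(j - 1)
      if (bitwAnd(m, bit) > 0) next
      cand <- combine(base, cost[r + 1, j])
      tgt <- m + bit + 1
      if (cand < dp[tgt]) dp[tgt] <- cand
    }
  }
  # backtrack
  assign_col <- integer(n)
  m <- 2^n - 1
  for (r in n:1) {
    for (j in seq_len(n)) {
      bit <- 2^(j - 1)
      if (bitwAnd(m, bit) == 0) next
      prev <- m - bit
      cand <- combine(dp[prev + 1], cost[r, j])
      if (cand <= dp[m + 1] + 1e-12) {
        assign_col[r] <- j
        m <- prev
        break
      }
    }
  }
  list(value = dp[2^n], assignment = assign_col)
}

#' Bottleneck and Wasserstein distance between persistence diagrams
#'
#' Exact optimal matching between two diagrams in one homology dimension,
#' with the standard diagonal completion: any point may be matched to its
#' orthogonal projection on the diagonal at cost `(death - birth) / 2`, and
#' the ground distance between matched points is the sup norm. The bottleneck
#' distance minimises the maximum cost; the Wasserstein-p distance minimises
#' `(sum cost^p)^(1/p)`. The optimum is found by exhaustive assignment
#' (bitmask dynamic programming), so the combined point count is capped at 12
#' — subsample or prune low-persistence points for larger diagrams.
#'
#' @param a,b persistence diagrams (data frames with `birth`, `death`, and
#'   optionally `dimension`).
#' @param metric `"bottleneck"` or `"wasserstein"`.
#' @param p Wasserstein order (default 2); ignored for bottleneck.
#' @param dimension homology dimension to compare; required when a diagram
#'   mixes dimensions.
#' @return object of class `diagram_distance`: `metric`, `value`, and a
#'   `matching` data frame (rows of `a` / `b` matched, 0 = diagonal).
#' @export
diagram_distance <- function(a, b, metric = c("bottleneck", "wasserstein"),
                             p = 2, dimension = NULL) {
  metric <- match.arg(metric)
  pick <- function(pd) {
    pd <- as.data.frame(pd)
    if (!is.null(dimension) && "dimension" %in% names(pd))
      pd <- pd[pd$dimension == dimension, , drop = FALSE]
    else if ("dimension" %in% names(pd) &&
             length(unique(pd$dimension)) > 1)
      stop("diagram mixes homology dimensions; pass `dimension`")
    if (any(!is.finite(pd$death))) {
      warning("dropping points with infinite death from the matching")
      pd <- pd[is.finite(pd$death), , drop = FALSE]
    }
    pd
  }
  a <- pick(a); b <- pick(b)
  m <- nrow(a); n <- nrow(b)
  if (m + n == 0)
    return(structure(list(metric = metric, value = 0,
                          matching = data.frame(a = integer(0),
                                                b = integer(0))),
                     class = "diagram_distance"))
  if (m + n > 12)
    stop("combined diagram size exceeds 12 points; subsample or prune low-persistence points")
  N <- m + n
  cost <- matrix(0, N, N)
  if (m > 0 && n > 0)
    for (i in seq_len(m)) for (j in seq_len(n))
      cost[i, j] <- max(abs(a$birth[i] - b$birth[j]),
                        abs(a$death[i] - b$death[j]))
  if (m > 0)        # a-point i -> diagonal slots (columns n+1..N)
    for (i in seq_len(m)) cost[i, n + seq_len(m)] <- (a$death[i] - a$birth[i]) / 2
  if (n > 0)        # diagonal rows (m+1..N) -> b-point j
    for (j in seq_len(n)) cost[m + seq_len(n), j] <- (b$death[j] - b$birth[j]) / 2
  if (metric == "wasserstein") {
    res <- .assignment_dp(cost^p, `+`)
    value <- res$value^(1 / p)
  } else {
    res <- .assignment_dp(cost, max)
    value <- res$value
  }
  asg <- res$assignment
  matching <- data.frame(
    a = c(seq_len(m), rep(0L, n)),
    b = ifelse(asg <= n, asg, 0L))[seq_len(N), , drop = FALSE]
  matching <- matching[matching$a > 0 | matching$b > 0, , drop = FALSE]
  structure(list(metric = metric, value = value, p = p,
                 matching = matching),
            class = "diagram_distance")
}

#' @export
print.diagram_distance <- function(x, ...) {
  cat(sprintf("%s distance: %.6g\n", x$metric, x$value))
  invisible(x)
}
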