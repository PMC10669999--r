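# Vietoris-Rips clique filtration and persistent homology by boundary-matrix
# reduction over GF(2). Designed for dependence networks with at most a few
# dozen nodes (19-channel EEG being the motivating case), where exact plain
# column reduction is fast and transparent.

.simplex_key <- function(v) paste(v, collapse = ".")

#' Vietoris-Rips clique filtration of a distance matrix
#'
#' Enumerates every simplex on up to `max_dim + 1` vertices and assigns it
#' the clique filtration value: the maximum pairwise distance among its
#' vertices (vertices enter at 0). Simplices are sorted by
#' (filtration value, dimension, lexicographic vertex order), a valid
#' filtration order in which every face precedes its cofaces.
#'
#' @param D symmetric non-negative matrix with zero diagonal (e.g. a
#'   [distance_matrix()]).
#' @param max_dim maximum simplex dimension, at most 3 (homology is then
#'   reliable up to dimension `max_dim - 1`).
#' @return object of class `filtered_complex`: parallel lists/vectors
#'   `simplices` (integer vertex tuples), `dim`, `value`, plus `n_vertices`.
#' @export
vr_filtration <- function(D, max_dim = 2) {
  D <- unclass(as.matrix(D))
  P <- nrow(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("`D` must be symmetric")
  if (any(D < 0)) stop("`D` must be non-negative")
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal")
  if (max_dim < 0 || max_dim > 3) stop("`max_dim` must be in 0..3")
  max_dim <- min(max_dim, P - 1L)
  simplices <- list()
  dims <- integer(0)
  values <- numeric(0)
  for (k in 0:max_dim) {
    combs <- utils::combn(P, k + 1L)
    vals <- if (k == 0) rep(0, ncol(combs)) else {
      apply(combs, 2L, function(v) max(D[v, v]))
    }
    simplices <- c(simplices, lapply(seq_len(ncol(combs)),
                                     function(j) combs[, j]))
    dims <- c(dims, rep.int(k, ncol(combs)))
    values <- c(values, vals)
  }
  keys <- vapply(simplices, function(v)
    paste(sprintf("%04d", v), collapse = "."), character(1))
  ord <- order(values, dims, keys)
  structure(
    list(simplices = simplices[ord], dim = dims[ord], value = values[ord],
         n_vertices = P, max_dim = max_dim),
    class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat(sprintf("Vietoris-Rips filtration: %d vertices, %d simplices up to dimension %d\n",
              x$n_vertices, length(x$simplices), x$max_dim))
  invisible(x)
}

# GF(2) symmetric difference of two sorted integer vectors.
.symdiff2 <- function(a, b) {
  v <- sort(c(a, b))
  v[!(duplicated(v) | duplicated(v, fromLast = TRUE))]
}

#' Persistent homology of a filtered complex
#'
#' Standard left-to-right column reduction of the GF(2) boundary matrix in
#' filtration order. A simplex whose reduced column vanishes creates a class
#' (birth at its filtration value); a simplex whose reduced column has pivot
#' `i` kills the class created by simplex `i` (death at its value). Classes
#' never killed get death `Inf`. Homology in the top simplex dimension is not
#' reported, since its deaths would require simplices one dimension higher.
#'
#' @param fc a [vr_filtration()] result (or any face-closed sorted complex in
#'   the same format).
#' @param drop_zero drop zero-persistence pairs (birth equal to death) from
#'   the returned diagram; default TRUE.
#' @return a `persistence_diagram`: data frame with columns `dimension`,
#'   `birth`, `death` (possibly `Inf`).
#' @export
persistence <- function(fc, drop_zero = TRUE) {
  stopifnot(inherits(fc, "filtered_complex"))
  ns <- length(fc$simplices)
  if (is.unsorted(fc$value)) stop("complex is not sorted by filtration value")
  pos <- new.env(hash = TRUE, size = ns)
  for (j in seq_len(ns))
    assign(.simplex_key(fc$simplices[[j]]), j, envir = pos)
  boundary <- vector("list", ns)
  for (j in seq_len(ns)) {
    v <- fc$simplices[[j]]
    if (length(v) == 1L) { boundary[[j]] <- integer(0); next }
    faces <- vapply(seq_along(v), function(drop) {
      key <- .simplex_key(v[-drop])
      if (!exists(key, envir = pos, inherits = FALSE))
        stop("complex is not closed under faces")
      get(key, envir = pos, inherits = FALSE)
    }, integer(1))
    if (any(faces > j)) stop("a face appears after its coface in the order")
    boundary[[j]] <- sort(faces)
  }
  pivot_owner <- integer(ns)            # pivot row -> column that owns it
  killed <- logical(ns)
  dims <- integer(0); births <- numeric(0); deaths <- numeric(0)
  for (j in seq_len(ns)) {
    col <- boundary[[j]]
    while (length(col) > 0L) {
      low <- col[length(col)]
      owner <- pivot_owner[low]
      if (owner == 0L) break
      col <- .symdiff2(col, boundary[[owner]])
    }
    boundary[[j]] <- col
    if (length(col) > 0L) {
      low <- col[length(col)]
      pivot_owner[low] <- j
      killed[low] <- TRUE
      dims <- c(dims, fc$dim[low])
      births <- c(births, fc$value[low])
      deaths <- c(deaths, fc$value[j])
    }
  }
  # columns that stayed zero and were never killed: essential classes
  positive <- vapply(boundary, length, integer(1)) == 0L
  essential <- which(positive & !killed)
  dims <- c(dims, fc$dim[essential])
  births <- c(births, fc$value[essential])
  deaths <- c(deaths, rep(Inf, length(essential)))
  pd <- data.frame(dimension = dims, birth = births, death = deaths)
  # top-dimension classes cannot die within the complex: not reported
  keep_dim <- if (fc$max_dim == 0L) pd$dimension == 0L else
    pd$dimension < fc$max_dim
  pd <- pd[keep_dim, , drop = FALSE]
  if (drop_zero) pd <- pd[pd$death != pd$birth, , drop = FALSE]
  pd <- pd[order(pd$dimension, pd$birth, pd$death), , drop = FALSE]
  rownames(pd) <- NULL
  structure(pd, n_vertices = fc$n_vertices,
            class = c("persistence_diagram", "data.frame"))
}

#' Persistence diagram straight from a distance matrix
#'
#' Convenience wrapper: builds the clique filtration with simplices up to
#' dimension `max_hom_dim + 1` and reduces it, returning homology in
#' dimensions `0..max_hom_dim`.
#'
#' @inheritParams vr_filtration
#' @param max_hom_dim largest homology dimension reported (<= 2).
#' @inheritParams persistence
#' @return a `persistence_diagram`.
#' @export
vr_diagram <- function(D, max_hom_dim = 1, drop_zero = TRUE) {
  if (max_hom_dim < 0 || max_hom_dim > 2)
    stop("`max_hom_dim` must be in 0..2")
  persistence(vr_filtration(D, max_dim = max_hom_dim + 1L),
              drop_zero = drop_zero)
}

# --- independent Betti-number oracle ----------------------------------------

# cliques of `size` vertices whose pairwise distances are all <= eps,
# as a list of sorted integer vectors
.cliques_at <- function(D, eps, size) {
  P <- nrow(D)
  if (size > P) return(list())
  combs <- utils::combn(P, size)
  keep <- apply(combs, 2L, function(v)
    size == 1L || max(D[v, v]) <= eps)
  lapply(which(keep), function(j) combs[, j])
}

# rank over GF(2) of the boundary map from `upper` (k-simplices) to `lower`
# ((k-1)-simplices), given as lists of vertex tuples
.boundary_rank_gf2 <- function(upper, lower) {
  if (length(upper) == 0L || length(lower) == 0L) return(0L)
  idx <- new.env(hash = TRUE, size = length(lower))
  for (i in seq_along(lower))
    assign(.simplex_key(lower[[i]]), i, envir = idx)
  M <- matrix(FALSE, length(lower), length(upper))
  for (j in seq_along(upper)) {
    v <- upper[[j]]
    for (drop in seq_along(v))
      M[get(.simplex_key(v[-drop]), envir = idx), j] <- TRUE
  }
  rank <- 0L
  row <- 1L
  nr <- nrow(M); nc <- ncol(M)
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col])[1]
    if (is.na(piv)) next
    piv <- piv + row - 1L
    if (piv != row) M[c(piv, row), ] <- M[c(row, piv), ]
    hits <- which(M[, col]); hits <- hits[hits != row]
    if (length(hits)) M[hits, ] <- xor(M[hits, , drop = FALSE],
                                       matrix(M[row, ], length(hits), nc,
                                              byrow = TRUE))
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

#' Betti number of a thresholded clique complex (oracle)
#'
#' Computes the k-th Betti number of the clique complex of the graph with
#' edges at distance `<= eps`, independently of the reduction algorithm in
#' [persistence()]: union-find over edges for `k = 0`, and
#' `#k-simplices - rank(boundary_k) - rank(boundary_{k+1})` over GF(2) for
#' `k >= 1`. Intended as a cross-check on small complexes (P up to ~8 for
#' higher dimensions).
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param eps distance threshold.
#' @param k homology dimension.
#' @return a non-negative integer count.
#' @export
betti_profile <- function(D, eps, k) {
  D <- unclass(as.matrix(D))
  P <- nrow(D)
  if (k < 0 || k > P - 1L) stop("`k` out of range")
  if (k == 0L) {
    parent <- seq_len(P)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
      if (D[i, j] <= eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    return(sum(vapply(seq_len(P), function(i) find(i) == i, logical(1))))
  }
  s_km1 <- .cliques_at(D, eps, k)
  s_k <- .cliques_at(D, eps, k + 1L)
  s_kp1 <- .cliques_at(D, eps, k + 2L)
  length(s_k) - .boundary_rank_gf2(s_k, s_km1) -
    .boundary_rank_gf2(s_kp1, s_k)
}

#' Number of k-simplices of the thresholded clique complex
#'
#' Counting helper for Euler-characteristic checks.
#'
#' @inheritParams betti_profile
#' @return integer count of k-dimensional simplices at threshold `eps`.
#' @export
simplex_count <- function(D, eps, k) {
  length(.cliques_at(unclass(as.matrix(D)), eps, k + 1L))
}
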