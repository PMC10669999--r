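# Vietoris-Rips filtration, boundary-matrix reduction, Betti oracle.

test_that("clique filtration enumerates simplices with max-edge values", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  fc <- vr_filtration(D, max_dim = 2)
  expect_equal(sum(fc$dim == 0), 3)
  expect_equal(sum(fc$dim == 1), 3)
  expect_equal(sum(fc$dim == 2), 1)
  expect_equal(fc$value[fc$dim == 0], rep(0, 3))
  expect_equal(fc$value[fc$dim > 0], rep(1, 4))
  # unit square: both triangles and the tetrahedron-free 2-skeleton at sqrt(2)
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  Dsq <- as.matrix(dist(pts))
  fsq <- vr_filtration(Dsq, max_dim = 2)
  expect_equal(fc$n_vertices, 3)
  expect_equal(unique(fsq$value[fsq$dim == 2]), sqrt(2))
  expect_error(vr_filtration(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
  expect_error(vr_filtration(matrix(c(0, -1, -1, 0), 2), 1), "non-negative")
})

test_that("filtration order is valid: values sorted, faces precede cofaces", {
  set.seed(21)
  D <- random_distance(7)
  fc <- vr_filtration(D, max_dim = 3)
  expect_false(is.unsorted(fc$value))
  keys <- vapply(fc$simplices, paste, character(1), collapse = ".")
  pos <- stats::setNames(seq_along(keys), keys)
  for (j in seq_along(fc$simplices)) {
    v <- fc$simplices[[j]]
    if (length(v) == 1) next
    for (drop in seq_along(v))
      expect_lt(pos[paste(v[-drop], collapse = ".")], j)
  }
  # at most P(P-1)/2 distinct edge filtration values
  P <- 19
  D19 <- random_distance(P)
  f19 <- vr_filtration(D19, max_dim = 2)
  expect_lte(length(unique(f19$value[f19$dim == 1])), P * (P - 1) / 2)
})

test_that("unit square yields one H1 class born at 1, dying at sqrt(2)", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  pd <- vr_diagram(as.matrix(dist(pts)), max_hom_dim = 1)
  h1 <- pd[pd$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  h0 <- pd[pd$dimension == 0, ]
  expect_equal(nrow(h0), 4)                   # P birth events
  expect_equal(sum(is.finite(h0$death)), 3)   # P - 1 merges
  expect_equal(sum(is.infinite(h0$death)), 1)
})

test_that("H0 deaths follow the merge tree of two distant pairs", {
  a <- 0.2; far <- 5
  D <- matrix(far, 4, 4)
  D[1, 2] <- D[2, 1] <- a
  D[3, 4] <- D[4, 3] <- a
  diag(D) <- 0
  pd <- vr_diagram(D, max_hom_dim = 0)
  h0 <- pd[pd$dimension == 0, ]
  expect_equal(sort(h0$death[is.finite(h0$death)]), c(a, a, far))
})

test_that("a 7-point cycle carries a single persistent loop", {
  P <- 7
  D <- matrix(0, P, P)
  for (i in 1:P) for (j in 1:P) {
    d <- min(abs(i - j), P - abs(i - j))   # graph distance on the cycle
    D[i, j] <- d
  }
  # loop alive on the plateau between edge closure (1) and chord entry (2)
  expect_equal(betti_profile(D, 1, 1), 1)
  expect_equal(betti_profile(D, 1, 0), 1)
  pd <- vr_diagram(D, max_hom_dim = 1)
  h1 <- pd[pd$dimension == 1, ]
  expect_equal(nrow(h1[h1$death - h1$birth >= 1, ]), 1)
})

test_that("Betti oracle base cases", {
  set.seed(33)
  D <- random_distance(6, lo = 0.2, hi = 1)
  expect_equal(betti_profile(D, 0.1, 0), 6)   # below all distances
  expect_equal(betti_profile(D, 0.1, 1), 0)
  expect_equal(betti_profile(D, 1.5, 0), 1)   # complete graph: connected
})

test_that("diagram and independent Betti oracle agree on random complexes", {
  set.seed(55)
  for (r in 1:12) {
    P <- sample(4:8, 1)
    D <- random_distance(P)
    pd <- persistence(vr_filtration(D, max_dim = 3), drop_zero = FALSE)
    for (eps in sort(unique(D[upper.tri(D)]))) {
      for (k in 0:2) {
        alive <- sum(pd$dimension == k & pd$birth <= eps & pd$death > eps)
        expect_equal(alive, betti_profile(D, eps, k),
                     info = sprintf("r=%d P=%d eps=%.4f k=%d", r, P, eps, k))
      }
    }
  }
})

test_that("Euler characteristic identity holds at every threshold", {
  set.seed(77)
  for (r in 1:6) {
    P <- sample(4:6, 1)    # flag complexes this small have no homology above dim 2
    D <- random_distance(P)
    for (eps in unique(c(0, sort(D[upper.tri(D)])))) {
      chi_simplices <- sum(vapply(0:(P - 1), function(k)
        (-1)^k * simplex_count(D, eps, k), numeric(1)))
      chi_betti <- sum(vapply(0:2, function(k)
        (-1)^k * betti_profile(D, eps, k), numeric(1)))
      expect_equal(chi_simplices, chi_betti)
    }
  }
})

test_that("diagram is invariant under channel relabelling", {
  set.seed(88)
  D <- random_distance(7)
  pd1 <- vr_diagram(D, max_hom_dim = 1)
  perm <- sample(7)
  pd2 <- vr_diagram(D[perm, perm], max_hom_dim = 1)
  key <- function(pd) {
    pd <- pd[order(pd$dimension, pd$birth, pd$death), ]
    sprintf("%d|%.12f|%.12f", pd$dimension, pd$birth, pd$death)
  }
  expect_equal(key(pd1), key(pd2))
})

test_that("small metric perturbations move diagrams by at most the perturbation (stability)", {
  set.seed(99)
  delta <- 0.01
  for (r in 1:3) {
    D <- random_distance(5, lo = 0.3, hi = 1)
    E <- matrix(runif(25, -delta, delta), 5)
    E <- (E + t(E)) / 2
    diag(E) <- 0
    D2 <- pmax(D + E, 0)
    diag(D2) <- 0
    for (k in 0:1) {
      a <- vr_diagram(D, 1); a <- a[a$dimension == k & is.finite(a$death), ]
      b <- vr_diagram(D2, 1); b <- b[b$dimension == k & is.finite(b$death), ]
      if (nrow(a) + nrow(b) == 0 || nrow(a) + nrow(b) > 12) next
      expect_lte(diagram_distance(a, b, "bottleneck")$value, delta + 1e-12)
    }
  }
})

test_that("reduction rejects malformed complexes", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  fc <- vr_filtration(D, 2)
  broken <- fc
  broken$value <- rev(broken$value)
  expect_error(persistence(broken), "not sorted")
  noface <- fc
  keep <- noface$dim != 1 | seq_along(noface$dim) != which(noface$dim == 1)[1]
  noface$simplices <- noface$simplices[keep]
  noface$dim <- noface$dim[keep]
  noface$value <- noface$value[keep]
  expect_error(persistence(noface), "faces")
})
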