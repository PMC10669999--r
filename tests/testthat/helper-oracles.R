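# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (enumeration, brute force) so they share no code path
# with the implementations they check.

# random symmetric distance matrix with zero diagonal and distinct entries
random_distance <- function(P, lo = 0.1, hi = 1) {
  M <- matrix(stats::runif(P * P, lo, hi), P)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# brute-force optimal diagram matching over every permutation of the
# diagonally-augmented point sets; combined size must stay tiny
brute_diagram_distance <- function(a, b, metric = "bottleneck", p = 2) {
  m <- nrow(a); n <- nrow(b); N <- m + n
  cost <- matrix(0, N, N)
  if (m && n)
    for (i in 1:m) for (j in 1:n)
      cost[i, j] <- max(abs(a$birth[i] - b$birth[j]),
                        abs(a$death[i] - b$death[j]))
  if (m) for (i in 1:m) cost[i, n + 1:m] <- (a$death[i] - a$birth[i]) / 2
  if (n) for (j in 1:n) cost[m + 1:n, j] <- (b$death[j] - b$birth[j]) / 2
  pp <- perms(N)
  vals <- apply(pp, 1, function(sigma) {
    cc <- cost[cbind(seq_len(N), sigma)]
    if (metric == "bottleneck") max(cc) else sum(cc^p)^(1 / p)
  })
  min(vals)
}

# number of components of the sub-level set {i : v_i <= a} on the path graph
path_components_at <- function(v, a) {
  mask <- v <= a
  sum(rle(mask)$values)
}

# local minima of a sampled function (endpoints included; generic values)
n_local_minima <- function(v) {
  n <- length(v)
  left <- c(Inf, v[-n])
  right <- c(v[-1], Inf)
  sum(v < left & v < right)
}

# largest clique (exhaustive) of the graph with edges D <= eps, restricted
# to the given vertex subset
largest_clique_size <- function(D, eps, vertices = seq_len(nrow(D))) {
  best <- 1L
  for (k in length(vertices):2) {
    subs <- utils::combn(vertices, k)
    ok <- apply(subs, 2, function(v) max(D[v, v]) <= eps)
    if (any(ok)) return(k)
  }
  best
}

# minimal persistence-diagram data frame
pd_frame <- function(birth, death, dimension = 1L) {
  structure(data.frame(dimension = rep(as.integer(dimension),
                                       length.out = length(birth)),
                       birth = birth, death = death),
            class = c("persistence_diagram", "data.frame"))
}
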