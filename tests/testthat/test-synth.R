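# Latent AR(2) oscillators, mixture presets, and the closed-form coherence
# oracle.

test_that("AR(2) coefficients invert to roots of magnitude M and phase psi", {
  expect_equal(unname(ar2_coefficients(M = 2, psi = 0.25)), c(0, -0.25))
  cases <- expand.grid(M = c(1.01, 1.05, 1.1, 2, 5),
                       psi = c(0.02, 0.1, 0.25, 0.4, 0.49))
  for (i in seq_len(nrow(cases))) {
    co <- ar2_coefficients(cases$M[i], cases$psi[i])
    roots <- polyroot(c(1, -co["phi1"], -co["phi2"]))
    expect_equal(sort(Mod(roots)), rep(cases$M[i], 2), tolerance = 1e-10)
    expect_equal(sort(abs(Arg(roots))) / (2 * pi),
                 rep(cases$psi[i], 2), tolerance = 1e-10)
  }
  expect_error(ar2_coefficients(1, 0.1), "> 1")
  expect_error(ar2_coefficients(0.9, 0.1), "> 1")
  expect_error(ar2_coefficients(1.1, 0.5), "0, 0.5")
  expect_error(ar2_coefficients(1.1, 0), "0, 0.5")
})

test_that("AR(2) spectrum peaks at the requested frequency and is flat in the white-noise limit", {
  # psi = 10/100 at SR = 100 Hz puts the peak at 10 Hz
  spec <- ar2_spec(peak_freq = 10, sampling_rate = 100, root_magnitude = 1.1)
  grid <- seq(0, 50, by = 0.01)
  expect_lt(abs(grid[which.max(ar2_spectrum(spec, grid))] - 10), 0.25)
  # sharper roots concentrate the peak closer still
  sharp <- ar2_spec(10, 100, root_magnitude = 1.005)
  expect_lt(abs(grid[which.max(ar2_spectrum(sharp, grid))] - 10), 0.02)
  # enormous root magnitude ~ white noise: flat spectrum at sigma^2
  flat <- ar2_spec(25, 100, root_magnitude = 1e8, innovation_sd = 2)
  expect_equal(ar2_spectrum(flat, c(0, 10, 25, 50)), rep(4, 4),
               tolerance = 1e-6)
  expect_error(ar2_spectrum(spec, 60), "SR/2")
})

test_that("spectrum integrates to the process variance", {
  spec <- ar2_spec(10, 100, root_magnitude = 1.2)
  omega_f <- seq(0, 50, length.out = 20001)
  S <- ar2_spectrum(spec, omega_f)
  # two-sided symmetry: var = (1/2pi) int_{-pi}^{pi} S = 2 * (1/SR) * int_0^{SR/2} S df
  v_spec <- 2 * sum(S) * (omega_f[2] - omega_f[1]) / spec$sampling_rate
  z <- simulate_ar2(spec, 2e5, seed = 11)
  expect_equal(v_spec, var(z), tolerance = 0.05)
})

test_that("simulate_ar2 is deterministic, stationary, and matches Yule-Walker", {
  spec <- ar2_spec(10, 100, root_magnitude = 1.1)
  expect_identical(simulate_ar2(spec, 100, seed = 3),
                   simulate_ar2(spec, 100, seed = 3))
  z <- simulate_ar2(spec, 1e5, seed = 7)
  rho1 <- acf(z, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(rho1, spec$phi1 / (1 - spec$phi2), tolerance = 0.02)
  # smoothed-periodogram peak near the design frequency (the theoretical
  # AR(2) peak sits at 9.9 Hz for M = 1.1; raw-periodogram argmax is noisy)
  per <- stats::spec.pgram(z, spans = 51, taper = 0, plot = FALSE)
  fpeak <- per$freq[which.max(per$spec)] * 100
  expect_lt(abs(fpeak - 10), 0.5)
})

test_that("mixing is linear and validates dimensions", {
  spec <- ar2_spec(10, 100)
  A1 <- diag(3)
  m1 <- mixture_model(A1, replicate(3, spec, simplify = FALSE), 0)
  m2 <- mixture_model(2 * A1, replicate(3, spec, simplify = FALSE), 0)
  y1 <- simulate_mixture(m1, 200, seed = 5)
  y2 <- simulate_mixture(m2, 200, seed = 5)
  expect_equal(2 * y1$data, y2$data)
  expect_error(mixture_model(matrix(1, 2, 2),
                             replicate(3, spec, simplify = FALSE)),
               "ncol")
  expect_error(mixture_model(rbind(c(1, 0), c(0, 0)),
                             replicate(2, spec, simplify = FALSE)),
               "all-zero")
})

test_that("preset mixing matrices match the printed designs", {
  e1 <- preset_example("example1")
  expect_equal(dim(e1$mixing), c(9L, 8L))
  expect_equal(unname(rowSums(e1$mixing)), rep(1, 9))   # each row averages two latents
  e2 <- preset_example("example2")
  expect_equal(dim(e2$mixing), c(9L, 5L))
  single <- rowSums(abs(e2$mixing) > 0) == 1
  expect_equal(which(single), 6:9)                      # lone-latent block
  expect_equal(unname(e2$mixing[6:9, 5]), rep(1, 4))    # entry 2 with prefactor 1/2
  e3 <- preset_example("example3_group1", c = 0)
  expect_equal(unname(rowSums(abs(e3$mixing) > 0)), rep(2, 6))
  e3b <- preset_example("example3_group2")
  expect_equal(dim(e3b$mixing), c(6L, 6L))
  expect_error(preset_example("example9"))
  # adjacency invariants
  for (m in list(e1, e2, e3, e3b)) {
    expect_true(isSymmetric(m$ground_truth_adjacency))
    expect_true(all(diag(m$ground_truth_adjacency)))
  }
})

test_that("ground-truth adjacency carries the designed cycle counts", {
  # distance 0 between adjacent channels, 1 otherwise: exact clique complex
  beta1_of <- function(model) {
    adj <- model$ground_truth_adjacency
    D <- 1 - adj
    diag(D) <- 0
    betti_profile(D, 0.5, 1)
  }
  expect_equal(beta1_of(preset_example("example1")), 2)  # two cycles
  expect_equal(beta1_of(preset_example("example2")), 1)  # one cycle + clique
  expect_equal(beta1_of(preset_example("example3_group1")), 1)
  expect_equal(beta1_of(preset_example("example3_group2")), 0)
})

test_that("theoretical coherence has unit diagonal, 1/4 for half-shared latents, and vanishes with noise", {
  m0 <- preset_example("example3_group1", c = 0)
  C0 <- theoretical_coherence(m0, 10)
  expect_equal(unname(diag(C0)), rep(1, 6))
  # channels sharing one of their two iid latents: closed form gives 1/4
  expect_equal(C0[1, 2], 0.25, tolerance = 1e-9)
  expect_equal(C0[1, 3], 0, tolerance = 1e-12)
  # off-diagonal coherence decreases monotonically to 0 as c grows
  # (the latent spectrum peaks near 400 at 10 Hz, so the noise floor must be
  # far larger before coherence is negligible)
  cs <- c(0, 0.5, 1, 2, 5, 500)
  offdiag <- sapply(cs, function(cc)
    theoretical_coherence(preset_example("example3_group1", c = cc), 10)[1, 2])
  expect_true(all(diff(offdiag) < 0))
  expect_lt(offdiag[length(cs)], 1e-3)
})

test_that("estimated band coherence separates adjacent from non-adjacent channels", {
  m <- preset_example("example1", c = 0.1)
  adj <- m$ground_truth_adjacency
  off <- upper.tri(adj)
  diffs <- sapply(1:20, function(s) {
    y <- simulate_mixture(m, 512, seed = 200 + s)
    sp <- smoothed_periodogram(fourier_coeffs(y), span = 9)
    C <- coherence(sp, band_presets("alpha"))
    mean(C[off & adj]) - mean(C[off & !adj])
  })
  expect_gt(mean(diffs), 0.05)
})

test_that("estimated coherence decreases with the sensor-noise scale", {
  cs <- c(0, 0.5, 1, 2, 5)
  mean_coh <- sapply(cs, function(cc) {
    m <- preset_example("example3_group1", c = cc)
    mean(sapply(1:8, function(s) {
      y <- simulate_mixture(m, 512, seed = 40 + s)
      C <- coherence(smoothed_periodogram(fourier_coeffs(y), span = 9),
                     band_presets("alpha"))
      mean(C[upper.tri(C)])
    }))
  })
  expect_true(all(diff(mean_coh) < 0))
})

test_that("estimated coherence converges to the closed form as T grows", {
  m <- preset_example("example3_group1", c = 0.5)
  fgrid <- seq(8, 12 - 0.01, by = 0.01)   # band-average of the closed form
  Cth <- Reduce(`+`, lapply(fgrid, theoretical_coherence, model = m)) /
    length(fgrid)
  mae <- sapply(c(2^12, 2^15), function(T) {
    y <- simulate_mixture(m, T, seed = 99)
    C <- coherence(smoothed_periodogram(fourier_coeffs(y), span = 9),
                   band_presets("alpha"))
    mean(abs(C - Cth)[upper.tri(C)])
  })
  # sampling error shrinks with T; the O(1/span) smoothing bias remains
  expect_lt(mae[2], mae[1])
  expect_lt(mae[2], 0.1)
})
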