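# Spherical-harmonic transform and shape descriptors

test_that("a constant grid has pure degree-0 content", {
  a <- sh_expand(matrix(2.5, 24, 24))
  expect_equal(Mod(a[1, 1]), 2.5 * sqrt(4 * pi), tolerance = 1e-12)
  off <- Mod(unclass(a))
  off[1, 1] <- 0
  expect_lt(max(off) / Mod(a[1, 1]), 1e-10)
  f <- sh_power_spectrum(a, 12)
  expect_lt(max(f[-1]) / f[1], 1e-6)
  expect_true(all(f >= 0))
})

test_that("expansion matches the adaptive-quadrature oracle for l <= 4", {
  rfun <- function(th, ph) {
    1 + 0.10 * Re(ylm_explicit(1, 0, th, ph)) +
        0.08 * Re(ylm_explicit(2, 1, th, ph)) +
        0.06 * Re(ylm_explicit(3, 2, th, ph)) +
        0.05 * Re(ylm_explicit(4, 4, th, ph))
  }
  f_impl <- sh_power_spectrum(sh_expand(sample_grid(rfun, 32)), 5)
  f_oracle <- oracle_power_spectrum(rfun, lmax = 4)
  expect_equal(as.numeric(f_impl), f_oracle, tolerance = 1e-6)
  # dominant non-zero-degree power sits where the bump was placed
  g1 <- sample_grid(function(th, ph)
    1 + 0.1 * Re(ylm_explicit(1, 0, th, ph)), 32)
  f1 <- sh_power_spectrum(sh_expand(g1), 8)
  expect_equal(which.max(f1[-1]), 1)
})

test_that("analysis and synthesis are mutually inverse for band-limited fields", {
  N <- 24
  set.seed(7)
  L <- N / 2 - 1
  A <- matrix(0 + 0i, L + 1, L + 1)
  for (l in 0:L) for (m in 0:l)
    A[l + 1, m + 1] <- complex(real = rnorm(1),
                               imaginary = if (m == 0) 0 else rnorm(1))
  A <- structure(A, class = "sph_coeffs", normalization = "orthonormal",
                 grid_size = N, lmax_grid = L, real_field = TRUE)
  g <- sh_reconstruct(A, N)
  A2 <- sh_expand(g)
  expect_lt(max(Mod(unclass(A2) - unclass(A))), 1e-8)
  # and grid -> coeffs -> grid
  g2 <- sh_reconstruct(A2, N)
  expect_equal(g2, g, tolerance = 1e-10)
  # zeroing all l > 0 yields a constant grid
  A0 <- A
  A0[-1, ] <- 0
  gc <- sh_reconstruct(A0, N)
  expect_lt(diff(range(gc)), 1e-10 * abs(mean(gc)))
})

test_that("truncation keeps the power of retained degrees (Parseval)", {
  mesh <- bumpy_sphere_mesh(3, 2, 0.25, n_subdiv = 4)
  a <- sh_expand(to_spherical_grid(mesh, 60))
  f_full <- sh_power_spectrum(a, 6)
  # rebuild from a truncated coefficient set and re-expand
  keep <- 6
  At <- unclass(a)
  At[(keep + 1):nrow(At), ] <- 0
  At <- structure(At, class = "sph_coeffs", normalization = "orthonormal",
                  grid_size = attr(a, "grid_size"),
                  lmax_grid = attr(a, "lmax_grid"), real_field = TRUE)
  f_trunc <- sh_power_spectrum(sh_expand(sh_reconstruct(At)), 6)
  expect_equal(as.numeric(f_trunc), as.numeric(f_full), tolerance = 1e-10)
})

test_that("spectra are invariant under mesh rotation", {
  mesh <- bumpy_sphere_mesh(3, 2, 0.25, n_subdiv = 4)
  f0 <- sh_power_spectrum(sh_expand(to_spherical_grid(mesh, 120)), 8)
  keep <- f0 > 0.01 * sum(f0)
  for (seed in 1:5) {
    fr <- sh_power_spectrum(sh_expand(to_spherical_grid(
      random_rotation_mesh(mesh, seed), 120)), 8)
    expect_lt(max(abs(fr[keep] - f0[keep]) / f0[keep]), 0.05)
  }
})

test_that("scaling the radii by s scales every F(l) by s^2", {
  mesh <- bumpy_sphere_mesh(2, 1, 0.2, n_subdiv = 3)
  g <- to_spherical_grid(mesh, 60)$radii
  f1 <- as.numeric(sh_power_spectrum(sh_expand(g), 8))
  f2 <- as.numeric(sh_power_spectrum(sh_expand(2 * g), 8))
  expect_identical(f2, 4 * f1)  # s = 2: exact in floating point
  f3 <- as.numeric(sh_power_spectrum(sh_expand(3 * g), 8))
  expect_equal(f3, 9 * f1, tolerance = 1e-12)
})

test_that("l_max bounds are validated", {
  a <- sh_expand(matrix(1, 16, 16))
  expect_error(sh_power_spectrum(a, 9), "band limit")
  expect_silent(sh_power_spectrum(a, 8))
})

test_that("static features take the first frame; time maps stack and flatten in time order", {
  spectra <- lapply(1:5, function(t) t * (1:4))
  expect_equal(static_feature(spectra), 1:4)
  expect_error(static_feature(list()), "empty")
  tm <- time_map(spectra, n_time = 3, l_max = 4)
  expect_equal(dim(tm), c(4, 3))
  expect_equal(tm[, 1], static_feature(spectra))
  expect_equal(as.vector(tm), c(1 * (1:4), 2 * (1:4), 3 * (1:4)))
  expect_equal(length(as.vector(tm)), 4 * 3)  # l_max * T
  # T = 1 reduces to the static feature
  expect_equal(as.vector(time_map(spectra, 1)), static_feature(spectra))
  expect_error(time_map(spectra, 6), "too short")
})

test_that("frequency maps obey DFT identities", {
  # constant in time: all magnitude in the f = 0 bin
  const <- time_map(rep(list(c(2, 3)), 8), 8, 2)
  fm <- frequency_map(const)
  expect_equal(dim(fm), dim(const))
  expect_equal(fm[, 1], 8 * c(2, 3))
  expect_true(all(abs(fm[, -1]) < 1e-12))
  # circular time shift leaves the magnitude map unchanged
  set.seed(3)
  spectra <- lapply(1:8, function(t) rnorm(3)^2)
  tm <- time_map(spectra, 8, 3)
  tm_shift <- time_map(spectra[c(4:8, 1:3)], 8, 3)
  expect_equal(unclass(frequency_map(tm_shift)),
               unclass(frequency_map(tm)), tolerance = 1e-12)
  # Parseval along time with the unnormalised DFT: sum_f |.|^2 = T sum_t .^2
  expect_equal(sum(unclass(frequency_map(tm))^2),
               8 * sum(unclass(tm)^2), tolerance = 1e-12)
})
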