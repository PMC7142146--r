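# Synthetic ground-truth fixtures

test_that("icospheres have the expected resolution and unit radius", {
  m <- icosphere(3)
  expect_equal(nrow(m$vertices), 642)
  expect_equal(nrow(m$faces), 1280)
  expect_equal(range(sqrt(rowSums(m$vertices^2))), c(1, 1),
               tolerance = 1e-12)
  expect_true(all(edge_share_counts(m$faces) == 2))
})

test_that("re_ylm matches the explicit harmonic table", {
  set.seed(17)
  th <- runif(50, 0, pi)
  ph <- runif(50, 0, 2 * pi)
  for (lm in list(c(1, 0), c(2, 1), c(3, 3), c(4, 2))) {
    expect_equal(re_ylm(lm[1], lm[2], th, ph),
                 Re(ylm_explicit(lm[1], lm[2], th, ph)), tolerance = 1e-12)
  }
  # negative orders via the conjugation identity
  expect_equal(re_ylm(2, -1, th, ph),
               Re((-1)^1 * Conj(ylm_explicit(2, 1, th, ph))),
               tolerance = 1e-12)
  expect_error(re_ylm(2, 3, th, ph), "invalid")
})

test_that("bumpy spheres put their non-zero-degree power at the chosen degree", {
  sphere <- bumpy_sphere_mesh(2, 0, 0, n_subdiv = 3)
  r <- sqrt(rowSums(sphere$vertices^2))
  expect_equal(range(r), c(1, 1), tolerance = 1e-12)
  m <- bumpy_sphere_mesh(2, 0, 0.2, n_subdiv = 4)
  f <- sh_power_spectrum(sh_expand(to_spherical_grid(m, 60)), 6)
  expect_equal(which.max(f[-1]), 2)       # l = 2 dominates above degree 0
  expect_gt(min(sqrt(rowSums(m$vertices^2))), 0)  # star-shaped: r > 0
  expect_error(bumpy_sphere_mesh(2, 0, 0.6), "amplitude")
  expect_error(bumpy_sphere_mesh(2, 3, 0.1), "invalid")
})

test_that("oscillating tracks traverse the same shapes at different pace", {
  spec0 <- oscillation_spec(amplitude = 0, noise_sd = 0, n_frames = 5,
                            frequency = 1)
  tr0 <- oscillating_cell_track(spec0, n_subdiv = 2)
  for (t in 2:5) expect_equal(tr0[[t]]$vertices, tr0[[1]]$vertices)

  mk <- function(f) oscillating_cell_track(
    oscillation_spec(amplitude = 0.3, noise_sd = 0, n_frames = 20,
                     frequency = f, seed = 3), n_subdiv = 2)
  tr2 <- mk(2)
  tr5 <- mk(5)
  # the aspect oscillation preserves the enclosed volume
  signed_volume <- function(m) {
    v <- m$vertices
    f <- m$faces
    a <- v[f[, 1], ]; b <- v[f[, 2], ]; c <- v[f[, 3], ]
    sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
  vols <- vapply(tr2, signed_volume, numeric(1))
  expect_equal(max(abs(vols)) / min(abs(vols)), 1, tolerance = 1e-9)
  # frames at matched phases (lambda equal) have identical spectra ...
  sp2 <- track_spectra(tr2[c(1, 6, 11, 16)], 60, 8)   # sin = 0: lambda = 1
  sp5 <- track_spectra(tr5[c(1, 3, 5, 7)], 60, 8)
  for (k in 1:4) expect_equal(as.numeric(sp2[[k]]), as.numeric(sp5[[k]]),
                              tolerance = 1e-10)
  # ... but the frequency maps differ between the two pacings
  fm2 <- frequency_map(time_map(track_spectra(tr2, 60, 6), 20))
  fm5 <- frequency_map(time_map(track_spectra(tr5, 60, 6), 20))
  expect_gt(max(abs(fm2 - fm5)), 1e-3)
})

test_that("the frequency map of a noise-free track peaks at the doubled aspect frequency", {
  # F(l) is quadratic in the deformation, so an aspect oscillation at
  # frequency f shows up at 2f in the degree-2 row of the frequency map
  # (conjugate DFT bins 2f+1 and T-2f+1; a single Nyquist bin when 2f=T/2)
  for (f in c(2, 5)) {
    tr <- oscillating_cell_track(
      oscillation_spec(amplitude = 0.3, noise_sd = 0, n_frames = 20,
                       frequency = f, seed = 1), n_subdiv = 2)
    fm <- frequency_map(time_map(track_spectra(tr, 60, 6), 20))
    row <- fm[3, -1]
    expected <- unique(c(2 * f + 1, 20 - 2 * f + 1))
    peaks <- order(row, decreasing = TRUE)[seq_along(expected)] + 1
    expect_setequal(peaks, expected)
  }
  expect_error(oscillation_spec(frequency = 10, n_frames = 20), "Nyquist")
})

test_that("random rotations are proper, rigid and seed-dependent", {
  m <- bumpy_sphere_mesh(3, 1, 0.2, n_subdiv = 2)
  r1 <- random_rotation_mesh(m, seed = 1)
  R <- attr(r1, "rotation")
  expect_equal(det(R), 1, tolerance = 1e-12)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  i <- c(1, 10, 50)
  j <- c(5, 120, 101)
  d0 <- sqrt(rowSums((m$vertices[i, ] - m$vertices[j, ])^2))
  d1 <- sqrt(rowSums((r1$vertices[i, ] - r1$vertices[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-12)
  r2 <- random_rotation_mesh(m, seed = 2)
  expect_false(isTRUE(all.equal(r1$vertices, r2$vertices)))
  expect_identical(random_rotation_mesh(m, seed = 1)$vertices, r1$vertices)
})
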