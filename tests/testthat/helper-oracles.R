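# Independent oracles used across the test suite.

# Hand-coded orthonormal complex spherical harmonics Y_lm for l <= 4,
# m >= 0 (Condon-Shortley phase), written from the standard closed-form
# table -- deliberately independent of the package's Legendre recursion.
ylm_explicit <- function(l, m, theta, phi) {
  s <- sin(theta)
  c <- cos(theta)
  base <- switch(paste(l, m),
    "0 0" = 0.5 * sqrt(1 / pi) + 0 * c,
    "1 0" = 0.5 * sqrt(3 / pi) * c,
    "1 1" = -0.5 * sqrt(3 / (2 * pi)) * s,
    "2 0" = 0.25 * sqrt(5 / pi) * (3 * c^2 - 1),
    "2 1" = -0.5 * sqrt(15 / (2 * pi)) * s * c,
    "2 2" = 0.25 * sqrt(15 / (2 * pi)) * s^2,
    "3 0" = 0.25 * sqrt(7 / pi) * (5 * c^3 - 3 * c),
    "3 1" = -0.125 * sqrt(21 / pi) * s * (5 * c^2 - 1),
    "3 2" = 0.25 * sqrt(105 / (2 * pi)) * s^2 * c,
    "3 3" = -0.125 * sqrt(35 / pi) * s^3,
    "4 0" = (3 / 16) * sqrt(1 / pi) * (35 * c^4 - 30 * c^2 + 3),
    "4 1" = -(3 / 8) * sqrt(5 / pi) * s * (7 * c^3 - 3 * c),
    "4 2" = (3 / 8) * sqrt(5 / (2 * pi)) * s^2 * (7 * c^2 - 1),
    "4 3" = -(3 / 8) * sqrt(35 / pi) * s^3 * c,
    "4 4" = (3 / 16) * sqrt(35 / (2 * pi)) * s^4,
    stop("ylm_explicit only covers l <= 4, m >= 0"))
  base * exp(1i * m * phi)
}

# Oracle power spectrum F(l), l = 0..4, of an analytic radial function
# r(theta, phi), by nested adaptive 1D quadrature (stats::integrate, phi
# inside theta) of A_lm = Int r Conj(Y_lm) dOmega -- independent of the
# grid transform under test.
oracle_power_spectrum <- function(rfun, lmax = 4, tol = 1e-10) {
  coef_part <- function(l, m, part) {
    outer_f <- function(thetas) {
      vapply(thetas, function(th) {
        stats::integrate(function(ph) {
          z <- rfun(th, ph) * Conj(ylm_explicit(l, m, th, ph)) * sin(th)
          if (part == "re") Re(z) else Im(z)
        }, 0, 2 * pi, rel.tol = tol, abs.tol = tol)$value
      }, numeric(1))
    }
    stats::integrate(outer_f, 0, pi, rel.tol = tol, abs.tol = tol)$value
  }
  vapply(0:lmax, function(l) {
    p <- 0
    for (m in 0:l) {
      re <- coef_part(l, m, "re")
      im <- coef_part(l, m, "im")
      p <- p + (if (m == 0) 1 else 2) * (re^2 + im^2)
    }
    p
  }, numeric(1))
}

# sample an analytic radial function on the package's equiangular grid
sample_grid <- function(rfun, N) {
  th <- pi * (seq_len(N) - 0.5) / N
  ph <- 2 * pi * (seq_len(N) - 1) / N
  outer(th, ph, rfun)
}

# brute-force count of integer lattice points within radius r of origin
ball_lattice_count <- function(r) {
  n <- 0L
  for (z in -floor(r):floor(r))
    for (y in -floor(r):floor(r))
      n <- n + sum((-floor(r):floor(r))^2 + y^2 + z^2 <= r^2)
  n
}

# multiplicity of each undirected edge in a face matrix
edge_share_counts <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  tabulate(factor(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
}

# Gaussian two-class toy dataset with optional group structure
toy_dataset <- function(n_per_class, p = 4, delta = 0, n_groups = NULL,
                        group_delta = 0, seed = 1, kind = "static") {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  cls <- rep(c("a", "b"), each = n_per_class)
  x[cls == "b", 1] <- x[cls == "b", 1] + delta
  gid <- NULL
  if (!is.null(n_groups)) {
    gid <- paste0(cls, "_g", (seq_len(n) - 1) %% n_groups + 1)
    if (group_delta != 0) {
      for (g in unique(gid)) {
        set.seed(seed + sum(utf8ToInt(g)))
        x[gid == g, ] <- sweep(x[gid == g, , drop = FALSE], 2,
                               rnorm(p, sd = group_delta), "+")
      }
    }
  }
  shape_dataset(x, paste0("c", seq_len(n)), cls, gid, kind)
}
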