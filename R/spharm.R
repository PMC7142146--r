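# Spherical-harmonic (SPHARM) transform and rotation-invariant shape
# descriptors.
#
# A radial surface function r(theta, phi) sampled on an N x N equiangular
# grid (theta offset off the poles) is expanded into complex spherical
# harmonics Y_lm by FFT in azimuth and exact quadrature in colatitude:
# the grid's colatitude nodes cos(theta_i) are the Fejer (first rule)
# Chebyshev points, whose weights integrate polynomials up to degree N - 1
# exactly, so analysis and synthesis are exact for fields band-limited to
# degree N/2 - 1 (a Driscoll-Healy-type sampling theorem on the offset
# grid).
#
# The rotation-invariant power spectrum per degree,
#   F(l) = sum_m |A(l, m)|^2,
# is the static shape descriptor; stacking it over time gives the dynamic
# time map F(l, t), and a DFT along t the frequency map F(l, f).

.sh_cache <- new.env(parent = emptyenv())

# Fejer first-rule quadrature weights for nodes x_i = cos(pi*(i+0.5)/N):
# sum_i w_i p(x_i) = integral_{-1}^{1} p(x) dx exactly for deg(p) <= N - 1
.fejer1_weights <- function(N) {
  theta <- pi * (seq_len(N) - 0.5) / N
  k <- seq_len(floor(N / 2))
  w <- vapply(theta, function(th) {
    1 - 2 * sum(cos(2 * k * th) / (4 * k^2 - 1))
  }, numeric(1))
  2 * w / N
}

# Fully normalised associated Legendre functions Pbar_lm(x) including the
# spherical-harmonic norm: Y_lm = Pbar_lm(cos theta) * exp(i m phi) with
# integral |Y_lm|^2 dOmega = 1 (Condon-Shortley phase included).
# Returns a list over m = 0..lmax; element m+1 is a (lmax - m + 1) x
# length(x) matrix with rows l = m..lmax.
.norm_legendre <- function(x, lmax) {
  s <- sqrt(pmax(0, 1 - x^2))
  out <- vector("list", lmax + 1)
  pmm <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in 0:lmax) {
    if (m > 0) pmm <- -sqrt((2 * m + 1) / (2 * m)) * s * pmm
    rows <- matrix(0, lmax - m + 1, length(x))
    rows[1, ] <- pmm
    if (lmax > m) {
      rows[2, ] <- sqrt(2 * m + 3) * x * pmm
      if (lmax > m + 1) {
        for (l in (m + 2):lmax) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          rows[l - m + 1, ] <- a * (x * rows[l - m, ] - b * rows[l - m - 1, ])
        }
      }
    }
    out[[m + 1]] <- rows
  }
  out
}

# cached analysis design (nodes, weights, Legendre tables) for grid size N
.sh_design <- function(N) {
  key <- paste0("N", N)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  theta <- pi * (seq_len(N) - 0.5) / N
  x <- cos(theta)
  des <- list(theta = theta, x = x, w = .fejer1_weights(N),
              lmax = N / 2 - 1,
              P = .norm_legendre(x, N / 2 - 1))
  .sh_cache[[key]] <- des
  des
}

#' Expand a spherical grid into complex spherical-harmonic coefficients
#'
#' Computes the coefficients `A(l, m)` of the radial function sampled on an
#' `N x N` equiangular grid up to degree `N/2 - 1` (exact for band-limited
#' fields), under the orthonormal (unit-power) convention with
#' Condon-Shortley phase. Since the radial field is real, only orders
#' `m >= 0` are stored; `A(l, -m) = (-1)^m * Conj(A(l, m))`.
#'
#' @param grid A `sph_grid` from [to_spherical_grid()], or a plain numeric
#'   `N x N` matrix of radii (rows = colatitude with
#'   `theta_i = pi * (i + 0.5) / N`, columns = azimuth `phi_j = 2 pi j / N`).
#' @return An object of class `sph_coeffs`: complex lower-triangular matrix
#'   with `[l + 1, m + 1] = A(l, m)`, attributes `normalization`
#'   (`"orthonormal"`), `grid_size` and `lmax_grid`.
#' @examples
#' g <- matrix(2, 16, 16)           # sphere of radius 2
#' a <- sh_expand(g)
#' Mod(a[1, 1]) / sqrt(4 * pi)      # A(0,0) = 2 * sqrt(4 pi)
#' @export
sh_expand <- function(grid) {
  radii <- if (inherits(grid, "sph_grid")) grid$radii else as.matrix(grid)
  N <- nrow(radii)
  if (ncol(radii) != N) stop("grid must be square (N x N)")
  if (N %% 2 != 0) stop("grid size must be even")
  if (!all(is.finite(radii))) stop("grid radii must be finite")
  des <- .sh_design(N)
  L <- des$lmax + 1  # number of degrees 0..lmax
  # azimuthal DFT of every theta-row; Fhat[m + 1, i] = sum_j f(i, j) e^{-imphi_j}
  fhat <- mvfft(t(radii)) * (2 * pi / N)
  A <- matrix(0 + 0i, L, L)
  for (m in 0:(L - 1)) {
    A[(m + 1):L, m + 1] <- des$P[[m + 1]] %*% (des$w * fhat[m + 1, ])
  }
  structure(A, class = "sph_coeffs", normalization = "orthonormal",
            grid_size = N, lmax_grid = des$lmax, real_field = TRUE)
}

#' @export
print.sph_coeffs <- function(x, ...) {
  cat("SPHARM coefficients up to degree", attr(x, "lmax_grid"),
      "(orthonormal convention, real field, m >= 0 stored)\n")
  invisible(x)
}

#' Rotation-invariant power spectrum
#'
#' Sums the power of all orders of each degree,
#' `F(l) = sum_{m=-l..l} |A(l, m)|^2`, and truncates to the first `l_max`
#' degrees (`l = 0 .. l_max - 1`). `F` is unchanged under any 3D rotation
#' of the shape. Degree 0 is retained, so the descriptor is size-sensitive.
#'
#' @param coeffs A `sph_coeffs` object.
#' @param l_max Number of degrees to keep.
#' @return Numeric vector of length `l_max`, class `sph_spectrum`.
#' @export
sh_power_spectrum <- function(coeffs, l_max = 10L) {
  stopifnot(inherits(coeffs, "sph_coeffs"))
  l_max <- as.integer(l_max)
  if (l_max < 1) stop("'l_max' must be >= 1")
  if (l_max > attr(coeffs, "lmax_grid") + 1)
    stop("'l_max' exceeds the grid band limit (max ",
         attr(coeffs, "lmax_grid") + 1, " degrees)")
  A <- unclass(coeffs)
  f <- vapply(seq_len(l_max), function(li) {
    l <- li - 1
    p <- Mod(A[li, 1])^2
    if (l >= 1) p <- p + 2 * sum(Mod(A[li, 2:(l + 1)])^2)
    p
  }, numeric(1))
  structure(f, class = "sph_spectrum")
}

#' @export
print.sph_spectrum <- function(x, ...) {
  cat("Rotation-invariant SPHARM spectrum, l = 0 ..", length(x) - 1, "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Inverse SPHARM transform onto an equiangular grid
#'
#' Synthesises the radial field from its coefficients on a `grid_size` x
#' `grid_size` equiangular grid. For band-limited fields,
#' `sh_expand(sh_reconstruct(a))` is an identity to machine precision.
#' Degrees above the target grid's band limit are dropped.
#'
#' @param coeffs A `sph_coeffs` object.
#' @param grid_size Even output grid size; defaults to the analysis grid.
#' @return An `N x N` matrix of radii.
#' @export
sh_reconstruct <- function(coeffs, grid_size = NULL) {
  stopifnot(inherits(coeffs, "sph_coeffs"))
  if (is.null(grid_size)) grid_size <- attr(coeffs, "grid_size")
  N <- as.integer(grid_size)
  if (N < 8 || N %% 2 != 0) stop("'grid_size' must be an even integer >= 8")
  des <- .sh_design(N)
  A <- unclass(coeffs)
  lmax_use <- min(attr(coeffs, "lmax_grid"), des$lmax)
  g <- matrix(0 + 0i, N, N)  # rows m (0..N-1), cols theta nodes
  for (m in 0:lmax_use) {
    rows <- des$P[[m + 1]][seq_len(lmax_use - m + 1), , drop = FALSE]
    cm <- as.vector(t(A[(m + 1):(lmax_use + 1), m + 1]) %*% rows)
    g[m + 1, ] <- if (m == 0) cm else 2 * cm
  }
  t(Re(mvfft(g, inverse = TRUE)))
}

#' Static, time-map and frequency-map shape features
#'
#' `static_feature()` keeps the spectrum of the first time point only (one
#' observation per cell; the remaining frames are discarded).
#' `time_map()` stacks the first `n_time` per-frame spectra into an
#' `l_max x n_time` map `F(l, t)`; flattened column-by-column (t = 1 first)
#' it is the dynamic time-domain feature vector of length `l_max * n_time`.
#' `frequency_map()` applies an unpadded, unwindowed DFT of length `n_time`
#' along time for each degree and stores coefficient magnitudes, giving a
#' time-shift-invariant dynamic frequency-domain feature of the same size.
#'
#' @param spectra List of per-frame spectra (from [sh_power_spectrum()]),
#'   time-ordered.
#' @param n_time Number of leading time points `T` to use.
#' @param l_max Expected spectrum length (checked).
#' @param tm A `time_map`.
#' @return `static_feature()`: numeric vector of length `l_max`;
#'   `time_map()`: `l_max x n_time` matrix of class `time_map`;
#'   `frequency_map()`: matrix of the same shape, class `frequency_map`.
#' @export
static_feature <- function(spectra) {
  if (length(spectra) == 0) stop("empty spectrum list")
  as.numeric(spectra[[1]])
}

#' @rdname static_feature
#' @export
time_map <- function(spectra, n_time, l_max = length(spectra[[1]])) {
  if (length(spectra) == 0) stop("empty spectrum list")
  n_time <- as.integer(n_time)
  if (length(spectra) < n_time)
    stop("track too short: ", length(spectra), " frames, need ", n_time)
  if (any(lengths(spectra[seq_len(n_time)]) != l_max))
    stop("all spectra must have length l_max = ", l_max)
  m <- vapply(spectra[seq_len(n_time)], as.numeric, numeric(l_max))
  m <- matrix(m, nrow = l_max, ncol = n_time)
  structure(m, class = "time_map")
}

#' @rdname static_feature
#' @export
frequency_map <- function(tm) {
  stopifnot(inherits(tm, "time_map"))
  m <- unclass(tm)
  fm <- t(Mod(mvfft(t(m))))
  structure(matrix(fm, nrow = nrow(m), ncol = ncol(m)),
            class = "frequency_map")
}

#' Per-frame rotation-invariant spectra of a mesh track
#'
#' Convenience wrapper: projects every mesh onto a spherical grid and
#' computes its truncated power spectrum.
#'
#' @param meshes List of `surface_mesh` objects (one per time point).
#' @param grid_size,l_max Passed to [to_spherical_grid()] and
#'   [sh_power_spectrum()].
#' @return List of `sph_spectrum` vectors.
#' @export
track_spectra <- function(meshes, grid_size = 120L, l_max = 10L) {
  lapply(meshes, function(m)
    sh_power_spectrum(sh_expand(to_spherical_grid(m, grid_size)), l_max))
}
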