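# Synthetic ground-truth shapes and tracks: oracle meshes for the SPHARM
# tests and oscillating-ellipsoid tracks for the "same shape phases,
# different frequencies" demonstration, where static descriptors are blind
# by construction and only dynamic descriptors can discriminate.

#' Real part of an orthonormal spherical harmonic
#'
#' `Re Y_lm(theta, phi)` under the orthonormal convention with
#' Condon-Shortley phase (`m` may be negative).
#'
#' @param l Degree (>= 0).
#' @param m Order, `|m| <= l`.
#' @param theta,phi Colatitude and azimuth (radians), vectorised.
#' @return Numeric vector.
#' @export
re_ylm <- function(l, m, theta, phi) {
  if (l < 0 || abs(m) > l) stop("invalid (l, m): need l >= 0 and |m| <= l")
  am <- abs(m)
  P <- .norm_legendre(cos(theta), l)[[am + 1]][l - am + 1, ]
  # Y_{l,-m} = (-1)^m Conj(Y_lm) => same real part up to the sign (-1)^m
  sgn <- if (m < 0) (-1)^am else 1
  sgn * P * cos(am * phi)
}

.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `n_subdiv` times (each triangle into four) with
#' vertices projected onto the unit sphere. `n_subdiv = 3` gives 642
#' vertices, `4` gives 2562.
#'
#' @param n_subdiv Number of subdivision rounds (>= 0).
#' @return A `surface_mesh` with unit-radius vertices.
#' @export
icosphere <- function(n_subdiv = 3L) {
  ico <- .icosahedron()
  v <- ico$v
  f <- ico$f
  for (s in seq_len(n_subdiv)) {
    mid_cache <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      p <- v[i, ] + v[j, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(c, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  surface_mesh(v, f)
}

#' Single-harmonic "bumpy sphere" oracle mesh
#'
#' Icosphere with radii `r(theta, phi) = R * (1 + amplitude *
#' Re Y_lm(theta, phi))` -- a band-limited shape whose spherical-harmonic
#' content is known exactly, used to validate the SPHARM transform.
#'
#' @param l,m Harmonic degree and order (`|m| <= l`).
#' @param amplitude Bump amplitude, `|amplitude| < 0.5` (keeps the surface
#'   star-shaped with positive radii).
#' @param n_subdiv Icosphere subdivision rounds.
#' @param base_radius Base radius R.
#' @return A `surface_mesh`.
#' @export
bumpy_sphere_mesh <- function(l, m, amplitude, n_subdiv = 4L,
                              base_radius = 1) {
  if (abs(amplitude) >= 0.5) stop("|amplitude| must be < 0.5")
  if (l < 0 || abs(m) > l) stop("invalid (l, m): need l >= 0 and |m| <= l")
  mesh <- icosphere(n_subdiv)
  v <- mesh$vertices
  theta <- acos(pmin(1, pmax(-1, v[, 3])))
  phi <- atan2(v[, 2], v[, 1])
  r <- base_radius * (1 + amplitude * re_ylm(l, m, theta, phi))
  surface_mesh(v * r, mesh$faces,
               metadata = list(l = l, m = m, amplitude = amplitude))
}

#' Specification of an oscillating-ellipsoid cell track
#'
#' Describes a volume-preserving ellipsoid whose aspect ratio follows
#' `1 + amplitude * sin(2 * pi * frequency * t / n_frames + phase)` over
#' `n_frames` frames -- a track in which all cells pass through the same
#' shape phases while the pace is set by `frequency`.
#'
#' @param base_radius Base radius (spatial units).
#' @param amplitude Aspect oscillation amplitude, `< 1`.
#' @param frequency Cycles per track; must satisfy the Nyquist bound
#'   `frequency < n_frames / 2`.
#' @param n_frames Number of frames T.
#' @param noise_sd Radial vertex noise standard deviation (relative).
#' @param phase Phase offset (radians).
#' @param seed Seed for the vertex noise.
#' @return An object of class `oscillation_spec`.
#' @export
oscillation_spec <- function(base_radius = 10, amplitude = 0.3,
                             frequency = 2, n_frames = 20L, noise_sd = 0.02,
                             phase = 0, seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (abs(amplitude) >= 1) stop("'amplitude' must be < 1")
  if (frequency >= n_frames / 2)
    stop("'frequency' must be below the Nyquist bound n_frames / 2")
  structure(list(base_radius = base_radius, amplitude = amplitude,
                 frequency = frequency, n_frames = n_frames,
                 noise_sd = noise_sd, phase = phase,
                 seed = as.integer(seed)),
            class = "oscillation_spec")
}

#' Generate an oscillating-ellipsoid mesh track
#'
#' At frame t (t = 0 .. T-1) the x-axis is stretched by
#' `lambda_t = 1 + amplitude * sin(2 pi f t / T + phase)` and the y/z axes
#' shrunk by `1 / sqrt(lambda_t)` (volume preserved), then seeded radial
#' vertex noise is applied. Tracks with different `frequency` traverse the
#' same set of shapes, only at a different pace.
#'
#' @param spec An [oscillation_spec()].
#' @param n_subdiv Icosphere subdivision rounds of the base mesh.
#' @return List of `surface_mesh` objects, one per frame.
#' @export
oscillating_cell_track <- function(spec, n_subdiv = 3L) {
  stopifnot(inherits(spec, "oscillation_spec"))
  base <- icosphere(n_subdiv)
  v0 <- base$vertices * spec$base_radius
  set.seed(spec$seed)
  lapply(seq_len(spec$n_frames) - 1L, function(t) {
    lam <- 1 + spec$amplitude *
      sin(2 * pi * spec$frequency * t / spec$n_frames + spec$phase)
    v <- v0 %*% diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
    if (spec$noise_sd > 0)
      v <- v * (1 + rnorm(nrow(v), sd = spec$noise_sd))
    m <- surface_mesh(v, base$faces, metadata = list(time = t,
                                                     lambda = lam))
    m
  })
}

#' Apply a seeded uniformly random rotation to a mesh
#'
#' The rotation matrix is built from a random unit quaternion (uniform on
#' SO(3)), so pairwise vertex distances are preserved exactly and the
#' determinant is +1.
#'
#' @param mesh A `surface_mesh`.
#' @param seed Integer seed.
#' @return The rotated `surface_mesh`, with the matrix in attribute
#'   `rotation`.
#' @export
random_rotation_mesh <- function(mesh, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  out <- surface_mesh(mesh$vertices %*% t(R), mesh$faces, mesh$metadata)
  attr(out, "rotation") <- R
  out
}

#' Build (and optionally write) an oscillating two-or-more-class dataset
#'
#' One class per entry of `frequencies`; all classes traverse the same set
#' of shapes and differ only in oscillation frequency. By default the
#' cells are not synchronized: every class receives the *same* stratified
#' set of starting phases (a jittered uniform grid over the cycle,
#' permuted independently within each class), so the classes' single-frame
#' shape multisets are matched by construction -- a snapshot carries no
#' class information while the pace of the oscillation does. Cells get
#' derived per-cell seeds and are assigned round-robin to `n_groups`
#' pseudo time series per class (the group key for group-shuffle CV).
#' With `dir` set, meshes are written under the
#' `<class>/<series_id>/<cell_id>/t<k>.obj` convention.
#'
#' @param frequencies Oscillation frequency per class.
#' @param n_per_class Cells per class.
#' @param n_frames Frames per track.
#' @param base_radius,amplitude,noise_sd Passed to [oscillation_spec()].
#' @param phase Fixed phase offset for every cell, or `NULL` (default) for
#'   the matched stratified per-cell phases described above.
#' @param n_groups Pseudo time series per class.
#' @param n_subdiv Base-mesh subdivision rounds.
#' @param seed Master seed.
#' @param dir Optional output directory.
#' @return List of cell entries (`meshes`, `class`, `group_id`,
#'   `cell_id`), same layout as [read_mesh_tracks()].
#' @export
make_oscillating_dataset <- function(frequencies = c(2, 5),
                                     n_per_class = 30L, n_frames = 20L,
                                     base_radius = 10, amplitude = 0.3,
                                     noise_sd = 0.02, phase = NULL,
                                     n_groups = 6L, n_subdiv = 3L,
                                     seed = 1L, dir = NULL) {
  out <- list()
  if (is.null(phase)) {
    # one jittered phase grid shared by all classes, permuted per class
    set.seed((seed %% 100000L) * 10000L + 524287L)
    grid_phases <- 2 * pi * (seq_len(n_per_class) - runif(1)) / n_per_class
    phase_by_class <- lapply(seq_along(frequencies), function(ci)
      sample(grid_phases))
  }
  for (ci in seq_along(frequencies)) {
    f <- frequencies[ci]
    cls <- paste0("freq", f)
    for (i in seq_len(n_per_class)) {
      cell_seed <- (seed %% 100000L) * 10000L + ci * 1000L + i
      cell_phase <- if (is.null(phase)) phase_by_class[[ci]][i] else phase
      spec <- oscillation_spec(base_radius = base_radius,
                               amplitude = amplitude, frequency = f,
                               n_frames = n_frames, noise_sd = noise_sd,
                               phase = cell_phase, seed = cell_seed)
      entry <- list(meshes = oscillating_cell_track(spec, n_subdiv),
                    class = cls,
                    group_id = paste0(cls, "_s", ((i - 1) %% n_groups) + 1),
                    cell_id = paste0(cls, "_c", i))
      out[[length(out) + 1]] <- entry
      if (!is.null(dir)) {
        d <- file.path(dir, cls, entry$group_id, entry$cell_id)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        for (t in seq_along(entry$meshes))
          write_obj(entry$meshes[[t]],
                    file.path(d, sprintf("t%03d.obj", t - 1)))
      }
    }
  }
  out
}
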