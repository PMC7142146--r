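# Lattice Monte-Carlo cell-migration simulator (CMS).
#
# A synthetic cell is a set of occupied integer lattice sites ("spatial
# units", SU). Migration is simulated by repeatedly moving one SU from the
# cell's rear surface to a free site at its front, where front and rear are
# defined relative to a fixed, randomly drawn migration direction.

#' Parameters of the cell-migration simulator
#'
#' Bundles and validates all parameters of the lattice simulator. The four
#' shape parameters control where spatial units (SU) are removed and
#' inserted:
#'
#' * `fr` — front-rear threshold in (-1, 1): SU with relative position
#'   `P <= fr` belong to the rear; free sites with `P > fr` are front
#'   candidates. At `fr = 0` front and rear have equal weight; negative
#'   values widen the front, positive values narrow it.
#' * `nw` — neighbour-weight exponent (surface roughness): removal favours
#'   SU with few occupied 6-neighbours (`(6 - N)^nw`), insertion favours
#'   free sites with many (`N^nw`).
#' * `pw` — position-weight exponent (elongation): both moves favour sites
#'   aligned with the migration axis (`|P|^pw`).
#' * `dw` — distance-weight exponent (protrusion size): removal favours SU
#'   far from the centre of mass (`D^dw`).
#'
#' @param fr Front-rear threshold, in (-1, 1).
#' @param nw,pw,dw Non-negative score exponents.
#' @param radius_su Initial cell radius in lattice units (>= 2). The default
#'   6.2 gives an initial cell of 1021 SU.
#' @param n_iterations Total number of iterations (one SU move each).
#' @param save_interval Save an occupancy snapshot every this many
#'   iterations.
#' @param start_iteration Start of the analysis window: only snapshots at
#'   iterations strictly greater than this are kept.
#' @param p_init Integer lattice 3-vector, initial centre of mass.
#' @param seed Integer seed; fixes the migration direction and the whole
#'   Monte-Carlo trajectory.
#' @return An object of class `cms_params`.
#' @examples
#' p <- cms_params(n_iterations = 1000, save_interval = 500,
#'                 start_iteration = 0, radius_su = 3)
#' @export
cms_params <- function(fr = 0, nw = 4, pw = 4, dw = 6, radius_su = 6.2,
                       n_iterations = 100000L, save_interval = 500L,
                       start_iteration = 60000L, p_init = c(0L, 0L, 0L),
                       seed = 1L) {
  if (!is.numeric(fr) || length(fr) != 1 || fr <= -1 || fr >= 1)
    stop("'fr' must be a single number in (-1, 1)")
  for (nm in c("nw", "pw", "dw")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm))
  }
  if (!is.numeric(radius_su) || length(radius_su) != 1 || radius_su < 2)
    stop("invalid parameter: 'radius_su' must be >= 2")
  n_iterations <- as.integer(n_iterations)
  save_interval <- as.integer(save_interval)
  start_iteration <- as.integer(start_iteration)
  if (n_iterations < 1) stop("'n_iterations' must be a positive integer")
  if (save_interval < 1) stop("'save_interval' must be a positive integer")
  if (n_iterations < save_interval)
    stop("'n_iterations' must be >= 'save_interval'")
  if (start_iteration < 0 || start_iteration > n_iterations)
    stop("'start_iteration' must be in [0, n_iterations]")
  p_init <- as.integer(round(p_init))
  if (length(p_init) != 3) stop("'p_init' must be an integer 3-vector")
  structure(
    list(fr = fr, nw = nw, pw = pw, dw = dw, radius_su = radius_su,
         n_iterations = n_iterations, save_interval = save_interval,
         start_iteration = start_iteration, p_init = p_init,
         seed = as.integer(seed)),
    class = "cms_params")
}

#' @export
print.cms_params <- function(x, ...) {
  cat("CMS parameters: FR =", x$fr, " NW =", x$nw, " PW =", x$pw,
      " DW =", x$dw, "\n")
  cat("  radius", x$radius_su, "SU | iterations", x$n_iterations,
      "| save every", x$save_interval, "| analysis window (",
      x$start_iteration, ",", x$n_iterations, "] | seed", x$seed, "\n")
  invisible(x)
}

.cell_state <- function(occupancy, center_of_mass, v_D) {
  structure(list(occupancy = occupancy, center_of_mass = center_of_mass,
                 v_D = v_D),
            class = "cell_state")
}

#' Initialise a spherical cell
#'
#' Creates the initial cell state: all integer lattice sites within
#' `radius_su` of `p_init` are occupied, and the migration direction `v_D`
#' is drawn uniformly on the unit sphere from the seeded generator. `v_D`
#' stays fixed for the whole simulation.
#'
#' @param params A [cms_params()] object.
#' @return An object of class `cell_state` with fields `occupancy` (integer
#'   n x 3 matrix), `center_of_mass` and `v_D`.
#' @examples
#' cell <- init_cell(cms_params(radius_su = 3, n_iterations = 500))
#' nrow(cell$occupancy)  # 123 SU
#' @export
init_cell <- function(params) {
  stopifnot(inherits(params, "cms_params"))
  if (params$radius_su < 2) stop("invalid parameter: 'radius_su' must be >= 2")
  r <- params$radius_su
  ri <- floor(r)
  g <- as.matrix(expand.grid(x = -ri:ri, y = -ri:ri, z = -ri:ri))
  keep <- rowSums(g^2) <= r^2
  occ <- g[keep, , drop = FALSE]
  occ <- sweep(occ, 2, params$p_init, "+")
  storage.mode(occ) <- "integer"
  dimnames(occ) <- NULL
  set.seed(params$seed)
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) break
  }
  .cell_state(occ, colMeans(occ), v / n)
}

#' @export
print.cell_state <- function(x, ...) {
  cat("CMS cell state:", nrow(x$occupancy), "SU, centre of mass (",
      paste(sprintf("%.2f", x$center_of_mass), collapse = ", "),
      "), direction (",
      paste(sprintf("%.3f", x$v_D), collapse = ", "), ")\n")
  invisible(x)
}

#' Relative position of lattice sites along the migration axis
#'
#' For a site with position vector `v_P` relative to the cell's centre of
#' mass, the relative position is `P = unit(v_P) . v_D`, in `[-1, 1]`. A
#' site exactly at the centre of mass has `P = 0` by convention (it belongs
#' to the rear whenever `fr >= 0`).
#'
#' @param su Integer 3-vector or n x 3 matrix of lattice coordinates.
#' @param cell A `cell_state`.
#' @return Numeric vector of relative positions in `[-1, 1]`.
#' @export
relative_position <- function(su, cell) {
  stopifnot(inherits(cell, "cell_state"))
  if (is.null(dim(su))) su <- matrix(su, ncol = 3)
  vp <- sweep(su, 2, cell$center_of_mass, "-")
  nrm <- sqrt(rowSums(vp^2))
  p <- as.vector(vp %*% cell$v_D)
  out <- ifelse(nrm == 0, 0, p / pmax(nrm, .Machine$double.xmin))
  pmin(1, pmax(-1, out))
}

#' Rear and front move scores
#'
#' `rear_score()` scores an occupied surface SU for removal,
#' `S_r = |P|^pw * (6 - N)^nw * D^dw`; `front_score()` scores a free site
#' for insertion, `S_f = |P|^pw * N^nw`. `N` is the number of occupied
#' 6-neighbours and `D` the Euclidean distance to the centre of mass in
#' lattice units.
#'
#' @param P Relative position(s) in `[-1, 1]`.
#' @param N Integer neighbour count(s) in `0..6`.
#' @param D Non-negative distance(s) to the centre of mass.
#' @param params A [cms_params()] object (supplies the exponents).
#' @return Numeric vector of non-negative scores.
#' @examples
#' p <- cms_params()
#' rear_score(1, 5, 2, p)   # 64 at pw = 4, nw = 4, dw = 6 ... 1 * 1 * 64
#' front_score(1, 3, p)     # 81
#' @export
rear_score <- function(P, N, D, params) {
  stopifnot(inherits(params, "cms_params"))
  if (any(N < 0 | N > 6)) stop("invalid input: 'N' must be in 0..6")
  if (any(D < 0)) stop("invalid input: 'D' must be non-negative")
  abs(P)^params$pw * (6 - N)^params$nw * D^params$dw
}

#' @rdname rear_score
#' @export
front_score <- function(P, N, params) {
  stopifnot(inherits(params, "cms_params"))
  if (any(N < 0 | N > 6)) stop("invalid input: 'N' must be in 0..6")
  abs(P)^params$pw * N^params$nw
}

.nb_offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

.coord_key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")

#' Partition the cell surface into rear candidates and free front sites
#'
#' Rear candidates are occupied sites with relative position `P <= fr` that
#' have at least one empty 6-neighbour; front candidates are empty sites
#' 6-adjacent to the cell whose own relative position satisfies `P > fr`.
#'
#' @param cell A `cell_state`.
#' @param params A [cms_params()] object.
#' @return List with integer matrices `rear_surface` and `front_free`
#'   (possibly with zero rows).
#' @export
partition_front_rear <- function(cell, params) {
  stopifnot(inherits(cell, "cell_state"), inherits(params, "cms_params"))
  occ <- cell$occupancy
  occ_keys <- .coord_key(occ)
  n <- nrow(occ)
  # neighbour occupancy counts and the set of adjacent free sites
  nb_occ <- integer(n)
  free <- NULL
  for (k in 1:6) {
    nb <- sweep(occ, 2, .nb_offsets[k, ], "+")
    hit <- .coord_key(nb) %in% occ_keys
    nb_occ <- nb_occ + hit
    free <- rbind(free, nb[!hit, , drop = FALSE])
  }
  free <- free[!duplicated(.coord_key(free)), , drop = FALSE]
  p_occ <- relative_position(occ, cell)
  rear <- occ[nb_occ < 6 & p_occ <= params$fr, , drop = FALSE]
  p_free <- relative_position(free, cell)
  front <- free[p_free > params$fr, , drop = FALSE]
  storage.mode(rear) <- "integer"
  storage.mode(front) <- "integer"
  list(rear_surface = rear, front_free = front)
}

.run_cms <- function(cell, params, n_iter, save_at) {
  cms_run_cpp(cell$occupancy, cell$center_of_mass, cell$v_D,
              params$fr, params$nw, params$pw, params$dw,
              as.integer(n_iter), as.integer(save_at))
}

#' Advance the simulation by one Monte-Carlo step
#'
#' Moves exactly one SU from the rear surface to a free front site, chosen
#' by acceptance-rejection sampling on the rear and front scores (a uniform
#' candidate is accepted with probability `S / max(S)`; rear SU and front
#' site are drawn independently). The occupancy count is conserved and the
#' centre of mass is updated exactly. Connectivity is not enforced.
#'
#' Uses the current R random-number state; seed it yourself (or use
#' [cms_simulate()], which seeds from `params$seed`).
#'
#' @param cell A `cell_state`.
#' @param params A [cms_params()] object.
#' @return The new `cell_state`, with an attribute `moved` holding the
#'   `removed` and `added` lattice coordinates.
#' @export
cms_step <- function(cell, params) {
  res <- .run_cms(cell, params, 1L, integer(0))
  out <- .cell_state(res$occupancy, res$center_of_mass, cell$v_D)
  attr(out, "moved") <- list(removed = res$last_removed,
                             added = res$last_added)
  out
}

#' Simulate one migrating cell
#'
#' Initialises a spherical cell ([init_cell()]) and runs `n_iterations`
#' Monte-Carlo iterations, saving occupancy snapshots at every iteration
#' divisible by `save_interval`. Only snapshots in the analysis window
#' `(start_iteration, n_iterations]` are returned; with the defaults
#' (100000 iterations, interval 500, window start 60000) that is 80 frames.
#'
#' @param params A [cms_params()] object.
#' @return An object of class `lattice_track`: list with `frames` (list of
#'   integer n x 3 occupancy matrices), `iterations` (iteration index per
#'   frame) and `params`.
#' @examples
#' tr <- cms_simulate(cms_params(radius_su = 3, n_iterations = 1000,
#'                               save_interval = 500, start_iteration = 0))
#' length(tr$frames)  # 2
#' @export
cms_simulate <- function(params) {
  stopifnot(inherits(params, "cms_params"))
  cell <- init_cell(params)  # seeds the generator
  save_at <- seq(params$save_interval, params$n_iterations,
                 by = params$save_interval)
  save_at <- save_at[save_at > params$start_iteration]
  res <- .run_cms(cell, params, params$n_iterations, save_at)
  structure(list(frames = res$frames, iterations = as.integer(save_at),
                 params = params),
            class = "lattice_track")
}

#' @export
print.lattice_track <- function(x, ...) {
  cat("CMS lattice track:", length(x$frames), "frames of",
      if (length(x$frames)) nrow(x$frames[[1]]) else 0, "SU; iterations",
      if (length(x$iterations)) paste(min(x$iterations), "-",
                                      max(x$iterations)) else "-", "\n")
  invisible(x)
}

#' Write or read a lattice track as CSV
#'
#' The on-disk format is one row per SU per frame with columns
#' `frame` (the iteration index), `x`, `y`, `z`. Integer coordinates
#' round-trip exactly.
#'
#' @param track A `lattice_track`.
#' @param path File path.
#' @return `read_track()` returns a `lattice_track` (with `params = NULL`).
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "lattice_track"))
  n <- vapply(track$frames, nrow, integer(1))
  df <- data.frame(frame = rep(track$iterations, n),
                   do.call(rbind, track$frames))
  names(df) <- c("frame", "x", "y", "z")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- read.csv(path)
  if (!all(c("frame", "x", "y", "z") %in% names(df)))
    stop("not a track CSV: need columns frame, x, y, z")
  iters <- sort(unique(df$frame))
  frames <- lapply(iters, function(it) {
    m <- as.matrix(df[df$frame == it, c("x", "y", "z")])
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  structure(list(frames = frames, iterations = as.integer(iters),
                 params = NULL),
            class = "lattice_track")
}
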