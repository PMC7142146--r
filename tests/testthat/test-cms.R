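# Lattice cell-migration simulator

test_that("initial cell is the lattice ball with a seeded unit direction", {
  p <- cms_params(radius_su = 3, n_iterations = 500, start_iteration = 0,
                  seed = 11)
  cell <- init_cell(p)
  expect_equal(nrow(cell$occupancy), ball_lattice_count(3))  # 123
  expect_equal(sqrt(sum(cell$v_D^2)), 1, tolerance = 1e-12)
  expect_equal(cell$center_of_mass, colMeans(cell$occupancy))

  # same seed twice: identical state; p_init translates the ball
  expect_identical(init_cell(p), cell)
  p2 <- cms_params(radius_su = 3, n_iterations = 500, start_iteration = 0,
                   p_init = c(5, -2, 7), seed = 11)
  cell2 <- init_cell(p2)
  expect_equal(colMeans(cell2$occupancy), c(5, -2, 7))
  expect_error(cms_params(radius_su = 1.5), "radius_su")
})

test_that("relative position follows the dot-product definition", {
  p <- cms_params(radius_su = 3, n_iterations = 500, start_iteration = 0)
  cell <- init_cell(p)            # symmetric ball: centre of mass (0,0,0)
  cell$v_D <- c(1, 0, 0)
  expect_equal(relative_position(c(4, 0, 0), cell), 1)
  expect_equal(relative_position(c(-4, 0, 0), cell), -1)
  expect_equal(relative_position(c(0, 0, 0), cell), 0)  # degenerate: P = 0
  expect_equal(relative_position(c(0, 3, 0), cell), 0)
  P <- relative_position(cell$occupancy, cell)
  expect_true(all(P >= -1 & P <= 1))
})

test_that("rear and front scores evaluate the printed formulas", {
  p <- cms_params()  # pw = 4, nw = 4, dw = 6
  expect_equal(rear_score(1, 5, 2, p), 64)     # 1 * 1 * 2^6
  expect_equal(front_score(1, 3, p), 81)       # 1 * 3^4
  expect_equal(rear_score(0, 2, 3, p), 0)      # P = 0
  expect_equal(rear_score(0.7, 6, 3, p), 0)    # fully enclosed
  expect_equal(rear_score(0.7, 3, 0, p), 0)    # at the centre of mass
  expect_equal(front_score(0.9, 0, p), 0)      # isolated free site
  # front score monotone non-decreasing in N at fixed P
  s <- front_score(rep(0.5, 7), 0:6, p)
  expect_true(all(diff(s) >= 0))
  expect_error(rear_score(0.5, 7, 1, p), "invalid")
  expect_error(front_score(0.5, -1, p), "invalid")
})

test_that("front/rear partition respects the threshold and adjacency", {
  p <- cms_params(radius_su = 3, fr = 0, n_iterations = 500,
                  start_iteration = 0, seed = 3)
  cell <- init_cell(p)
  parts <- partition_front_rear(cell, p)
  expect_true(all(relative_position(parts$rear_surface, cell) <= p$fr))
  expect_true(all(relative_position(parts$front_free, cell) > p$fr))
  # every rear-surface member has at least one empty 6-neighbour
  occ_keys <- apply(cell$occupancy, 1, paste, collapse = ",")
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(nrow(parts$rear_surface))) {
    nb <- sweep(offsets, 2, parts$rear_surface[i, ], "+")
    expect_true(any(!(apply(nb, 1, paste, collapse = ",") %in% occ_keys)))
  }
  # front sites are empty and 6-adjacent to the cell
  expect_false(any(apply(parts$front_free, 1, paste,
                         collapse = ",") %in% occ_keys))
  # extreme threshold: front almost empty, rear covers ~ all surface
  p99 <- cms_params(radius_su = 3, fr = 0.99, n_iterations = 500,
                    start_iteration = 0, seed = 3)
  parts99 <- partition_front_rear(cell, p99)
  expect_lt(nrow(parts99$front_free), nrow(parts$front_free) / 5)
  expect_gt(nrow(parts99$rear_surface), nrow(parts$rear_surface))
})

test_that("one step moves exactly one SU from rear to front", {
  p <- cms_params(radius_su = 4, n_iterations = 500, start_iteration = 0,
                  seed = 5)
  cell <- init_cell(p)
  for (k in 1:25) {
    nxt <- cms_step(cell, p)
    expect_equal(nrow(nxt$occupancy), nrow(cell$occupancy))  # conservation
    mv <- attr(nxt, "moved")
    # removed SU satisfied P <= FR at selection time, added site P > FR
    expect_lte(relative_position(mv$removed, cell), p$fr)
    expect_gt(relative_position(mv$added, cell), p$fr)
    expect_equal(nxt$center_of_mass, colMeans(nxt$occupancy),
                 tolerance = 1e-9)
    cell <- nxt
  }
})

test_that("stalls raise errors identifying the empty candidate set", {
  p_front <- cms_params(radius_su = 3, fr = 0.999, n_iterations = 10,
                        save_interval = 10, start_iteration = 0, seed = 2)
  expect_error(cms_simulate(p_front), "front")
  p_rear <- cms_params(radius_su = 3, fr = -0.999, n_iterations = 10,
                       save_interval = 10, start_iteration = 0, seed = 2)
  expect_error(cms_simulate(p_rear), "rear")
})

test_that("frame schedule, volume conservation and determinism hold", {
  p <- cms_params(radius_su = 4, n_iterations = 1000, save_interval = 500,
                  start_iteration = 0, seed = 9)
  tr <- cms_simulate(p)
  expect_equal(length(tr$frames), 2)           # iterations 500, 1000
  expect_identical(tr$iterations, c(500L, 1000L))
  expect_equal(unique(vapply(tr$frames, nrow, integer(1))),
               ball_lattice_count(4))
  expect_true(all(diff(tr$iterations) > 0))
  # bitwise determinism under the same parameters
  expect_identical(cms_simulate(p), tr)
  # analysis window start excludes earlier snapshots
  p2 <- cms_params(radius_su = 4, n_iterations = 2000, save_interval = 500,
                   start_iteration = 1000, seed = 9)
  expect_identical(cms_simulate(p2)$iterations, c(1500L, 2000L))
})

test_that("slow migration: displacement after 1000 iterations is below one diameter", {
  for (seed in 1:4) {
    p <- cms_params(n_iterations = 1000, save_interval = 1000,
                    start_iteration = 0, seed = seed)
    tr <- cms_simulate(p)
    disp <- sqrt(sum((colMeans(tr$frames[[1]]) - p$p_init)^2))
    expect_lt(disp, 2 * p$radius_su)
  }
})

test_that("the cell drifts along its migration direction", {
  projections <- vapply(1:12, function(seed) {
    p <- cms_params(radius_su = 5, n_iterations = 3000, save_interval = 3000,
                    start_iteration = 0, seed = seed)
    cell0 <- init_cell(p)
    tr <- cms_simulate(p)
    sum((colMeans(tr$frames[[1]]) - cell0$center_of_mass) * cell0$v_D)
  }, numeric(1))
  expect_true(all(projections > 0))  # sign test: drift is never backwards
})

test_that("larger position weight concentrates removals near |P| = 1", {
  mean_removed_p <- function(pw, n_steps = 150) {
    p <- cms_params(radius_su = 4, pw = pw, n_iterations = 500,
                    start_iteration = 0, seed = 21)
    cell <- init_cell(p)
    set.seed(99)
    vals <- numeric(n_steps)
    for (k in seq_len(n_steps)) {
      nxt <- cms_step(cell, p)
      vals[k] <- abs(relative_position(attr(nxt, "moved")$removed, cell))
      cell <- nxt
    }
    mean(vals)
  }
  expect_gt(mean_removed_p(8), mean_removed_p(0.5))
})

test_that("track CSV round-trips coordinates exactly", {
  p <- cms_params(radius_su = 3, n_iterations = 600, save_interval = 300,
                  start_iteration = 0, seed = 13)
  tr <- cms_simulate(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track(tr, path)
  back <- read_track(path)
  expect_identical(back$frames, tr$frames)
  expect_identical(back$iterations, tr$iterations)
})
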