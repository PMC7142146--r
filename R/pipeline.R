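# End-to-end experiment orchestration: simulate cell cohorts per parameter
# value, extract static/dynamic SPHARM features, classify every class pair
# against naive controls, and assemble the report.

#' Configuration of a simulator-parameter experiment
#'
#' One experiment varies a single simulator parameter over `values` (one
#' class per value; the reference design uses three values and 70 cells per
#' class) while all other parameters stay at their defaults.
#'
#' @param parameter Which simulator parameter to vary: `"fr"`, `"nw"`,
#'   `"pw"` or `"dw"`.
#' @param values Parameter value per class (>= 2 values).
#' @param n_cells_per_class Cells per class (default 70).
#' @param base_params [cms_params()] defaults for the non-studied
#'   parameters (FR = 0, NW = 4, PW = 4, DW = 6).
#' @param l_max,n_time Feature truncation: spectrum degrees and time
#'   points.
#' @param grid_size Spherical grid size.
#' @param cv A [cv_config()].
#' @param seed Master seed; per-cell simulation seeds are derived from it
#'   together with the class and cell index, so a dataset can be extended
#'   without reshuffling existing cells.
#' @param out_dir Optional directory for track CSVs and feature tables.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(parameter = c("pw", "nw", "dw", "fr"),
                              values, n_cells_per_class = 70L,
                              base_params = cms_params(),
                              l_max = 10L, n_time = 20L, grid_size = 120L,
                              cv = cv_config(), seed = 1L, out_dir = NULL) {
  parameter <- match.arg(parameter)
  if (length(values) < 2)
    stop("'values' needs at least 2 parameter values (one class each)")
  if (cv$scheme == "shuffle" &&
      n_cells_per_class < cv$n_train_per_class + 1)
    stop("'n_cells_per_class' must exceed cv$n_train_per_class")
  structure(list(parameter = parameter, values = values,
                 n_cells_per_class = as.integer(n_cells_per_class),
                 base_params = base_params, l_max = as.integer(l_max),
                 n_time = as.integer(n_time),
                 grid_size = as.integer(grid_size), cv = cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys are rejected. Keys `cms.*` set the
#' base simulator parameters and `cv.*` the cross-validation options.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("parameter", "values", "n_cells_per_class", "l_max", "n_time",
             "grid_size", "seed", "out_dir", "cms", "cv")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  base <- do.call(cms_params, if (is.null(y$cms)) list() else y$cms)
  cv <- do.call(cv_config, if (is.null(y$cv)) list() else y$cv)
  args <- y[setdiff(names(y), c("cms", "cv"))]
  args$base_params <- base
  args$cv <- cv
  do.call(experiment_config, args)
}

.cell_seed <- function(master, class_idx, cell_idx) {
  (master %% 100000L) * 10000L + class_idx * 1000L + cell_idx
}

#' Simulate the cell cohort of an experiment
#'
#' Runs the simulator once per cell (classes x `n_cells_per_class`), with
#' the studied parameter set per class and derived per-cell seeds. With
#' `cfg$out_dir` set, each track is also written as CSV under
#' `<out_dir>/tracks/<class>/<cell>.csv`.
#'
#' @param cfg An [experiment_config()].
#' @return List with `tracks` (list of `lattice_track`), `class`,
#'   `cell_id` and `seeds`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  tracks <- list()
  class <- cell_id <- character(0)
  seeds <- integer(0)
  for (ci in seq_along(cfg$values)) {
    val <- cfg$values[ci]
    cls <- paste0(cfg$parameter, val)
    for (i in seq_len(cfg$n_cells_per_class)) {
      p <- cfg$base_params
      p[[cfg$parameter]] <- val
      p$seed <- .cell_seed(cfg$seed, ci, i)
      p <- do.call(cms_params, p[setdiff(names(p), character(0))])
      tr <- cms_simulate(p)
      tracks[[length(tracks) + 1]] <- tr
      class <- c(class, cls)
      cell_id <- c(cell_id, paste0(cls, "_c", i))
      seeds <- c(seeds, p$seed)
      if (!is.null(cfg$out_dir)) {
        d <- file.path(cfg$out_dir, "tracks", cls)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_track(tr, file.path(d, paste0(cls, "_c", i, ".csv")))
      }
    }
  }
  list(tracks = tracks, class = class, cell_id = cell_id, seeds = seeds)
}

#' Extract the three SPHARM feature tables from cell tracks
#'
#' Converts each track to meshes (lattice tracks are iso-surfaced first),
#' computes per-frame rotation-invariant spectra, and builds the static
#' (first frame), dynamic time-map and dynamic frequency-map feature
#' tables. Cells with fewer than `n_time` frames are excluded from the
#' dynamic tables only and recorded in `excluded`; unreadable tracks are
#' skipped with a warning.
#'
#' @param tracks List of `lattice_track` objects or of mesh lists; entries
#'   of the [read_mesh_tracks()] layout (with `$meshes`) are also
#'   accepted.
#' @param class Class label per track (taken from the track entry when
#'   omitted and available).
#' @param cell_id,group_id Optional per-track annotations.
#' @param l_max,n_time,grid_size Feature parameters.
#' @param static_all_timepoints Opt-in overfitting demonstration: also
#'   build a `static_all` table in which every time point of every cell is
#'   treated as an independent observation (the default contract keeps one
#'   observation per cell).
#' @return List of `shape_dataset`s: `static`, `time`, `frequency`
#'   (plus `static_all` when requested), `excluded` (cell ids too short
#'   for the dynamic tables) and `n_frames` per cell.
#' @export
extract_features <- function(tracks, class = NULL, cell_id = NULL,
                             group_id = NULL, l_max = 10L, n_time = 20L,
                             grid_size = 120L,
                             static_all_timepoints = FALSE) {
  n <- length(tracks)
  if (n == 0) stop("no tracks")
  get_field <- function(given, field, default) {
    if (!is.null(given)) return(given)
    got <- vapply(tracks, function(t)
      if (is.list(t) && !is.null(t[[field]])) as.character(t[[field]])
      else NA_character_, character(1))
    if (all(is.na(got))) default else got
  }
  class <- get_field(class, "class", stop("'class' labels are required"))
  cell_id <- get_field(cell_id, "cell_id", paste0("cell", seq_len(n)))
  group_id <- get_field(group_id, "group_id", NULL)
  spectra <- vector("list", n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tr <- tracks[[i]]
    meshes <- tryCatch({
      if (inherits(tr, "lattice_track")) track_to_meshes(tr)
      else if (is.list(tr) && !is.null(tr$meshes)) tr$meshes
      else tr
    }, error = function(e) e)
    if (inherits(meshes, "error")) {
      warning("skipping cell ", cell_id[i], ": ",
              conditionMessage(meshes))
      ok[i] <- FALSE
      next
    }
    sp <- tryCatch(track_spectra(meshes, grid_size, l_max),
                   error = function(e) e)
    if (inherits(sp, "error")) {
      warning("skipping cell ", cell_id[i], ": ", conditionMessage(sp))
      ok[i] <- FALSE
      next
    }
    spectra[[i]] <- sp
  }
  idx <- which(ok)
  n_frames <- vapply(spectra[idx], length, integer(1))
  gid <- if (is.null(group_id)) NULL else group_id[idx]
  static <- shape_dataset(
    t(vapply(spectra[idx], static_feature, numeric(l_max))),
    cell_id[idx], class[idx], gid, "static")
  long <- n_frames >= n_time
  excluded <- cell_id[idx][!long]
  dyn_idx <- idx[long]
  gid_dyn <- if (is.null(group_id)) NULL else group_id[dyn_idx]
  tmaps <- lapply(spectra[dyn_idx], time_map, n_time = n_time,
                  l_max = l_max)
  time_ds <- shape_dataset(
    t(vapply(tmaps, as.vector, numeric(l_max * n_time))),
    cell_id[dyn_idx], class[dyn_idx], gid_dyn, "time")
  freq_ds <- shape_dataset(
    t(vapply(tmaps, function(tm) as.vector(unclass(frequency_map(tm))),
             numeric(l_max * n_time))),
    cell_id[dyn_idx], class[dyn_idx], gid_dyn, "frequency")
  out <- list(static = static, time = time_ds, frequency = freq_ds,
              excluded = excluded,
              n_frames = stats::setNames(n_frames, cell_id[idx]))
  if (static_all_timepoints) {
    feats <- do.call(rbind, lapply(seq_along(idx), function(k)
      t(vapply(spectra[[idx[k]]], as.numeric, numeric(l_max)))))
    reps <- rep(seq_along(idx), n_frames)
    tix <- unlist(lapply(n_frames, seq_len))
    out$static_all <- shape_dataset(
      feats, paste0(cell_id[idx][reps], "_t", tix), class[idx][reps],
      if (is.null(group_id)) NULL else group_id[idx][reps], "static_all")
  }
  out
}

.class_pairs <- function(classes) {
  classes <- sort(unique(classes))
  if (length(classes) < 2) stop("need >= 2 classes")
  utils::combn(classes, 2, simplify = FALSE)
}

#' Run a full classification experiment
#'
#' Simulates the cohort, extracts the three feature kinds and, for every
#' pair of classes and every feature kind, computes cross-validation
#' accuracies, the matching naive control (random-classifier control for
#' balanced data, pooled over all class pairs under the shuffle scheme),
#' and one-sided Mann-Whitney p-values: against the control, against the
#' static accuracies (for the dynamic kinds) and against the dynamic
#' time-domain accuracies (for the frequency kind). Significance tiers
#' follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param cfg An [experiment_config()].
#' @param features Optional precomputed result of [extract_features()]
#'   (skips simulation).
#' @return An object of class `classification_report`: list with `table`
#'   (one row per pair x kind), `accuracies`, `controls` and `manifest`.
#' @export
run_experiment <- function(cfg, features = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  manifest <- list(parameter = cfg$parameter, values = cfg$values,
                   n_cells_per_class = cfg$n_cells_per_class,
                   l_max = cfg$l_max, n_time = cfg$n_time,
                   grid_size = cfg$grid_size, seed = cfg$seed,
                   scheme = cfg$cv$scheme,
                   time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (is.null(features)) {
    data <- generate_dataset(cfg)
    features <- extract_features(data$tracks, class = data$class,
                                 cell_id = data$cell_id,
                                 l_max = cfg$l_max, n_time = cfg$n_time,
                                 grid_size = cfg$grid_size)
    manifest$cell_seeds <- data$seeds
  }
  manifest$excluded <- features$excluded
  kinds <- c("static", "time", "frequency")
  pairs <- .class_pairs(features$static$class)
  cv_run <- function(ds, cfg_cv) {
    if (cfg_cv$scheme == "shuffle") cv_stratified_shuffle(ds, cfg_cv)
    else cv_group_shuffle(ds, cfg_cv)
  }
  pair_name <- function(p) paste(p, collapse = " vs ")
  accuracies <- list()
  controls <- list()
  rows <- list()
  for (kind in kinds) {
    ds_all <- features[[kind]]
    # per-pair accuracies and per-pair random controls, pooled across pairs
    pair_ctrl <- list()
    for (p in pairs) {
      sub <- .ds_subset(ds_all, ds_all$class %in% p)
      key <- paste(kind, pair_name(p), sep = " | ")
      accuracies[[key]] <- cv_run(sub, cfg$cv)
      if (is_balanced(sub$class, cfg$cv$balance_threshold)) {
        pair_ctrl[[pair_name(p)]] <- control_random_accuracy(sub, cfg$cv)
      } else {
        pair_ctrl[[pair_name(p)]] <-
          control_majority_accuracy(sub, n_rounds = 150L,
                                    seed = cfg$cv$seed + 2L)
        attr(pair_ctrl[[pair_name(p)]], "kind") <- "majority"
      }
    }
    pooled <- unlist(pair_ctrl, use.names = FALSE)
    controls[[kind]] <- list(per_pair = pair_ctrl, pooled = pooled)
    for (p in pairs) {
      pn <- pair_name(p)
      key <- paste(kind, pn, sep = " | ")
      ctrl_kind <- attr(pair_ctrl[[pn]], "kind")
      ctrl <- if (is.null(ctrl_kind)) pooled else pair_ctrl[[pn]]
      ctrl_kind <- if (is.null(ctrl_kind)) "random" else ctrl_kind
      acc <- accuracies[[key]]
      p_ctrl <- compare_accuracies(acc, ctrl)
      p_static <- if (kind == "static") NA_real_ else
        compare_accuracies(acc, accuracies[[paste("static", pn,
                                                  sep = " | ")]])
      p_time <- if (kind != "frequency") NA_real_ else
        compare_accuracies(acc, accuracies[[paste("time", pn,
                                                  sep = " | ")]])
      n_a <- sum(ds_all$class == p[1])
      n_b <- sum(ds_all$class == p[2])
      rows[[length(rows) + 1]] <- data.frame(
        pair = pn, feature_kind = kind, n_class_a = n_a, n_class_b = n_b,
        control_kind = ctrl_kind,
        mean_accuracy = mean(acc, na.rm = TRUE),
        mean_control = mean(ctrl),
        p_vs_control = p_ctrl,
        sig_vs_control = significance_tier(p_ctrl),
        p_vs_static = p_static, p_vs_dynamic_time = p_time)
    }
  }
  structure(list(table = do.call(rbind, rows), accuracies = accuracies,
                 controls = controls, manifest = manifest),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (", x$manifest$parameter, " = ",
      paste(x$manifest$values, collapse = "/"), ", ",
      x$manifest$n_cells_per_class, " cells/class, scheme ",
      x$manifest$scheme, ")\n\n", sep = "")
  df <- x$table
  df$mean_accuracy <- sprintf("%.3f", df$mean_accuracy)
  df$mean_control <- sprintf("%.3f", df$mean_control)
  df$p_vs_control <- format.pval(df$p_vs_control, digits = 2)
  print(df[, c("pair", "feature_kind", "mean_accuracy", "mean_control",
               "p_vs_control", "sig_vs_control")], row.names = FALSE)
  invisible(x)
}

#' Write a classification report table as CSV
#'
#' @param report A `classification_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
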