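# Linear-SVM classification harness: cross-validation schemes, balance
# rule, naive-classifier controls and Mann-Whitney significance tests.
#
# Individual migrating cells -- never individual time points of the same
# cell -- are the independent observations. Multi-class problems are always
# decomposed into two-class comparisons.

#' Bundle feature vectors with cell annotations
#'
#' @param features Numeric n x p matrix, one row per cell.
#' @param cell_id Character/integer cell identifiers.
#' @param class Class label per cell (>= 2 distinct values for
#'   classification calls).
#' @param group_id Optional time-series (imaging session) key per cell;
#'   required by the group-shuffle scheme and the majority control.
#' @param feature_kind Tag: `"static"`, `"time"`, `"frequency"` (free
#'   form).
#' @return An object of class `shape_dataset`.
#' @export
shape_dataset <- function(features, cell_id, class, group_id = NULL,
                          feature_kind = "static") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(cell_id) != n || length(class) != n)
    stop("'cell_id' and 'class' must have one entry per feature row")
  if (!is.null(group_id) && length(group_id) != n)
    stop("'group_id' must have one entry per feature row")
  if (anyNA(features)) stop("features must not contain missing values")
  structure(list(features = features, cell_id = as.character(cell_id),
                 class = as.character(class),
                 group_id = if (is.null(group_id)) NULL
                            else as.character(group_id),
                 feature_kind = feature_kind),
            class = "shape_dataset")
}

#' @export
print.shape_dataset <- function(x, ...) {
  cat("Shape dataset (", x$feature_kind, "): ", nrow(x$features),
      " cells x ", ncol(x$features), " features; classes: ",
      paste(sprintf("%s (%d)", names(table(x$class)), table(x$class)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# subset of a shape_dataset by row index
.ds_subset <- function(ds, idx) {
  shape_dataset(ds$features[idx, , drop = FALSE], ds$cell_id[idx],
                ds$class[idx],
                if (is.null(ds$group_id)) NULL else ds$group_id[idx],
                ds$feature_kind)
}

#' Write or read a feature table as CSV
#'
#' One row per cell: columns `cell_id`, `group_id`, `class`,
#' `feature_kind`, then `f_0 ... f_{p-1}`.
#'
#' @param ds A `shape_dataset`.
#' @param path File path.
#' @return `read_features()` returns a `shape_dataset`.
#' @export
write_features <- function(ds, path) {
  stopifnot(inherits(ds, "shape_dataset"))
  p <- ncol(ds$features)
  df <- data.frame(cell_id = ds$cell_id,
                   group_id = if (is.null(ds$group_id)) "" else ds$group_id,
                   class = ds$class, feature_kind = ds$feature_kind,
                   ds$features)
  names(df)[-(1:4)] <- paste0("f_", seq_len(p) - 1)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, colClasses = c(cell_id = "character",
                                      group_id = "character",
                                      class = "character"))
  fcols <- grep("^f_\\d+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f_", "", fcols)))]
  if (length(fcols) == 0) stop("no feature columns f_0, f_1, ... in ", path)
  gid <- df$group_id
  if (all(is.na(gid)) || all(gid == "")) gid <- NULL
  shape_dataset(as.matrix(df[, fcols, drop = FALSE]), df$cell_id, df$class,
                gid, df$feature_kind[1])
}

#' Cross-validation configuration
#'
#' @param scheme `"shuffle"` (stratified shuffle split: random
#'   class-balanced train/test cells each round) or `"group_shuffle"`
#'   (one whole time series per class held out each round; a group is
#'   never split between train and test).
#' @param n_rounds Number of cross-validation rounds.
#' @param n_train_per_class,n_test_per_class Cells per class in the train
#'   and test split (shuffle scheme).
#' @param balance_threshold A dataset is balanced when no class holds more
#'   than this fraction of cells.
#' @param standardize Standardise features by training-set mean/sd each
#'   round (off by default; margin classifiers are scale-sensitive, so the
#'   flag is exposed).
#' @param cost SVM regularisation constant, held fixed (not tuned).
#' @param seed Master seed; per-round seeds are derived deterministically
#'   from it, so any single round is reproducible in isolation.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(scheme = c("shuffle", "group_shuffle"),
                      n_rounds = 150L, n_train_per_class = 50L,
                      n_test_per_class = 20L, balance_threshold = 0.60,
                      standardize = FALSE, cost = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  n_rounds <- as.integer(n_rounds)
  if (n_rounds < 1) stop("'n_rounds' must be >= 1")
  if (balance_threshold <= 0.5 || balance_threshold >= 1)
    stop("'balance_threshold' must be in (0.5, 1)")
  structure(list(scheme = scheme, n_rounds = n_rounds,
                 n_train_per_class = as.integer(n_train_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 balance_threshold = balance_threshold,
                 standardize = isTRUE(standardize), cost = cost,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# deterministic per-round seeds derived from a master seed
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit a linear maximum-margin classifier
#'
#' Linear-kernel support vector machine (C-classification, fixed cost) on
#' cell feature vectors.
#'
#' @param x Numeric n x p feature matrix.
#' @param y Class labels (>= 2 classes present).
#' @param cost Regularisation constant (fixed default 1; deliberately not
#'   tuned so that controls and comparisons hold it constant).
#' @return A fitted `svm` model (predict with `predict(model, newx)`).
#' @export
fit_linear_classifier <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2)
    stop("need at least 2 classes to fit a classifier, got ", nlevels(y))
  if (anyNA(x)) stop("features must not contain missing values")
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE,
             type = "C-classification")
}

.fit_predict_accuracy <- function(xtr, ytr, xte, yte, cost, standardize) {
  if (standardize) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xtr <- scale(xtr, mu, sdv)
    xte <- scale(xte, mu, sdv)
  }
  fit <- fit_linear_classifier(xtr, ytr, cost)
  mean(as.character(predict(fit, xte)) == as.character(yte))
}

#' Stratified-shuffle-split cross-validation accuracy
#'
#' In each of `n_rounds` rounds, `n_train_per_class` cells per class are
#' drawn at random for training and `n_test_per_class` of the remaining
#' cells per class for testing (all remaining cells if fewer). Train and
#' test are disjoint by construction.
#'
#' @param ds A `shape_dataset`.
#' @param cfg A [cv_config()].
#' @return Numeric vector of `n_rounds` test accuracies in `[0, 1]`.
#' @export
cv_stratified_shuffle <- function(ds, cfg) {
  stopifnot(inherits(ds, "shape_dataset"), inherits(cfg, "cv_config"))
  classes <- sort(unique(ds$class))
  if (length(classes) < 2) stop("need >= 2 classes")
  counts <- table(ds$class)
  short <- names(counts)[counts < cfg$n_train_per_class + 1]
  if (length(short))
    stop("insufficient cells for class ", paste(short, collapse = ", "),
         ": need at least n_train_per_class + 1 = ",
         cfg$n_train_per_class + 1)
  seeds <- .derive_seeds(cfg$seed, cfg$n_rounds)
  vapply(seq_len(cfg$n_rounds), function(r) {
    set.seed(seeds[r])
    tr <- te <- integer(0)
    for (cl in classes) {
      idx <- which(ds$class == cl)
      tr_cl <- sample(idx, cfg$n_train_per_class)
      rest <- setdiff(idx, tr_cl)
      te_cl <- if (length(rest) > cfg$n_test_per_class)
        sample(rest, cfg$n_test_per_class) else rest
      tr <- c(tr, tr_cl)
      te <- c(te, te_cl)
    }
    .fit_predict_accuracy(ds$features[tr, , drop = FALSE], ds$class[tr],
                          ds$features[te, , drop = FALSE], ds$class[te],
                          cfg$cost, cfg$standardize)
  }, numeric(1))
}

#' Group-shuffle-split cross-validation accuracy
#'
#' In each round, one randomly chosen group (time series) per class forms
#' the test set and all remaining groups the training set, so cells from
#' the same series are never split between train and test.
#'
#' @param ds A `shape_dataset` with `group_id` set.
#' @param cfg A [cv_config()].
#' @return Numeric vector of `n_rounds` test accuracies.
#' @export
cv_group_shuffle <- function(ds, cfg) {
  stopifnot(inherits(ds, "shape_dataset"), inherits(cfg, "cv_config"))
  if (is.null(ds$group_id)) stop("group-shuffle CV needs 'group_id'")
  classes <- sort(unique(ds$class))
  if (length(classes) < 2) stop("need >= 2 classes")
  grp_by_class <- lapply(classes, function(cl)
    unique(ds$group_id[ds$class == cl]))
  names(grp_by_class) <- classes
  single <- classes[lengths(grp_by_class) < 2]
  if (length(single))
    stop("class ", paste(single, collapse = ", "),
         " has a single group; group-shuffle CV needs >= 2 groups per class")
  seeds <- .derive_seeds(cfg$seed, cfg$n_rounds)
  vapply(seq_len(cfg$n_rounds), function(r) {
    set.seed(seeds[r])
    test_groups <- vapply(classes, function(cl)
      sample(grp_by_class[[cl]], 1), character(1))
    te <- which(ds$group_id %in% test_groups)
    tr <- setdiff(seq_along(ds$class), te)
    if (length(unique(ds$class[tr])) < 2) return(NA_real_)
    .fit_predict_accuracy(ds$features[tr, , drop = FALSE], ds$class[tr],
                          ds$features[te, , drop = FALSE], ds$class[te],
                          cfg$cost, cfg$standardize)
  }, numeric(1))
}

#' Balance rule
#'
#' A dataset is balanced when no class contains strictly more than
#' `threshold` (default 60%) of all cells; exactly 60% still counts as
#' balanced.
#'
#' @param labels Class label per cell.
#' @param threshold Balance threshold fraction.
#' @return `TRUE` if balanced.
#' @examples
#' is_balanced(rep(c("a", "b"), c(60, 40)))  # TRUE
#' is_balanced(rep(c("a", "b"), c(61, 39)))  # FALSE
#' @export
is_balanced <- function(labels, threshold = 0.60) {
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  max(table(labels)) / length(labels) <= threshold + 1e-12
}

#' Random-classifier control accuracies
#'
#' Estimates the chance-level accuracy distribution by shuffling class
#' labels and re-running cross-validation. With the `"shuffle"` scheme
#' (synthetic data): 5 label shuffles x 10 CV rounds = 50 control values
#' per class pair; pooling the three pairs of a 3-class set gives the 150
#' control values used for testing. With `"group_shuffle"` (grouped data):
#' 15 shuffles x 10 rounds = 150 values per pair; labels are permuted at
#' the group level so that whole time series keep a single (random) label
#' and the group-shuffle machinery stays valid.
#'
#' @param ds A balanced two-class `shape_dataset`.
#' @param cfg A [cv_config()]; `cfg$scheme` selects the control recipe and
#'   `cfg$seed` the randomness.
#' @param n_shuffles,n_rounds_per_shuffle Override the per-scheme defaults
#'   (5 x 10 for `"shuffle"`, 15 x 10 for `"group_shuffle"`).
#' @return Numeric vector of control accuracies (50 or 150 values).
#' @export
control_random_accuracy <- function(ds, cfg, n_shuffles = NULL,
                                    n_rounds_per_shuffle = 10L) {
  stopifnot(inherits(ds, "shape_dataset"), inherits(cfg, "cv_config"))
  if (!is_balanced(ds$class, cfg$balance_threshold))
    stop("dataset is unbalanced (a class holds more than ",
         round(100 * cfg$balance_threshold), "% of cells); ",
         "use control_majority_accuracy()")
  if (is.null(n_shuffles))
    n_shuffles <- if (cfg$scheme == "shuffle") 5L else 15L
  shuffle_seeds <- .derive_seeds(cfg$seed + 1L, n_shuffles)
  out <- lapply(seq_len(n_shuffles), function(s) {
    set.seed(shuffle_seeds[s])
    ds2 <- ds
    if (cfg$scheme == "shuffle") {
      ds2$class <- sample(ds$class)
    } else {
      groups <- unique(ds$group_id)
      glab <- vapply(groups, function(g)
        ds$class[match(g, ds$group_id)], character(1))
      glab <- sample(glab)  # permute which series carries which label
      names(glab) <- groups
      ds2$class <- unname(glab[ds$group_id])
    }
    sub_cfg <- cfg
    sub_cfg$n_rounds <- as.integer(n_rounds_per_shuffle)
    sub_cfg$seed <- shuffle_seeds[s]
    if (cfg$scheme == "shuffle") cv_stratified_shuffle(ds2, sub_cfg)
    else cv_group_shuffle(ds2, sub_cfg)
  })
  unlist(out)
}

#' Majority-classifier control accuracies
#'
#' Control for unbalanced grouped data: in each round one time series per
#' class is drawn at random, all drawn cells are assigned to the overall
#' majority class, and the resulting accuracy (the majority fraction of
#' the drawn cells) is recorded.
#'
#' @param ds A `shape_dataset` with `group_id` set.
#' @param n_rounds Number of draws (default 150).
#' @param seed Seed for the draws.
#' @return Numeric vector of `n_rounds` control accuracies.
#' @export
control_majority_accuracy <- function(ds, n_rounds = 150L, seed = 1L) {
  stopifnot(inherits(ds, "shape_dataset"))
  if (is.null(ds$group_id)) stop("the majority control needs 'group_id'")
  classes <- sort(unique(ds$class))
  grp_by_class <- lapply(classes, function(cl)
    unique(ds$group_id[ds$class == cl]))
  if (any(lengths(grp_by_class) == 0)) stop("a class has no groups")
  majority <- names(which.max(table(ds$class)))
  seeds <- .derive_seeds(seed, n_rounds)
  vapply(seq_len(as.integer(n_rounds)), function(r) {
    set.seed(seeds[r])
    gsel <- vapply(seq_along(classes), function(i)
      sample(grp_by_class[[i]], 1), character(1))
    drawn <- ds$class[ds$group_id %in% gsel]
    mean(drawn == majority)
  }, numeric(1))
}

#' One-sided Mann-Whitney comparison of accuracy distributions
#'
#' Tests H1: the first accuracy sample is stochastically greater than the
#' second (Mann-Whitney U; mid-ranks with normal approximation and tie
#' correction for large samples, exact for small untied samples).
#'
#' @param a,b Numeric accuracy vectors.
#' @return The one-sided p-value.
#' @export
compare_accuracies <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty accuracy vector")
  suppressWarnings(wilcox.test(a, b, alternative = "greater"))$p.value
}

#' Significance tier annotation
#'
#' @param p P-value(s).
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or
#'   `"ns"`.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}

#' Tune the feature-vector size for maximal CV accuracy
#'
#' Evaluates mean cross-validation accuracy for every combination of
#' `l_max` and `n_time` and returns the maximising pair; ties break toward
#' the smaller feature vector.
#'
#' @param builder Function `(l_max, n_time) -> shape_dataset`.
#' @param l_max_grid,n_time_grid Candidate values.
#' @param cfg A [cv_config()].
#' @return List with `l_max`, `n_time`, `accuracy` and the full `table`
#'   of mean accuracies.
#' @export
tune_feature_params <- function(builder, l_max_grid, n_time_grid, cfg) {
  stopifnot(length(l_max_grid) > 0, length(n_time_grid) > 0)
  grid <- expand.grid(l_max = as.integer(l_max_grid),
                      n_time = as.integer(n_time_grid))
  grid$size <- grid$l_max * grid$n_time
  grid <- grid[order(grid$size, grid$l_max), ]
  grid$accuracy <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    ds <- builder(grid$l_max[i], grid$n_time[i])
    acc <- if (cfg$scheme == "shuffle") cv_stratified_shuffle(ds, cfg)
           else cv_group_shuffle(ds, cfg)
    grid$accuracy[i] <- mean(acc, na.rm = TRUE)
    if (is.null(best) || grid$accuracy[i] > best$accuracy + 1e-12)
      best <- list(l_max = grid$l_max[i], n_time = grid$n_time[i],
                   accuracy = grid$accuracy[i])
  }
  best$table <- grid[, c("l_max", "n_time", "accuracy")]
  best
}
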