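# Linear-SVM cross-validation harness, controls, significance tests

test_that("the linear classifier separates separable data deterministically", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  y <- rep(c("a", "b"), each = 20)
  fit <- fit_linear_classifier(x, y)
  expect_equal(mean(as.character(predict(fit, x)) == y), 1)
  # row-order permutation leaves predictions unchanged
  perm <- sample(seq_along(y))
  fit2 <- fit_linear_classifier(x[perm, ], y[perm])
  xnew <- matrix(rnorm(20), 10)
  expect_identical(as.character(predict(fit, xnew)),
                   as.character(predict(fit2, xnew)))
  expect_error(fit_linear_classifier(x, rep("a", 40)), "2 classes")
})

test_that("stratified shuffle CV returns n_rounds accuracies at chance for null data", {
  ds <- toy_dataset(70, delta = 0, seed = 2)
  cfg <- cv_config("shuffle", n_rounds = 150, n_train_per_class = 50,
                   n_test_per_class = 20, seed = 3)
  acc <- cv_stratified_shuffle(ds, cfg)
  expect_length(acc, 150)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_lt(abs(mean(acc) - 0.5), 0.05)
  # strong signal is found
  ds2 <- toy_dataset(70, delta = 6, seed = 2)
  expect_gt(mean(cv_stratified_shuffle(ds2, cfg)), 0.95)
  # errors name the deficient class
  small <- toy_dataset(30, seed = 1)
  expect_error(cv_stratified_shuffle(small, cfg), "class a")
})

test_that("CV rounds are reproducible and seed-dependent", {
  ds <- toy_dataset(30, delta = 1, seed = 4)
  cfg <- cv_config("shuffle", n_rounds = 20, n_train_per_class = 20,
                   n_test_per_class = 10, seed = 5)
  expect_identical(cv_stratified_shuffle(ds, cfg),
                   cv_stratified_shuffle(ds, cfg))
  cfg2 <- cv_config("shuffle", n_rounds = 20, n_train_per_class = 20,
                    n_test_per_class = 10, seed = 6)
  expect_false(identical(cv_stratified_shuffle(ds, cfg),
                         cv_stratified_shuffle(ds, cfg2)))
})

test_that("group shuffle CV never leaks group information", {
  # group-confounded features: each series has its own mean shift but the
  # classes are identical in distribution -- held-out-group accuracy must
  # stay at chance even though within-group classification would be easy
  ds <- toy_dataset(36, delta = 0, n_groups = 6, group_delta = 3, seed = 7)
  cfg <- cv_config("group_shuffle", n_rounds = 100, seed = 8)
  acc <- cv_group_shuffle(ds, cfg)
  expect_length(acc, 100)
  ctrl <- control_random_accuracy(ds, cfg)
  expect_gt(compare_accuracies(acc, ctrl), 0.05)
  # sanity: the same data classified ignoring groups overfits to them
  cfg_s <- cv_config("shuffle", n_rounds = 50, n_train_per_class = 24,
                     n_test_per_class = 12, seed = 8)
  expect_gt(mean(cv_stratified_shuffle(ds, cfg_s)), mean(acc))
  # single-group classes are rejected
  ds1 <- toy_dataset(10, n_groups = 1, seed = 1)
  expect_error(cv_group_shuffle(ds1, cfg), "single group")
})

test_that("the balance rule uses a strict greater-than-60% cut", {
  expect_true(is_balanced(rep(c("a", "b"), c(70, 70))))
  expect_true(is_balanced(rep(c("a", "b"), c(60, 40))))   # exactly 60%
  expect_false(is_balanced(rep(c("a", "b"), c(61, 39))))  # 61% > 60%
  expect_true(is_balanced(rep(c("a", "b"), c(3, 2))))     # 60% again
  expect_error(is_balanced(rep("a", 5)), "2 classes")
})

test_that("random controls produce the prescribed counts at chance level", {
  ds <- toy_dataset(70, delta = 3, seed = 9)
  cfg <- cv_config("shuffle", n_rounds = 150, n_train_per_class = 50,
                   n_test_per_class = 20, seed = 10)
  ctrl <- control_random_accuracy(ds, cfg)
  expect_length(ctrl, 50)  # 5 shuffles x 10 rounds per class pair
  expect_lt(abs(mean(ctrl) - 0.5), 0.05)
  # grouped scheme: 15 x 10 = 150 per pair
  dsg <- toy_dataset(36, n_groups = 6, seed = 11)
  cfgg <- cv_config("group_shuffle", n_rounds = 150, seed = 12)
  ctrlg <- control_random_accuracy(dsg, cfgg)
  expect_length(ctrlg, 150)
  expect_lt(abs(mean(ctrlg, na.rm = TRUE) - 0.5), 0.07)
  # unbalanced data are rejected towards the majority control
  ds_unb <- shape_dataset(matrix(rnorm(200), 100), paste0("c", 1:100),
                          rep(c("a", "b"), c(65, 35)))
  expect_error(control_random_accuracy(ds_unb, cfg), "majority")
})

test_that("majority-control accuracy equals the majority fraction of the draw", {
  # every class-a series has 7 cells, every class-b series 3; majority = a
  cls <- rep(c("a", "b"), c(70, 30))
  gid <- c(paste0("a_s", rep(1:10, each = 7)), paste0("b_s", rep(1:10, each = 3)))
  ds <- shape_dataset(matrix(0, 100, 2), paste0("c", 1:100), cls, gid)
  ctrl <- control_majority_accuracy(ds, n_rounds = 150, seed = 13)
  expect_length(ctrl, 150)
  expect_true(all(ctrl == 0.7))  # 7 of 10 drawn cells belong to class a
})

test_that("one-sided Mann-Whitney comparison behaves at the null and the extreme", {
  # identical distributions: p stays non-significant in >= 90% of draws
  set.seed(14)
  p_null <- replicate(40, {
    a <- sample(seq(0, 1, by = 0.05), 150, replace = TRUE)
    b <- sample(seq(0, 1, by = 0.05), 150, replace = TRUE)
    compare_accuracies(a, b)
  })
  expect_gte(mean(p_null > 0.05), 0.9)
  # complete separation at n = 150 per group
  a <- runif(150, 0.8, 1)
  b <- runif(150, 0, 0.2)
  expect_lt(compare_accuracies(a, b), 1e-6)
  # swapped arguments are complementary
  expect_gt(compare_accuracies(b, a), 0.999)
  expect_error(compare_accuracies(numeric(0), a), "empty")
})

test_that("feature-size tuning maximises accuracy with ties towards smaller vectors", {
  cfg <- cv_config("shuffle", n_rounds = 10, n_train_per_class = 14,
                   n_test_per_class = 6, seed = 15)
  # signal only in the first 3 feature dimensions; larger l_max adds noise
  builder <- function(l_max, n_time) {
    set.seed(100 + l_max)
    n <- 40
    x <- matrix(rnorm(n * l_max), n, l_max)
    cls <- rep(c("a", "b"), each = n / 2)
    x[cls == "b", seq_len(min(3, l_max))] <-
      x[cls == "b", seq_len(min(3, l_max))] + 5
    shape_dataset(x, paste0("c", 1:n), cls)
  }
  single <- tune_feature_params(builder, 4, 1, cfg)
  expect_equal(single$l_max, 4)
  expect_equal(single$n_time, 1)
  tuned <- tune_feature_params(builder, c(3, 8), 1, cfg)
  # both sizes classify perfectly; the tie breaks to the smaller vector
  expect_equal(tuned$l_max, 3)
  expect_equal(nrow(tuned$table), 2)
})

test_that("feature tables round-trip through CSV", {
  ds <- toy_dataset(5, n_groups = 2, seed = 16, kind = "frequency")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(ds, path)
  back <- read_features(path)
  expect_equal(back$features, ds$features, ignore_attr = TRUE)
  expect_identical(back$class, ds$class)
  expect_identical(back$group_id, ds$group_id)
  expect_identical(back$feature_kind, "frequency")
})
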