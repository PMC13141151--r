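test_that("the quantile labeling rule is strict on both conjuncts", {
  f <- tibble::tibble(q80 = c(80, 150, 200, 199.9),
                      q99 = c(99, 250, 150, 199.9))
  expect_equal(label_by_rule(f), c(1L, 0L, 0L, 1L))
  attr(f, "unit_kind") <- c("concentration")
  expect_error(label_by_rule(f), "concentration")
})

test_that("raising the threshold can only move labels 0 -> 1", {
  withr::with_seed(21, {
    f <- tibble::tibble(q99 = runif(400, 0, 500))
    f$q80 <- f$q99 * runif(400, 0.3, 1)
    prev <- label_by_rule(f, 100)
    for (th in seq(125, 400, by = 25)) {
      cur <- label_by_rule(f, th)
      expect_true(all(cur >= prev))
      prev <- cur
    }
  })
})

test_that("the benchmark training table labels M stochastic, P deterministic", {
  corp <- structure(
    list(models = list(benchmark = benchmark_model()),
         metadata = tibble::tibble(model_id = "benchmark",
                                   family = "benchmark", seed_offset = 1L,
                                   n_species = 2L),
         spec = corpus_spec(n_models = 1L)),
    class = "corpus")
  tab <- build_training_table(corp, horizon = 100, n_grid = 501)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$label[tab$species == "M"], 1L)
  expect_equal(tab$label[tab$species == "P"], 0L)
})

test_that("an empty corpus yields an empty training table", {
  tab <- build_training_table(empty_corpus())
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("model_id", "species", "label") %in% names(tab)))
})

test_that("the forest recovers a linearly separable rule exactly", {
  tab <- toy_examples()
  pm <- train_partition_model(tab, n_trees = 100L, seed = 5L)
  expect_identical(pm$decision_threshold, 0.5)
  pred <- predict(pm, tab)
  expect_equal(pred$label, tab$label)
  # calibrator pushes out-of-fold probabilities to the extremes
  expect_lte(max(pred$probability[tab$label == 0L]), 0.2)
  expect_gte(min(pred$probability[tab$label == 1L]), 0.8)
  # LOMO evaluation is perfect
  rep <- evaluate_lomo(tab, n_trees = 100L, seed = 5L)
  expect_equal(rep$mean_balanced_accuracy, 1)
  expect_equal(rep$pooled_mcc, 1)
})

test_that("training and prediction are deterministic given the seed", {
  tab <- toy_examples()
  p1 <- predict(train_partition_model(tab, n_trees = 50L, seed = 3L), tab)
  p2 <- predict(train_partition_model(tab, n_trees = 50L, seed = 3L), tab)
  expect_identical(p1, p2)
})

test_that("degenerate training tables are refused", {
  tab <- toy_examples()
  one_model <- dplyr::filter(tab, model_id == "toy_01")
  expect_error(train_partition_model(one_model), "2 models")
  single_class <- dplyr::mutate(tab, label = 1L)
  expect_error(train_partition_model(single_class), "single class")
  expect_error(evaluate_lomo(dplyr::filter(
    tab, model_id %in% c("toy_01", "toy_02"))), "3 models")
})

test_that("the isotonic calibrator is monotone non-decreasing", {
  pm <- train_partition_model(toy_examples(), n_trees = 100L, seed = 5L)
  expect_true(all(diff(pm$calibrator$y) >= -1e-12))
  grid_feats <- tibble::tibble(
    mean = seq(1, 3000, length.out = 50), q50 = mean, q80 = mean,
    q99 = seq(1, 3000, length.out = 50))
  pr <- predict(pm, grid_feats)
  # calibrated probability non-increasing as q99 rises through the rule
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})

test_that("confusion-matrix metrics match hand-computed values", {
  # one fold with TP=3, FN=2, TN=4, FP=1 via the mean heuristic
  tab <- tibble::tibble(
    model_id = "m1",
    species = sprintf("s%d", 1:10),
    label = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    mean = c(10, 20, 30, 500, 600, 900, 800, 700, 650, 100),
    q50 = 1, q80 = 1, q99 = 1
  )
  rep <- heuristic_baseline(tab, "mean", cutoff = 200)
  expect_equal(rep$folds$balanced_accuracy, (3 / 5 + 4 / 5) / 2)
  expect_equal(rep$folds$mcc, 10 / sqrt(600))

  # perfect fold and all-wrong fold
  perfect <- dplyr::mutate(tab, mean = ifelse(label == 1, 10, 900))
  expect_equal(heuristic_baseline(perfect, "mean")$folds$balanced_accuracy, 1)
  expect_equal(heuristic_baseline(perfect, "mean")$folds$mcc, 1)
  wrong <- dplyr::mutate(tab, mean = ifelse(label == 1, 900, 10))
  expect_equal(heuristic_baseline(wrong, "mean")$folds$balanced_accuracy, 0)
  expect_equal(heuristic_baseline(wrong, "mean")$folds$mcc, -1)
})

test_that("burst-like trajectories split the rule from the heuristics", {
  # transient spike: mean low, q99 high -- rule says deterministic,
  # abundance heuristics say stochastic
  burst <- tibble::tibble(q80 = 40, q99 = 5000, mean = 150, q50 = 30)
  expect_equal(label_by_rule(burst), 0L)
  expect_true(burst$mean < 200 && burst$q50 < 200) # heuristics would say 1
  tab <- toy_examples()
  tab$mean[1] <- 150
  tab$q50[1] <- 30
  tab$q80[1] <- 40
  tab$q99[1] <- 5000
  tab$label[1] <- 0L
  hm <- heuristic_baseline(tab, "mean")
  expect_lt(hm$folds$balanced_accuracy[1], 1) # the disagreement surfaces
})

test_that("constant features give chance-level balanced accuracy", {
  tab <- tibble::tibble(
    model_id = rep(c("a", "b"), each = 8),
    species = sprintf("s%d", 1:16),
    label = rep(c(0L, 1L), 8),
    mean = 100, q50 = 100, q80 = 100, q99 = 100
  )
  rep <- heuristic_baseline(tab, "mean") # everything predicted stochastic
  expect_equal(rep$mean_balanced_accuracy, 0.5)
})

test_that("threshold sensitivity reports zero flips at the baseline", {
  tab <- toy_examples()
  ts <- threshold_sensitivity(tab, thresholds = seq(150, 300, by = 25))
  expect_equal(ts$flip_fraction[ts$threshold == 200], 0)
  expect_true(all(ts$flip_fraction >= 0 & ts$flip_fraction <= 1))
  # no quantiles inside [150, 300): no flips anywhere
  expect_equal(max(ts$flip_fraction), 0)
  # one species at q80 = q99 = 250 in a 40-species table flips only at 300
  tab2 <- toy_examples(n_models = 4L, n_per = 10L)
  tab2$q80[1] <- 250
  tab2$q99[1] <- 250
  ts2 <- threshold_sensitivity(tab2, thresholds = c(200, 300))
  expect_equal(ts2$flip_fraction[ts2$threshold == 300], 1 / 40)
})

test_that("predict_partition classifies the benchmark correctly", {
  pm <- train_partition_model(toy_examples(), n_trees = 100L, seed = 5L)
  part <- predict_partition(benchmark_model(), pm, horizon = 100,
                            n_grid = 501)
  expect_equal(part$label[part$species == "M"], 1L)
  expect_equal(part$label[part$species == "P"], 0L)
  expect_true(all(part$probability >= 0 & part$probability <= 1))
  # feature-name mismatch is an error
  expect_error(predict(pm, tibble::tibble(a = 1)), "feature-name mismatch")
})
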