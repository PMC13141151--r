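# Regime classifier: quantile labeling rule, random-forest training with
# isotonic calibration, leave-one-model-out evaluation, threshold
# sensitivity and abundance-heuristic baselines.

#' Label species by the abundance-quantile rule
#'
#' The conservative ground-truth rule for regime labels: a species is
#' labeled stochastic (1) iff both the 0.80 and the 0.99 quantile of its
#' deterministic trajectory lie strictly below the threshold (200 molecules
#' by default); otherwise deterministic (0).
#'
#' @param features Feature tibble from [extract_features()] (needs columns
#'   `q80` and `q99`, in molecule units). Features computed from a
#'   concentration-unit trajectory are refused: convert the model with
#'   [convert_to_counts()] first.
#' @param threshold Molecule-count threshold (strict `<` on both quantiles).
#' @return Integer vector of labels (1 stochastic, 0 deterministic), one per
#'   row of `features`.
#' @examples
#' label_by_rule(tibble::tibble(q80 = 80, q99 = 99)) # 1
#' label_by_rule(tibble::tibble(q80 = 150, q99 = 250)) # 0
#' @export
label_by_rule <- function(features, threshold = 200) {
  stopifnot(is.data.frame(features),
            all(c("q80", "q99") %in% names(features)))
  uk <- attr(features, "unit_kind")
  if (!is.null(uk) && any(uk == "concentration")) {
    stop("features were extracted from a concentration-unit trajectory; ",
         "convert the model to molecule counts first", call. = FALSE)
  }
  as.integer(features$q80 < threshold & features$q99 < threshold)
}

#' Build a labeled training table from a corpus
#'
#' Runs the deterministic pre-simulation and feature extraction for every
#' model of the corpus and labels each species with [label_by_rule()].
#' Models whose pre-simulation fails are skipped with a warning and listed
#' in the `skipped` attribute.
#'
#' @param corpus A `corpus` from [generate_corpus()] (models in count units).
#' @param horizon,n_grid,rtol,atol Pre-simulation settings; `horizon`
#'   defaults to the corpus spec's `presim_horizon`.
#' @param threshold Labeling threshold (molecules).
#' @return A tibble with columns `model_id`, `species`, `label` and the 18
#'   feature columns; deterministic given corpus and settings.
#' @export
build_training_table <- function(corpus, horizon = NULL, n_grid = 2001L,
                                 rtol = 1e-6, atol = 1e-9, threshold = 200) {
  stopifnot(inherits(corpus, "corpus"))
  horizon <- horizon %||% corpus$spec$presim_horizon
  skipped <- character()
  rows <- lapply(names(corpus$models), function(id) {
    model <- corpus$models[[id]]
    feats <- tryCatch({
      traj <- run_presim(model, horizon = horizon, n_grid = n_grid,
                         rtol = rtol, atol = atol)
      extract_features(traj)
    }, error = function(e) {
      warning("pre-simulation failed for ", id, " (skipped): ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(feats)) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(model_id = id),
                     feats[, "species", drop = FALSE],
                     tibble::tibble(label = label_by_rule(feats, threshold)),
                     feats[, setdiff(names(feats), "species")])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(model_id = character(), species = character(),
                          label = integer())
  }
  attr(out, "skipped") <- skipped
  out
}

feature_columns <- function(examples) {
  setdiff(names(examples), c("model_id", "species", "label"))
}

fit_forest <- function(x, y, n_trees, seed, mtry = NULL) {
  y <- factor(y, levels = c(0L, 1L))
  tab <- table(y)
  cw <- as.numeric(sum(tab) / (2 * pmax(tab, 1L)))
  ranger::ranger(
    x = as.data.frame(x), y = y, probability = TRUE,
    num.trees = n_trees, mtry = mtry %||% floor(sqrt(ncol(x))),
    min.node.size = 1L, class.weights = cw, seed = seed,
    num.threads = 1L, importance = "impurity"
  )
}

forest_prob <- function(forest, x) {
  pr <- stats::predict(forest, data = as.data.frame(x),
                       num.threads = 1L)$predictions
  unname(pr[, "1"])
}

#' Train the random-forest partition model
#'
#' Fits a probability random forest (balanced class weights, `sqrt(F)`
#' candidate features per split, seeded) on all labeled examples, obtains
#' out-of-fold probabilities by leave-one-model-out (LOMO) over the
#' `model_id` groups, fits an isotonic (monotone non-decreasing) calibrator
#' on the out-of-fold (probability, label) pairs, and packages everything
#' with the fixed decision threshold of 0.5.
#'
#' @param examples Training table from [build_training_table()]; needs at
#'   least two distinct models and both labels.
#' @param n_trees Number of trees.
#' @param seed Integer seed for the forest.
#' @param mtry Candidate features per split (default `floor(sqrt(F))`).
#' @return A `partition_model` object.
#' @export
train_partition_model <- function(examples, n_trees = 300L, seed = 1L,
                                  mtry = NULL) {
  stopifnot(is.data.frame(examples), "label" %in% names(examples))
  if (length(unique(examples$model_id)) < 2L) {
    stop("need examples from at least 2 models for LOMO calibration",
         call. = FALSE)
  }
  if (length(unique(examples$label)) < 2L) {
    stop("training data contain a single class; both regimes are required",
         call. = FALSE)
  }
  fcols <- feature_columns(examples)
  forest <- fit_forest(examples[fcols], examples$label, n_trees, seed, mtry)

  # LOMO out-of-fold probabilities for calibration
  oof <- rep(NA_real_, nrow(examples))
  for (id in unique(examples$model_id)) {
    hold <- examples$model_id == id
    train <- examples[!hold, ]
    if (length(unique(train$label)) < 2L) next
    f <- fit_forest(train[fcols], train$label, n_trees, seed, mtry)
    oof[hold] <- forest_prob(f, examples[hold, fcols])
  }
  ok <- which(!is.na(oof))
  ord <- ok[order(oof[ok])]
  iso <- stats::isoreg(oof[ord], examples$label[ord])
  cal_x <- iso$x
  cal_y <- pmin(pmax(iso$yf, 0), 1)

  structure(
    list(forest = forest,
         calibrator = list(x = cal_x, y = cal_y),
         decision_threshold = 0.5,
         feature_names = fcols,
         n_trees = n_trees, seed = seed,
         n_examples = nrow(examples),
         n_models = length(unique(examples$model_id))),
    class = "partition_model"
  )
}

calibrate_prob <- function(pm, p) {
  cal <- pm$calibrator
  xs <- cal$x
  ys <- cal$y
  if (length(unique(xs)) < 2L) return(pmin(pmax(p, 0), 1))
  out <- stats::approx(xs, ys, xout = p, rule = 2, ties = mean)$y
  pmin(pmax(out, 0), 1)
}

#' @export
print.partition_model <- function(x, ...) {
  cat("<partition_model> random forest (", x$n_trees, " trees) + isotonic ",
      "calibration\n  trained on ", x$n_examples, " species from ",
      x$n_models, " models; decision threshold ", x$decision_threshold,
      "\n", sep = "")
  invisible(x)
}

#' Predict regime probabilities for a feature table
#'
#' @param object A `partition_model`.
#' @param newdata Feature tibble with the model's feature columns.
#' @param ... Unused.
#' @return Tibble with `species` (if present in `newdata`),
#'   `raw_probability`, `probability` (calibrated) and `label`
#'   (1 iff calibrated probability >= 0.5; the tie at exactly 0.5 goes to the
#'   stochastic regime).
#' @export
predict.partition_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f) > 0L) {
    stop("feature-name mismatch: missing ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  raw <- forest_prob(object$forest, newdata[object$feature_names])
  p <- calibrate_prob(object, raw)
  out <- tibble::tibble(raw_probability = raw, probability = p,
                        label = as.integer(p >= object$decision_threshold))
  if ("species" %in% names(newdata)) {
    out <- dplyr::bind_cols(newdata[, "species", drop = FALSE], out)
  }
  out
}

#' @exportS3Method generics::tidy
tidy.partition_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @exportS3Method generics::glance
glance.partition_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_features = length(x$feature_names),
                 n_examples = x$n_examples, n_models = x$n_models,
                 oob_brier = x$forest$prediction.error,
                 decision_threshold = x$decision_threshold)
}

# confusion-matrix metrics -------------------------------------------------

confusion_counts <- function(truth, pred) {
  c(tp = sum(truth == 1L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L))
}

balanced_accuracy <- function(cc) {
  tpr <- if (cc["tp"] + cc["fn"] > 0) cc["tp"] / (cc["tp"] + cc["fn"]) else NA
  tnr <- if (cc["tn"] + cc["fp"] > 0) cc["tn"] / (cc["tn"] + cc["fp"]) else NA
  unname(mean(c(tpr, tnr), na.rm = TRUE))
}

mcc <- function(cc) {
  cc <- as.numeric(cc) # tp fn tn fp
  tp <- cc[1]; fn <- cc[2]; tn <- cc[3]; fp <- cc[4]
  if (tp + fn == 0 || tn + fp == 0) return(NA_real_) # single-class truth
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

new_classifier_report <- function(folds, method) {
  pooled <- c(tp = sum(folds$tp), fn = sum(folds$fn),
              tn = sum(folds$tn), fp = sum(folds$fp))
  structure(
    list(folds = folds,
         mean_balanced_accuracy = mean(folds$balanced_accuracy),
         mean_mcc = mean(folds$mcc, na.rm = TRUE),
         pooled_confusion = matrix(
           pooled[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE,
           dimnames = list(truth = c("1", "0"), predicted = c("1", "0"))),
         pooled_balanced_accuracy = balanced_accuracy(pooled),
         pooled_mcc = mcc(pooled),
         method = method),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> method: ", x$method, ", ", nrow(x$folds),
      " LOMO folds\n", sep = "")
  cat(sprintf("  mean balanced accuracy: %.4f (pooled %.4f)\n",
              x$mean_balanced_accuracy, x$pooled_balanced_accuracy))
  cat(sprintf("  mean MCC: %.4f (pooled %.4f)%s\n", x$mean_mcc, x$pooled_mcc,
              if (any(x$folds$single_class))
                paste0(" [", sum(x$folds$single_class),
                       " single-class fold(s) excluded from mean MCC]")
              else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classifier_report <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.classifier_report <- function(x, ...) {
  tibble::tibble(method = x$method, n_folds = nrow(x$folds),
                 mean_balanced_accuracy = x$mean_balanced_accuracy,
                 mean_mcc = x$mean_mcc,
                 pooled_balanced_accuracy = x$pooled_balanced_accuracy,
                 pooled_mcc = x$pooled_mcc)
}

fold_metrics <- function(examples, pred) {
  ids <- unique(examples$model_id)
  rows <- lapply(ids, function(id) {
    sel <- examples$model_id == id
    cc <- confusion_counts(examples$label[sel], pred[sel])
    tibble::tibble(model_id = id, n_species = sum(sel),
                   balanced_accuracy = balanced_accuracy(cc),
                   mcc = mcc(cc),
                   single_class = is.na(mcc(cc)),
                   tp = cc[["tp"]], fn = cc[["fn"]], tn = cc[["tn"]],
                   fp = cc[["fp"]])
  })
  dplyr::bind_rows(rows)
}

#' Leave-one-model-out evaluation of the partitioner
#'
#' For every model of the corpus, trains the forest (with inner LOMO
#' isotonic calibration) on the remaining models, predicts the held-out
#' species, and reports per-fold balanced accuracy and Matthews correlation
#' coefficient along with their means and the pooled confusion matrix.
#' Folds whose ground truth is single-class get balanced accuracy over the
#' defined class only and are flagged and excluded from the mean MCC.
#'
#' @param x A `corpus` (at least 3 models) or a prebuilt training table from
#'   [build_training_table()].
#' @param n_trees,seed,mtry Forest settings, as in
#'   [train_partition_model()].
#' @param ... Pre-simulation settings passed to [build_training_table()]
#'   when `x` is a corpus.
#' @return A `classifier_report`.
#' @export
evaluate_lomo <- function(x, n_trees = 300L, seed = 1L, mtry = NULL, ...) {
  examples <- if (inherits(x, "corpus")) build_training_table(x, ...) else x
  ids <- unique(examples$model_id)
  if (length(ids) < 3L) {
    stop("LOMO evaluation needs at least 3 models", call. = FALSE)
  }
  pred <- rep(NA_integer_, nrow(examples))
  for (id in ids) {
    hold <- examples$model_id == id
    pm <- train_partition_model(examples[!hold, ], n_trees = n_trees,
                                seed = seed, mtry = mtry)
    pr <- predict(pm, examples[hold, ])
    pred[hold] <- pr$label
  }
  new_classifier_report(fold_metrics(examples, pred), "random_forest")
}

#' Abundance-heuristic baseline classifiers
#'
#' Classifies a species as stochastic iff its trajectory mean (or median)
#' molecule count is strictly below the cutoff, and evaluates with the same
#' LOMO fold structure and metrics as [evaluate_lomo()] for comparability.
#'
#' @param examples Training table from [build_training_table()].
#' @param statistic `"mean"` or `"median"` (the `q50` feature).
#' @param cutoff Molecules.
#' @return A `classifier_report`.
#' @export
heuristic_baseline <- function(examples, statistic = c("mean", "median"),
                               cutoff = 200) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "mean") "mean" else "q50"
  stopifnot(col %in% names(examples))
  pred <- as.integer(examples[[col]] < cutoff)
  new_classifier_report(fold_metrics(examples, pred),
                        paste0("heuristic_", statistic))
}

#' Classify the species of a model with a trained partitioner
#'
#' Runs the deterministic pre-simulation, extracts features, applies the
#' calibrated forest and returns per-species stochastic probabilities and
#' binary labels. The partition is computed once, before simulation, and
#' stays fixed throughout a hybrid run.
#'
#' @param model An [ode_model()] in count units.
#' @param pm A `partition_model`.
#' @param horizon,n_grid,rtol,atol Pre-simulation settings.
#' @return Tibble with `species`, `probability`, `label`.
#' @export
predict_partition <- function(model, pm, horizon = 500, n_grid = 2001L,
                              rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "ode_model"), inherits(pm, "partition_model"))
  if (any(model$species$unit != "count")) {
    stop("model must be in count units; use convert_to_counts() first",
         call. = FALSE)
  }
  traj <- run_presim(model, horizon = horizon, n_grid = n_grid,
                     rtol = rtol, atol = atol)
  feats <- extract_features(traj)
  pr <- predict(pm, feats)
  pr[, c("species", "probability", "label")]
}

#' Sensitivity of the labeling to the abundance threshold
#'
#' Relabels every species with [label_by_rule()] at each threshold and
#' reports the fraction of species whose label differs from the 200-molecule
#' baseline, plus the maximum over the grid.
#'
#' @param x A `corpus` or a training table with feature columns.
#' @param thresholds Numeric thresholds (molecules), typically spanning
#'   150-300.
#' @param ... Pre-simulation settings when `x` is a corpus.
#' @param baseline Baseline threshold (200).
#' @return Tibble with `threshold`, `n_flipped`, `flip_fraction`; the
#'   maximum flip fraction is attached as attribute `max_flip_fraction`.
#' @export
threshold_sensitivity <- function(x, thresholds = seq(150, 300, by = 25),
                                  baseline = 200, ...) {
  examples <- if (inherits(x, "corpus")) build_training_table(x, ...) else x
  base <- as.integer(examples$q80 < baseline & examples$q99 < baseline)
  rows <- lapply(thresholds, function(th) {
    lab <- as.integer(examples$q80 < th & examples$q99 < th)
    tibble::tibble(threshold = th, n_flipped = sum(lab != base),
                   flip_fraction = mean(lab != base))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "max_flip_fraction") <- max(out$flip_fraction)
  out
}
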