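#' Specify a classifier
#'
#' The four supported families with their reference hyperparameters: random
#' forest (`"rf"`, 100 trees), support vector machine (`"svm"`, RBF kernel,
#' cost 2.0, gamma 0.01, standardized inputs, probability calibration),
#' bagged decision trees (`"dt"`, 10 bootstrap-aggregated trees), and neural
#' network (`"nn"`, 500 training epochs; `nnet` fits a single hidden layer of
#' `(attributes + classes) / 2` units).  All hyperparameters can be
#' overridden through `...` and are serialized with every result.
#'
#' @param algorithm One of `"rf"`, `"svm"`, `"dt"`, `"nn"`.
#' @param seed Integer seed governing every stochastic component.
#' @param ... Hyperparameter overrides.
#' @return A `quadpot_classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("rf", "svm", "dt", "nn"),
                            seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    rf = list(ntree = 100L),
    svm = list(cost = 2.0, gamma = 0.01, epsilon = 1e-12,
               kernel = "radial", probability = TRUE),
    dt = list(bags = 10L, cp = 0.01),
    nn = list(maxit = 500L, decay = 0, hidden = NA_integer_,
              learning_rate = 0.3, momentum = 0.2))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, seed = as.integer(seed),
                 hyperparameters = hp),
            class = "quadpot_classifier_spec")
}

#' @export
print.quadpot_classifier_spec <- function(x, ...) {
  cat("<quadpot_classifier_spec> ", toupper(x$algorithm),
      " (seed ", x$seed, ")\n", sep = "")
  hp <- x$hyperparameters
  cat(" ", paste(names(hp), unlist(hp), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# --- feature encoding --------------------------------------------------------

CATEGORICAL_ATTRS <- c("native", "replacement", paste0("aa_n", 1:6),
                       "ss", "depth")
AA_LEVELS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

# One-hot encode the categorical attributes over their closed vocabularies;
# numeric attributes pass through.  Fixed level sets keep train/test matrices
# conformable.
encode_features <- function(df) {
  attrs <- feature_attribute_names()
  missing <- setdiff(attrs, names(df))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks attribute(s): ",
                 paste(missing, collapse = ", ")))
  }
  num <- setdiff(attrs, CATEGORICAL_ATTRS)
  mats <- list(as.matrix(df[num]))
  for (cn in CATEGORICAL_ATTRS) {
    lv <- if (cn == "ss") c("H", "S", "C") else
          if (cn == "depth") c("S", "U", "B") else AA_LEVELS
    fx <- factor(df[[cn]], levels = lv)
    m <- matrix(0, nrow(df), length(lv),
                dimnames = list(NULL, paste0(cn, "_", lv)))
    m[cbind(seq_len(nrow(df)), as.integer(fx))] <- 1
    mats[[length(mats) + 1]] <- m
  }
  do.call(cbind, mats)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu, "-"), 2, st$sd, "/")
}

# --- training and prediction -------------------------------------------------

#' Train a classifier on a variant feature table
#'
#' @param features Feature table from [encode_dataset()] with an `activity`
#'   column of `"U"`/`"A"` labels.
#' @param spec A [classifier_spec()].
#' @return A `quadpot_model` exposing class-probability prediction via
#'   [predict()].
#' @export
train_classifier <- function(features, spec = classifier_spec("rf")) {
  stopifnot(inherits(spec, "quadpot_classifier_spec"))
  if (!"activity" %in% names(features)) {
    abort("feature table has no 'activity' label column")
  }
  y <- factor(features$activity, levels = c("U", "A"))
  if (length(unique(y)) < 2) abort("training set contains a single class")
  X <- encode_features(features)
  hp <- spec$hyperparameters
  st <- NULL
  fit <- switch(spec$algorithm,
    rf = withr::with_seed(spec$seed,
      randomForest::randomForest(X, y, ntree = hp$ntree)),
    svm = {
      st <- standardize_fit(X)
      withr::with_seed(spec$seed,
        e1071::svm(standardize_apply(X, st), y, kernel = hp$kernel,
                   cost = hp$cost, gamma = hp$gamma,
                   probability = hp$probability, scale = FALSE))
    },
    dt = withr::with_seed(spec$seed, {
      df <- data.frame(X, check.names = TRUE)
      df$.y <- y
      lapply(seq_len(hp$bags), function(b) {
        idx <- sample(nrow(df), replace = TRUE)
        if (length(unique(df$.y[idx])) < 2) idx <- seq_len(nrow(df))
        rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                     method = "class", cp = hp$cp)
      })
    }),
    nn = {
      st <- standardize_fit(X)
      hidden <- hp$hidden
      if (is.na(hidden)) {
        hidden <- max(1L, floor((length(feature_attribute_names()) + 2) / 2))
      }
      withr::with_seed(spec$seed,
        nnet::nnet(standardize_apply(X, st), nnet::class.ind(y),
                   size = hidden, maxit = hp$maxit, decay = hp$decay,
                   softmax = TRUE, trace = FALSE, MaxNWts = 100000))
    })
  structure(list(spec = spec, fit = fit, standardizer = st,
                 levels = c("U", "A")),
            class = "quadpot_model")
}

#' Predict class probabilities for variants
#'
#' @param object A `quadpot_model`.
#' @param newdata A feature table.
#' @param ... Unused.
#' @return A tibble `prob_u`, `class` (predicted at the 0.5 threshold,
#'   ties to `"U"`).
#' @export
predict.quadpot_model <- function(object, newdata, ...) {
  X <- encode_features(newdata)
  if (!is.null(object$standardizer)) {
    X <- standardize_apply(X, object$standardizer)
  }
  prob_u <- switch(object$spec$algorithm,
    rf = unname(predict(object$fit, X, type = "prob")[, "U"]),
    svm = {
      pr <- predict(object$fit, X, probability = TRUE)
      unname(attr(pr, "probabilities")[, "U"])
    },
    dt = {
      df <- data.frame(X, check.names = TRUE)
      probs <- vapply(object$fit, function(tr) {
        predict(tr, df, type = "prob")[, "U"]
      }, numeric(nrow(df)))
      if (nrow(df) == 1) mean(probs) else rowMeans(matrix(probs, nrow(df)))
    },
    nn = {
      pr <- predict(object$fit, X)
      unname(pr[, "U"])
    })
  tibble(prob_u = prob_u,
         class = ifelse(prob_u >= 0.5, "U", "A"))
}

# --- metrics -----------------------------------------------------------------

#' Binary classification metrics
#'
#' The unaffected class U is Positive and the affected class A is Negative.
#' Reports the confusion counts, sensitivity, specificity, PPV (precision),
#' balanced accuracy `BAR = (sensitivity + specificity) / 2`, the Matthews
#' correlation coefficient, and the AUC computed by the rank (Mann-Whitney)
#' formulation from the class-U probabilities.
#'
#' @param truth True labels (`"U"`/`"A"`).
#' @param predicted Predicted labels.
#' @param score_u Class-U probabilities (for AUC; `NA` omitted gives
#'   `auc = NA`).
#' @return A one-row tibble of metrics.
#' @export
compute_metrics <- function(truth, predicted, score_u = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("U", "A")), all(predicted %in% c("U", "A")))
  tp <- sum(truth == "U" & predicted == "U")
  tn <- sum(truth == "A" & predicted == "A")
  fp <- sum(truth == "A" & predicted == "U")
  fn <- sum(truth == "U" & predicted == "A")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- tp / (tp + fp)
  denom <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  auc <- NA_real_
  if (!is.null(score_u)) {
    r <- rank(score_u)
    n_u <- sum(truth == "U")
    n_a <- sum(truth == "A")
    if (n_u > 0 && n_a > 0) {
      auc <- (sum(r[truth == "U"]) - n_u * (n_u + 1) / 2) / (n_u * n_a)
    }
  }
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = sens, specificity = spec, ppv = ppv,
         bar = (sens + spec) / 2, mcc = mcc, auc = auc)
}

# --- cross-validation --------------------------------------------------------

stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validate a classifier
#'
#' Leave-one-out CV (deterministic given the model seed) or stratified
#' 10-fold CV repeated `repeats` times with per-repeat fold seeds; repeated
#' 10-fold metrics are reported per repeat and averaged by [glance()].
#'
#' @param features Labeled feature table.
#' @param spec A [classifier_spec()].
#' @param scheme `"loocv"` or `"cv10"`.
#' @param repeats Repeats for `"cv10"` (default 10).
#' @param seed Fold-assignment seed for `"cv10"`.
#' @return A `quadpot_cv` with `$predictions` (held-out predictions),
#'   `$metrics` (one row per repeat), `$scheme`, `$spec`.
#' @export
cross_validate <- function(features, spec = classifier_spec("rf"),
                           scheme = c("loocv", "cv10"), repeats = 10L,
                           seed = spec$seed) {
  scheme <- match.arg(scheme)
  y <- factor(features$activity, levels = c("U", "A"))
  if (length(unique(y)) < 2) abort("dataset contains a single class")
  n <- nrow(features)
  run_folds <- function(fold, repeat_id) {
    parts <- purrr::map(sort(unique(fold)), function(k) {
      test_idx <- which(fold == k)
      train <- features[-test_idx, , drop = FALSE]
      if (length(unique(train$activity)) < 2) {
        abort("a training fold contains a single class; use fewer folds")
      }
      mdl <- train_classifier(train, spec)
      pr <- predict(mdl, features[test_idx, , drop = FALSE])
      tibble(repeat_id = repeat_id, fold = k, index = test_idx,
             truth = as.character(y[test_idx]),
             prob_u = pr$prob_u, class = pr$class)
    })
    dplyr::bind_rows(parts)
  }
  if (scheme == "loocv") {
    preds <- run_folds(seq_len(n), 1L)
    metrics <- compute_metrics(preds$truth, preds$class, preds$prob_u)
    metrics$repeat_id <- 1L
  } else {
    preds <- dplyr::bind_rows(purrr::map(seq_len(repeats), function(r) {
      fold <- stratified_folds(y, 10L, seed + r - 1L)
      run_folds(fold, r)
    }))
    metrics <- preds |>
      dplyr::group_by(repeat_id = .data$repeat_id) |>
      dplyr::group_modify(~compute_metrics(.x$truth, .x$class, .x$prob_u)) |>
      dplyr::ungroup()
  }
  structure(list(predictions = preds, metrics = metrics, scheme = scheme,
                 spec = spec, seed = seed, n = n),
            class = "quadpot_cv")
}

#' @export
print.quadpot_cv <- function(x, ...) {
  cat("<quadpot_cv> ", toupper(x$spec$algorithm), ", scheme ", x$scheme,
      ", n = ", x$n, "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `quadpot_cv`.
#' @param ... Unused.
#' @export
tidy.quadpot_cv <- function(x, ...) x$metrics

#' @rdname cross_validate
#' @export
glance.quadpot_cv <- function(x, ...) {
  out <- dplyr::summarise(x$metrics, dplyr::across(
    c("sensitivity", "specificity", "ppv", "bar", "mcc", "auc"),
    mean))
  out$algorithm <- x$spec$algorithm
  out$scheme <- x$scheme
  out$repeats <- nrow(x$metrics)
  out
}

# --- permutation significance ------------------------------------------------

#' Label-permutation null distribution of classifier performance
#'
#' Shuffles the activity labels `n_permutations` times, re-runs
#' cross-validation on each control set, and records the null BAR and MCC.
#' An empirical p-value for the unpermuted result is computed as
#' `(1 + #{null >= observed}) / (n_permutations + 1)`.
#'
#' @param features Labeled feature table.
#' @param spec A [classifier_spec()].
#' @param n_permutations Number of label shuffles (`>= 1`).
#' @param seed Seed for shuffling (model/fold seeds derive from it).
#' @param scheme,repeats Passed to [cross_validate()] (default single-repeat
#'   `"cv10"`, the reduced-cost scheme).
#' @return A `quadpot_permtest`: `$null` (tibble `permutation`, `bar`,
#'   `mcc`), `$observed`, `$p_bar`, `$p_mcc`.
#' @export
permutation_significance <- function(features, spec = classifier_spec("rf"),
                                     n_permutations = 200L, seed = 1L,
                                     scheme = "cv10", repeats = 1L) {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  observed <- glance(cross_validate(features, spec, scheme = scheme,
                                    repeats = repeats, seed = seed))
  labels <- features$activity
  null_rows <- purrr::map(seq_len(n_permutations), function(b) {
    perm <- features
    perm$activity <- withr::with_seed(seed + b, sample(labels))
    g <- glance(cross_validate(perm, spec, scheme = scheme,
                               repeats = repeats, seed = seed + b))
    tibble(permutation = b, bar = g$bar, mcc = g$mcc)
  })
  null <- dplyr::bind_rows(null_rows)
  structure(list(
    null = null, observed = observed,
    p_bar = (1 + sum(null$bar >= observed$bar)) / (n_permutations + 1),
    p_mcc = (1 + sum(null$mcc >= observed$mcc)) / (n_permutations + 1),
    spec = spec, seed = seed),
    class = "quadpot_permtest")
}

#' @export
print.quadpot_permtest <- function(x, ...) {
  cat("<quadpot_permtest> ", nrow(x$null), " label permutations\n", sep = "")
  cat(sprintf("  null BAR %.3f +/- %.3f, null MCC %.3f +/- %.3f\n",
              mean(x$null$bar), sd(x$null$bar),
              mean(x$null$mcc), sd(x$null$mcc)))
  cat(sprintf("  observed BAR %.3f (p = %.4g), MCC %.3f (p = %.4g)\n",
              x$observed$bar, x$p_bar, x$observed$mcc, x$p_mcc))
  invisible(x)
}

#' @rdname permutation_significance
#' @param x A `quadpot_permtest`.
#' @param ... Unused.
#' @export
tidy.quadpot_permtest <- function(x, ...) x$null

#' @rdname permutation_significance
#' @export
glance.quadpot_permtest <- function(x, ...) {
  tibble(null_bar_mean = mean(x$null$bar), null_bar_sd = sd(x$null$bar),
         null_mcc_mean = mean(x$null$mcc), null_mcc_sd = sd(x$null$mcc),
         observed_bar = x$observed$bar, observed_mcc = x$observed$mcc,
         p_bar = x$p_bar, p_mcc = x$p_mcc)
}

# --- learning curves ---------------------------------------------------------

#' Learning curve over training-set size
#'
#' For each size, draws `samples_per_size` stratified random subsets without
#' replacement, runs 10-fold CV on each, and aggregates BAR, MCC and AUC as
#' mean and standard deviation over the subsets.
#'
#' @param features Labeled feature table.
#' @param spec A [classifier_spec()].
#' @param sizes Integer vector of subset sizes (each `<= nrow(features)`).
#' @param samples_per_size Subsets per size (default 10).
#' @param seed Sampling seed.
#' @return A `quadpot_learning_curve` tibble: `size`, mean/sd columns for
#'   `bar`, `mcc`, `auc`.
#' @export
learning_curve <- function(features, spec = classifier_spec("rf"),
                           sizes, samples_per_size = 10L, seed = 1L) {
  n <- nrow(features)
  stopifnot(all(sizes >= 20), all(sizes <= n))
  y <- features$activity
  rows <- purrr::map(sizes, function(sz) {
    per <- purrr::map(seq_len(samples_per_size), function(s) {
      sub_seed <- seed + 1000L * match(sz, sizes) + s
      idx <- if (sz == n) seq_len(n) else withr::with_seed(sub_seed, {
        unlist(lapply(unique(y), function(cl) {
          cand <- which(y == cl)
          sample(cand, round(sz * length(cand) / n))
        }))
      })
      g <- glance(cross_validate(features[idx, , drop = FALSE], spec,
                                 scheme = "cv10", repeats = 1L,
                                 seed = sub_seed))
      tibble(bar = g$bar, mcc = g$mcc, auc = g$auc)
    }) |> dplyr::bind_rows()
    tibble(size = sz,
           bar_mean = mean(per$bar), bar_sd = sd(per$bar),
           mcc_mean = mean(per$mcc), mcc_sd = sd(per$mcc),
           auc_mean = mean(per$auc), auc_sd = sd(per$auc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("quadpot_learning_curve", class(out))
  out
}
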