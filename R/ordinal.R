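# Ordinal evaluation harness: MAE, proportional-odds models, the
# random-forest and modal-class baselines, stratified CV-10 evaluation and
# paired model comparison.

#' Mean absolute error between ordinal predictions and observations
#'
#' `MAE = sum(|y_i - x_i|) / n`, the natural loss for five-category ALSFRS
#' targets where mispredicting by two points is worse than by one.
#'
#' @param predicted,observed Equal-length numeric vectors of classes.
#' @return Non-negative scalar.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort_config("predicted and observed must have equal length")
  }
  if (length(predicted) == 0) abort_config("need at least one prediction")
  mean(abs(as.numeric(predicted) - as.numeric(observed)))
}

#' MAE-optimal class from an ordinal distribution (the median)
#'
#' Returns, per row of a class-probability matrix, the smallest class whose
#' cumulative probability reaches 1/2 — the minimiser of expected absolute
#' error.
#'
#' @param probs Matrix of class probabilities, columns named by class.
#' @return Numeric vector of classes.
#' @export
distribution_median <- function(probs) {
  probs <- as.matrix(probs)
  classes <- as.numeric(colnames(probs))
  cum <- t(apply(probs, 1, cumsum))
  classes[max.col(cum >= 0.5 - 1e-12, "first")]
}

# cumulative link model ---------------------------------------------------

#' Proportional-odds cumulative link model for an ALSFRS item
#'
#' Fits `logit P(y <= k) = theta_k - x'beta` by maximum likelihood
#' (proportional odds, logit link).  The default class decision is the
#' median of the predicted distribution, which minimises expected absolute
#' error; `decision = "mode"` gives the most probable class instead.
#'
#' @inheritParams fit_multiclass_tree
#' @param decision Default decision rule stored with the model.
#' @return An `als_clm`.
#' @export
fit_clm <- function(data, target = "target", features = NULL,
                    decision = c("median", "mode")) {
  decision <- match.arg(decision)
  d <- prepare_xy(data, target, features)
  lev <- sort(unique(as.numeric(d$y)))
  if (length(lev) < 2) abort_config("target needs at least two observed classes")
  df <- as.data.frame(lapply(d$x, function(v) {
    if (is.character(v) || is.logical(v)) factor(v) else v
  }))
  if (ncol(df) == 0) df <- data.frame(row.names = seq_along(d$y))
  df$.y <- factor(as.numeric(d$y), levels = lev, ordered = TRUE)
  # drop constant columns: they carry no information and break polr
  keep <- vapply(df[d$features], function(v) length(unique(v)) > 1, logical(1))
  feats <- d$features[keep]
  form <- if (length(feats) == 0) .y ~ 1 else
    stats::reformulate(feats, response = ".y")
  if (length(lev) == 2) {
    # two observed classes: the cumulative logit model reduces to a
    # single binary logistic regression
    fit <- suppressWarnings(stats::glm(form, data = df, family = stats::binomial()))
    return(structure(list(fit = fit, levels = lev, features = d$features,
                          used_features = feats, decision = decision,
                          binary = TRUE),
                     class = "als_clm"))
  }
  fit <- tryCatch(
    MASS::polr(form, data = df, Hess = FALSE),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) {
    fit <- withCallingHandlers(
      tryCatch(MASS::polr(form, data = df, Hess = FALSE,
                          control = list(maxit = 500)),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  if (is.null(fit)) {
    rlang::warn("cumulative link fit failed; falling back to intercept-only")
    fit <- MASS::polr(.y ~ 1, data = df, Hess = FALSE)
    feats <- character(0)
  }
  structure(list(fit = fit, levels = lev, features = d$features,
                 used_features = feats, decision = decision),
            class = "als_clm")
}

#' @export
predict.als_clm <- function(object, newdata,
                            type = c("class", "prob"),
                            decision = NULL, ...) {
  type <- match.arg(type)
  decision <- decision %||% object$decision
  newdata <- tibble::as_tibble(newdata)
  df <- as.data.frame(lapply(newdata[intersect(object$features, names(newdata))],
                             function(v) {
                               if (is.character(v) || is.logical(v)) factor(v) else v
                             }))
  if (nrow(df) == 0) df <- data.frame(row.names = seq_len(nrow(newdata)))
  if (isTRUE(object$binary)) {
    p2 <- predict(object$fit, newdata = df, type = "response")
    p <- cbind(1 - p2, p2)
  } else {
    p <- predict(object$fit, newdata = df, type = "probs")
  }
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(newdata),
                                   ncol = length(object$levels), byrow = TRUE)
  colnames(p) <- object$levels
  # embed observed levels into the full 0..4 scale
  full <- matrix(0, nrow(p), 5, dimnames = list(NULL, 0:4))
  full[, as.character(object$levels)] <- p
  if (type == "prob") return(full)
  if (decision == "median") distribution_median(full)
  else as.numeric(colnames(full)[max.col(full, "first")])
}

#' @export
print.als_clm <- function(x, ...) {
  cat("<als_clm> proportional-odds model, levels {",
      paste(x$levels, collapse = ","), "}, ", length(x$used_features),
      " predictors, ", x$decision, " decision\n", sep = "")
  invisible(x)
}

# baselines ---------------------------------------------------------------

#' Random-forest baseline (nominal, non-ordinal)
#'
#' @inheritParams fit_multiclass_tree
#' @param n_trees Number of trees. @param bootstrap Bagging on/off.
#' @param seed Seed.
#' @return An `als_rf`.
#' @export
fit_rf <- function(data, target = "target", features = NULL, n_trees = 300L,
                   bootstrap = TRUE, seed = 1L) {
  d <- prepare_xy(data, target, features)
  x <- as.data.frame(lapply(d$x, function(v) {
    if (is.character(v) || is.logical(v)) factor(v) else v
  }))
  y <- factor(as.numeric(d$y))
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = y, ntree = n_trees, replace = bootstrap,
    sampsize = if (bootstrap) nrow(x) else nrow(x)
  ))
  structure(list(fit = fit, features = d$features,
                 levels = as.numeric(levels(y))),
            class = "als_rf")
}

#' @export
predict.als_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  x <- as.data.frame(lapply(newdata[intersect(object$features, names(newdata))],
                            function(v) {
                              if (is.character(v) || is.logical(v)) factor(v) else v
                            }))
  if (type == "class") as.numeric(as.character(predict(object$fit, x)))
  else {
    p <- predict(object$fit, x, type = "prob")
    full <- matrix(0, nrow(p), 5, dimnames = list(NULL, 0:4))
    full[, colnames(p)] <- p
    full
  }
}

#' Prior-only (modal class) predictor
#'
#' Predicts the most frequent training class for every record — the
#' baseline any informative model must beat.
#'
#' @inheritParams fit_multiclass_tree
#' @return An `als_prior`.
#' @export
fit_prior <- function(data, target = "target", features = NULL) {
  y <- as.numeric(tibble::as_tibble(data)[[target]])
  tab <- table(y)
  mode <- as.numeric(names(tab)[which.max(tab)])
  structure(list(mode = mode, marginal = as.numeric(tab) / length(y),
                 levels = as.numeric(names(tab))),
            class = "als_prior")
}

#' @export
predict.als_prior <- function(object, newdata, ...) {
  rep(object$mode, nrow(tibble::as_tibble(newdata)))
}

# cross-validated evaluation ----------------------------------------------

#' Default model set for the evaluation harness
#'
#' Named list of fitting closures (`function(train) -> model`) covering the
#' ordinal models (clm, odt, cpt), the multi-class tree and random-forest
#' baselines, and the prior-only predictor.
#'
#' @param seed Seed forwarded to the stochastic learners.
#' @param rf_trees Random-forest size.
#' @param models Which of the six to include.
#' @return Named list of closures.
#' @export
default_models <- function(seed = 1L, rf_trees = 200L,
                           models = c("clm", "odt", "cpt", "tree", "rf",
                                      "prior")) {
  all <- list(
    clm = function(train) fit_clm(train),
    odt = function(train) fit_odt(train, seed = seed),
    cpt = function(train) fit_cpt(train, seed = seed),
    tree = function(train) fit_multiclass_tree(train, seed = seed),
    rf = function(train) fit_rf(train, n_trees = rf_trees, seed = seed),
    prior = function(train) fit_prior(train)
  )
  all[match.arg(models, names(all), several.ok = TRUE)]
}

make_stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      ix <- which(y == cl)
      ix <- ix[sample.int(length(ix))]
      fold[ix] <- rep_len(sample.int(k), length(ix))
    }
    fold
  })
}

#' Stratified CV-10 evaluation of a model set
#'
#' Splits the table into `k` class-stratified folds; each model is fitted
#' on nine folds and scored on the held-out one.  Reports per-fold MAE and
#' accuracy and the pooled 5x5 confusion matrix per model.
#'
#' @param data An `als_modeling_table` (or data frame with a `target`
#'   column in `{0..4}`).
#' @param models Named list of fitting closures, see [default_models()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @return An `als_eval`: list with `folds` (tibble `model`, `fold`, `mae`,
#'   `accuracy`, `n_test`), `confusion` (named list of 5x5 count matrices),
#'   `setting`, `item`.
#' @export
cv_evaluate <- function(data, models = default_models(), k = 10L, seed = 1L) {
  data <- tibble::as_tibble(data)
  y <- as.numeric(data$target)
  fold <- make_stratified_folds(y, k, seed)
  classes <- 0:4
  conf <- lapply(models, function(m) {
    matrix(0L, 5, 5, dimnames = list(observed = classes, predicted = classes))
  })
  rows <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    train <- data[!test, , drop = FALSE]
    if (length(unique(y[!test])) < length(unique(y))) {
      rlang::warn(sprintf("fold %d: some class absent from training data", f))
    }
    for (mn in names(models)) {
      fitted <- models[[mn]](train)
      pred <- as.numeric(predict(fitted, data[test, , drop = FALSE]))
      obs <- y[test]
      pr <- factor(pmin(pmax(round(pred), 0), 4), levels = classes)
      ob <- factor(obs, levels = classes)
      conf[[mn]] <- conf[[mn]] + unclass(table(observed = ob, predicted = pr))
      rows[[length(rows) + 1]] <- tibble::tibble(
        model = mn, fold = f, mae = mae(pred, obs),
        accuracy = mean(pred == obs), n_test = sum(test))
    }
  }
  structure(list(folds = dplyr::bind_rows(rows), confusion = conf,
                 setting = attr(data, "setting"),
                 item = attr(data, "target_item")),
            class = "als_eval")
}

#' @export
print.als_eval <- function(x, ...) {
  g <- glance(x)
  cat("<als_eval>", if (!is.null(x$item)) paste0(" item=", x$item),
      if (!is.null(x$setting)) paste0(" setting=", x$setting), "\n", sep = "")
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.als_eval <- function(x, ...) x$folds

#' @export
glance.als_eval <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$folds, .data$model),
                   mean_mae = mean(.data$mae),
                   mean_accuracy = mean(.data$accuracy),
                   folds = dplyr::n(), .groups = "drop")
}

#' Paired comparison of two models' per-fold errors
#'
#' Two-sided paired t-test on matched per-fold (or per-item) MAEs.
#'
#' @param a,b Numeric vectors of matched errors, or an `als_eval` for `a`
#'   with `b` and `b2` naming two of its models.
#' @param b2 Second model name when `a` is an `als_eval`.
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p_value`, `note`.
#' @export
compare_models <- function(a, b, b2 = NULL) {
  if (inherits(a, "als_eval")) {
    folds <- a$folds
    xa <- folds$mae[folds$model == b]
    xb <- folds$mae[folds$model == b2]
  } else {
    xa <- as.numeric(a); xb <- as.numeric(b)
  }
  if (length(xa) != length(xb)) abort_config("paired vectors differ in length")
  d <- xa - xb
  if (sd(d) < 1e-12) {
    note <- if (abs(mean(d)) < 1e-12) "identical" else "identical-shift"
    return(tibble::tibble(mean_diff = mean(d), t = NA_real_,
                          df = NA_real_, p_value = NA_real_, note = note))
  }
  tt <- t.test(xa, xb, paired = TRUE)
  tibble::tibble(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 note = NA_character_)
}

#' All pairwise model comparisons with Holm adjustment
#'
#' @param eval An `als_eval`, or a tibble shaped like its `folds` element
#'   (possibly pooled over items).
#' @return Tibble of pairs with raw and Holm-adjusted p-values.
#' @export
compare_model_pairs <- function(eval) {
  folds <- if (inherits(eval, "als_eval")) eval$folds else tibble::as_tibble(eval)
  models <- unique(folds$model)
  prs <- combn(models, 2)
  out <- purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    wide <- tidyr::pivot_wider(
      folds[folds$model %in% c(a, b),
            intersect(c("item", "setting", "model", "fold", "mae"), names(folds))],
      names_from = "model", values_from = "mae")
    cmp <- compare_models(wide[[a]], wide[[b]])
    dplyr::bind_cols(tibble::tibble(model_a = a, model_b = b), cmp)
  })
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}
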