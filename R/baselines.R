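# Classical ML baselines: SVM, k-nearest neighbors, decision tree, random
# forest and two gradient-boosted tree variants, each grid-searched with
# the winner chosen by validation AUROC. Input mode "tabular" uses the
# flat variable table; mode "tss" uses the same concatenated inputs as the
# neural network.

default_baseline_grids <- function() {
  list(
    svm = expand.grid(cost = c(0.1, 1, 10), gamma_scale = c(1, 0.1)),
    knn = expand.grid(k = c(5, 15, 31)),
    decision_tree = expand.grid(cp = c(0.001, 0.01), maxdepth = c(5, 15)),
    random_forest = expand.grid(num_trees = 300, mtry_frac = c(0.1, 0.33)),
    xgb_tree = expand.grid(max_depth = c(3, 6), eta = 0.1, nrounds = 150),
    xgb_dart = expand.grid(max_depth = c(3, 6), eta = 0.1, nrounds = 150,
                           rate_drop = 0.1))
}

baseline_input <- function(bundle, mode) {
  switch(mode,
    tabular = as.matrix(bundle$tabular),
    tss = cbind(as.matrix(bundle$tss), as.matrix(bundle$demographics),
                as.matrix(bundle$severity)),
    stop_config("unknown baseline input mode '%s'", mode))
}

#' Fit the baseline model family
#'
#' Six models (SVM, kNN, decision tree, random forest, two
#' gradient-boosted tree variants), each fitted over a small hyperparameter
#' grid with the winning configuration chosen by validation AUROC.
#'
#' @param train,validation `feature_bundle` lists from
#'   [assemble_features()].
#' @param mode `"tabular"` (flat variable table) or `"tss"` (the neural
#'   network's concatenated inputs).
#' @param grids named list of hyperparameter grids (see
#'   `default_baseline_grids()`).
#' @param seed RNG seed for the stochastic learners.
#' @param models subset of model names to fit.
#' @return Named list of `baseline_fit` objects, each with the fitted
#'   model, its winning hyperparameters (`params`), `val_auroc` and a
#'   `predict_fun(newx)` closure.
#' @export
fit_baselines <- function(train, validation, mode = c("tabular", "tss"),
                          grids = default_baseline_grids(), seed = 1,
                          models = names(grids)) {
  mode <- match.arg(mode)
  xtr <- baseline_input(train, mode)
  xva <- baseline_input(validation, mode)
  ytr <- as.logical(train$label)
  yva <- as.logical(validation$label)
  # standardized copies for the scale-sensitive learners
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  ztr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
  zva <- sweep(sweep(xva, 2L, mu), 2L, sdv, "/")
  scaler <- function(x) sweep(sweep(x, 2L, mu), 2L, sdv, "/")

  out <- list()
  for (nm in models) {
    grid <- grids[[nm]]
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      gp <- grid[gi, , drop = FALSE]
      fit <- fit_one_baseline(nm, gp, ztr, ytr, xtr, seed, scaler)
      va <- auc_rank(fit$predict_fun(if (fit$scaled) zva else xva), yva)
      if (is.null(best) || va > best$val_auroc) {
        best <- list(name = nm, params = as.list(gp), val_auroc = va,
                     model = fit$model, predict_fun = fit$predict_fun,
                     scaled = fit$scaled, scaler = scaler)
      }
    }
    class(best) <- "baseline_fit"
    out[[nm]] <- best
  }
  out
}

fit_one_baseline <- function(nm, gp, ztr, ytr, xtr, seed, scaler) {
  yfac <- factor(ytr, levels = c(FALSE, TRUE))
  switch(nm,
    svm = {
      g <- gp$gamma_scale / ncol(ztr)
      m <- with_seed(seed, e1071::svm(ztr, yfac, kernel = "radial",
                                      cost = gp$cost, gamma = g,
                                      probability = TRUE, scale = FALSE))
      list(model = m, scaled = TRUE, predict_fun = function(newx) {
        pr <- attr(stats::predict(m, newx, probability = TRUE), "probabilities")
        pr[, "TRUE"]
      })
    },
    knn = {
      k <- gp$k
      m <- list(x = ztr, y = yfac, k = k)
      list(model = m, scaled = TRUE, predict_fun = function(newx) {
        pr <- class::knn(m$x, newx, m$y, k = m$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "TRUE", p, 1 - p)
      })
    },
    decision_tree = {
      vn <- paste0("V", seq_len(ncol(xtr)))  # syntactic names for the formula
      df <- as.data.frame(xtr)
      names(df) <- vn
      df$y <- yfac
      m <- rpart::rpart(y ~ ., df, method = "class",
                        control = rpart::rpart.control(cp = gp$cp,
                                                       maxdepth = gp$maxdepth))
      list(model = m, scaled = FALSE, predict_fun = function(newx) {
        nd <- as.data.frame(newx)
        names(nd) <- vn
        stats::predict(m, nd)[, "TRUE"]
      })
    },
    random_forest = {
      mtry <- max(1L, floor(gp$mtry_frac * ncol(xtr)))
      m <- ranger::ranger(x = xtr, y = yfac, num.trees = gp$num_trees,
                          mtry = mtry, probability = TRUE, seed = seed,
                          num.threads = 1)
      list(model = m, scaled = FALSE, predict_fun = function(newx)
        stats::predict(m, data = newx, num.threads = 1)$predictions[, "TRUE"])
    },
    xgb_tree = ,
    xgb_dart = {
      params <- list(objective = "binary:logistic", max_depth = gp$max_depth,
                     eta = gp$eta, nthread = 1,
                     booster = if (nm == "xgb_dart") "dart" else "gbtree")
      if (nm == "xgb_dart") params$rate_drop <- gp$rate_drop
      m <- with_seed(seed, xgboost::xgb.train(
        params = params, data = xgboost::xgb.DMatrix(xtr, label = as.numeric(ytr)),
        nrounds = gp$nrounds, verbose = 0))
      list(model = m, scaled = FALSE, predict_fun = function(newx)
        stats::predict(m, xgboost::xgb.DMatrix(newx)))
    },
    stop_config("unknown baseline model '%s'", nm))
}

#' Predict with a fitted baseline
#'
#' @param object a `baseline_fit` from [fit_baselines()].
#' @param newdata feature matrix in the same input mode the model was
#'   fitted with (a `feature_bundle` is also accepted together with
#'   `mode`).
#' @param mode input mode when `newdata` is a `feature_bundle`.
#' @param ... unused.
#' @return Positive-class probability vector.
#' @export
predict.baseline_fit <- function(object, newdata, mode = "tabular", ...) {
  if (inherits(newdata, "feature_bundle"))
    newdata <- baseline_input(newdata, mode)
  if (object$scaled) newdata <- object$scaler(newdata)
  object$predict_fun(newdata)
}
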