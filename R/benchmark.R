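#' Root-mean-square error
#' @param pred,truth Numeric vectors of equal length (>= 2).
#' @return RMSE in the units of the inputs (kcal mol^-1 for ddG).
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (length(pred) < 2L) stop("need at least two values")
  sqrt(mean((pred - truth)^2))
}

#' Pearson correlation with a zero-variance guard
#'
#' Standard product-moment correlation; a zero-variance input (e.g. a
#' constant predictor) yields 0 with a warning rather than an error so
#' degenerate baselines do not abort a benchmark run.
#'
#' @param pred,truth Numeric vectors of equal length (>= 2).
#' @return Pearson r.
#' @export
pearsonCor <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning("zero-variance input; Pearson correlation reported as 0")
    return(0)
  }
  stats::cor(pred, truth)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision of ranking the positive (resistant)
#' labels by score: items are sorted by decreasing score (ties broken by
#' stable sort on input order) and AP is the mean over positives of the
#' precision at each positive's rank.
#'
#' @param scores Numeric scores (here, predicted ddG).
#' @param labels Logical (or 0/1) vector; at least one positive required.
#' @return AP in (0, 1].
#' @export
#' @examples
#' auprc(c(3, 2, 1), c(TRUE, FALSE, FALSE))  # perfect ranking -> 1
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  npos <- sum(labels)
  if (npos == 0L) stop("AUPRC undefined: no positive labels")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  prec_at <- cumsum(lab) / seq_along(lab)
  mean(prec_at[lab])
}

#' Scenario specification for the benchmark
#'
#' Defines one of the three standard train/test scenarios over a tagged
#' sample corpus, with the TKI-tagged samples always forming the test set:
#' \enumerate{
#'   \item train on Platinum-tagged samples from non-tyrosine-kinase
#'     proteins;
#'   \item train on all Platinum-tagged samples;
#'   \item train on the CoreSet minus TKI-derived samples, restricted to
#'     single substitutions.
#' }
#'
#' @param id Scenario id, 1, 2 or 3.
#' @param nRepetitions Number of repetitions (default 5).
#' @param seeds Integer seeds, one per repetition (default `0:4`); each
#'   repetition re-seeds the estimator.
#' @return List of class `scenarioSpec`.
#' @export
scenarioSpec <- function(id, nRepetitions = 5, seeds = seq_len(nRepetitions) - 1) {
  stopifnot(id %in% 1:3, length(seeds) == nRepetitions)
  structure(list(id = id, nRepetitions = nRepetitions, seeds = seeds),
            class = "scenarioSpec")
}

#' Build scenario train and test sets
#'
#' @param samples Sample `data.frame` with columns `uniprot_id`, `drug`,
#'   `mutation`, `mutation_type`, `source` (tags such as `platinum`,
#'   `tki`, others) and `tyrosine_kinase` (logical protein-class flag,
#'   required for scenario 1).
#' @param spec A [scenarioSpec()].
#' @return List with `train` and `test` integer row indices into
#'   `samples`; the sets are disjoint on (protein, drug, mutation) triples.
#' @export
buildScenario <- function(samples, spec) {
  stopifnot(inherits(spec, "scenarioSpec"))
  src <- tolower(samples$source)
  test <- which(src == "tki")
  if (!length(test)) stop("no TKI-tagged test samples in the corpus")
  train <- switch(as.character(spec$id),
    "1" = {
      if (is.null(samples$tyrosine_kinase))
        stop("scenario 1 requires a tyrosine_kinase protein-class flag")
      which(src == "platinum" & !samples$tyrosine_kinase)
    },
    "2" = which(src == "platinum"),
    "3" = which(src != "tki" &
                samples$mutation_type == "single_substitution"))
  if (!length(train))
    stop("empty training set after applying the scenario ", spec$id,
         " filter")
  triple <- paste(samples$uniprot_id, samples$drug, samples$mutation,
                  sep = "\r")
  train <- setdiff(train, which(triple %in% triple[test]))
  if (!length(train))
    stop("training set empty after enforcing train/test disjointness")
  list(train = train, test = test)
}

#' Built-in estimator contracts
#'
#' Returns estimator contracts for the ten standard slots, each a list
#' with `name`, `family` and `fit(x, y)` returning an object with
#' `predict(x)`. Implementations: `decision_tree` (\pkg{rpart}),
#' `random_forest` (\pkg{randomForest}), `extra_trees` (\pkg{ranger} with
#' the extratrees split rule), `svr` (\pkg{e1071}), `elastic_net` and
#' `lasso` (\pkg{glmnet}), `bagging` (bootstrap aggregation of rpart
#' trees), `adaboost` (AdaBoost.R2 over rpart stumps), `gradient_boost`
#' (\pkg{xgboost}) and `mlp` (\pkg{nnet}, standardized inputs).
#' Hyperparameters are the backing library defaults except where noted.
#'
#' @param names Which estimators to return (default all ten).
#' @return Named list of estimator contracts.
#' @export
builtinEstimators <- function(names = c("decision_tree", "random_forest",
                                        "extra_trees", "svr", "elastic_net",
                                        "lasso", "bagging", "adaboost",
                                        "gradient_boost", "mlp")) {
  all <- list(
    decision_tree = list(family = "tree", fit = function(x, y) {
      d <- data.frame(y = y, x)
      m <- rpart::rpart(y ~ ., data = d)
      list(predict = function(nx) unname(predict(m, data.frame(nx))))
    }),
    random_forest = list(family = "tree", fit = function(x, y) {
      m <- randomForest::randomForest(x, y)
      list(predict = function(nx) unname(predict(m, nx)))
    }),
    extra_trees = list(family = "tree", fit = function(x, y) {
      d <- data.frame(y = y, x)
      m <- ranger::ranger(y ~ ., data = d, splitrule = "extratrees",
                          num.random.splits = 1, num.trees = 500)
      list(predict = function(nx)
        predict(m, data.frame(nx))$predictions)
    }),
    svr = list(family = "linear", fit = function(x, y) {
      m <- e1071::svm(x, y)
      list(predict = function(nx) unname(predict(m, nx)))
    }),
    elastic_net = list(family = "linear", fit = function(x, y) {
      m <- glmnet::cv.glmnet(as.matrix(x), y, alpha = 0.5, nfolds = 5)
      list(predict = function(nx)
        as.numeric(predict(m, as.matrix(nx), s = "lambda.min")))
    }),
    lasso = list(family = "linear", fit = function(x, y) {
      m <- glmnet::cv.glmnet(as.matrix(x), y, alpha = 1, nfolds = 5)
      list(predict = function(nx)
        as.numeric(predict(m, as.matrix(nx), s = "lambda.min")))
    }),
    bagging = list(family = "ensemble", fit = function(x, y) {
      n <- length(y)
      trees <- lapply(seq_len(25), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        rpart::rpart(y ~ ., data = data.frame(y = y[idx],
                                              x[idx, , drop = FALSE]))
      })
      list(predict = function(nx) {
        p <- vapply(trees, function(t) unname(predict(t, data.frame(nx))),
                    numeric(nrow(nx)))
        rowMeans(p)
      })
    }),
    adaboost = list(family = "ensemble", fit = .fit_adaboost_r2),
    gradient_boost = list(family = "ensemble", fit = function(x, y) {
      m <- xgboost::xgboost(data = as.matrix(x), label = y, nrounds = 100,
                            verbose = 0, nthread = 1)
      list(predict = function(nx) predict(m, as.matrix(nx)))
    }),
    mlp = list(family = "neural", fit = function(x, y) {
      x <- as.matrix(x)
      mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
      m <- nnet::nnet(xs, y, size = 8, linout = TRUE, trace = FALSE,
                      maxit = 500, decay = 1e-3)
      list(predict = function(nx) {
        nxs <- sweep(sweep(as.matrix(nx), 2, mu), 2, sdv, "/")
        as.numeric(predict(m, nxs))
      })
    }))
  missing <- setdiff(names, names(all))
  if (length(missing))
    stop("unknown estimator(s): ", paste(missing, collapse = ", "))
  out <- all[names]
  for (nm in names(out)) out[[nm]]$name <- nm
  out
}

# AdaBoost.R2 (Drucker 1997) with shallow rpart base learners
.fit_adaboost_r2 <- function(x, y, n_iter = 25) {
  n <- length(y)
  w <- rep(1 / n, n)
  models <- list(); betas <- numeric(0)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    m <- rpart::rpart(y ~ ., data = data.frame(y = y[idx],
                                               x[idx, , drop = FALSE]),
                      control = rpart::rpart.control(maxdepth = 4))
    pred <- unname(predict(m, data.frame(x)))
    err <- abs(pred - y)
    if (max(err) == 0) { models <- c(models, list(m)); betas <- c(betas, 1e-10); break }
    lossv <- err / max(err)
    loss <- sum(w * lossv)
    if (loss >= 0.5) break
    beta <- loss / (1 - loss)
    models <- c(models, list(m)); betas <- c(betas, beta)
    w <- w * beta^(1 - lossv)
    w <- w / sum(w)
  }
  if (!length(models)) {  # fell through immediately: single tree fallback
    m <- rpart::rpart(y ~ ., data = data.frame(y = y, x))
    models <- list(m); betas <- 0.5
  }
  list(predict = function(nx) {
    p <- vapply(models, function(m) unname(predict(m, data.frame(nx))),
                numeric(nrow(nx)))
    p <- matrix(p, nrow = nrow(nx))
    wts <- log(1 / betas)
    # weighted-median combination
    apply(p, 1, function(row) {
      ord <- order(row)
      cw <- cumsum(wts[ord])
      row[ord][which(cw >= 0.5 * sum(wts))[1]]
    })
  })
}

#' Run the scenario benchmark
#'
#' For each estimator and repetition: seed the RNG with the repetition
#' seed, fit on the scenario training set, predict the TKI test set and
#' compute RMSE, Pearson and AUPRC (resistant labels from true ddG above
#' the 1.36 kcal mol^-1 cutoff, scores the predicted ddG). Reports the
#' mean and standard deviation over repetitions plus the raw
#' per-repetition values and the experimental-vs-calculated scatter data.
#' An estimator that fails during fitting is recorded with `NA` metrics
#' and does not affect the others.
#'
#' @param samples Tagged sample `data.frame` (see [buildScenario()]) with
#'   a `ddg_kcal_mol` column.
#' @param features Numeric feature matrix, one row per sample row.
#' @param estimators List of estimator contracts ([builtinEstimators()]).
#' @param spec A [scenarioSpec()].
#' @return A [ScenarioReport].
#' @export
runBenchmark <- function(samples, features, estimators, spec) {
  stopifnot(nrow(samples) == nrow(features))
  split <- buildScenario(samples, spec)
  x_tr <- features[split$train, , drop = FALSE]
  y_tr <- samples$ddg_kcal_mol[split$train]
  x_te <- features[split$test, , drop = FALSE]
  y_te <- samples$ddg_kcal_mol[split$test]
  lab_te <- labelResistant(y_te)
  raw <- list(); scatter <- list()
  for (est in estimators) {
    for (r in seq_len(spec$nRepetitions)) {
      seed <- spec$seeds[r]
      fit_out <- tryCatch({
        set.seed(seed)
        fitted <- est$fit(x_tr, y_tr)
        pred <- fitted$predict(x_te)
        if (length(pred) != length(y_te) || any(!is.finite(pred)))
          stop("estimator contract violated: non-finite or wrong-length predictions")
        list(pred = as.numeric(pred))
      }, error = function(e) {
        warning("estimator ", est$name, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(fit_out)) {
        metrics <- c(rmse = NA_real_, pearson = NA_real_, auprc = NA_real_)
      } else {
        pred <- fit_out$pred
        scatter[[length(scatter) + 1L]] <- data.frame(
          estimator = est$name, repetition = r, truth = y_te, pred = pred)
        metrics <- c(rmse = rmse(pred, y_te),
                     pearson = suppressWarnings(pearsonCor(pred, y_te)),
                     auprc = auprc(pred, lab_te))
      }
      raw[[length(raw) + 1L]] <- data.frame(
        estimator = est$name, repetition = r, seed = seed,
        rmse = metrics["rmse"], pearson = metrics["pearson"],
        auprc = metrics["auprc"], row.names = NULL)
    }
  }
  raw <- do.call(rbind, raw)
  summ <- do.call(rbind, lapply(split(raw, raw$estimator), function(d) {
    do.call(rbind, lapply(c("rmse", "pearson", "auprc"), function(m) {
      s <- stats::sd(d[[m]])
      data.frame(estimator = d$estimator[1], metric = m,
                 mean = mean(d[[m]]), sd = if (is.na(s)) 0 else s)
    }))
  }))
  rownames(summ) <- NULL
  scatter <- if (length(scatter)) do.call(rbind, scatter) else
    data.frame(estimator = character(0), repetition = integer(0),
               truth = numeric(0), pred = numeric(0))
  new("ScenarioReport", summary = summ, raw = raw, scatter = scatter,
      scenario = as.numeric(spec$id))
}
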