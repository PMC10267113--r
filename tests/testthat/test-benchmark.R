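test_that("metric primitives match hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_equal(pearsonCor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_warning(r <- pearsonCor(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_equal(r, 0)
})

test_that("average precision matches hand-worked rankings", {
  # perfect ranking
  expect_equal(auprc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  # positive ranked last among n: AP = 1/n
  expect_equal(auprc(c(3, 2, 1), c(FALSE, FALSE, TRUE)), 1 / 3)
  expect_equal(auprc(c(5, 4, 3, 2, 1), c(FALSE, FALSE, FALSE, FALSE, TRUE)),
               1 / 5)
  # hand-worked: labels at ranks 1 and 3 -> (1/1 + 2/3)/2
  expect_equal(auprc(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE)),
               (1 + 2 / 3) / 2)
  # ties broken by input order (stable)
  expect_equal(auprc(c(1, 1), c(TRUE, FALSE)), 1)
  expect_equal(auprc(c(1, 1), c(FALSE, TRUE)), 1 / 2)
  expect_error(auprc(c(1, 2), c(FALSE, FALSE)), "no positive")
})

test_that("scenario construction filters and stays disjoint", {
  gen <- genFeatureTable(300, seed = 21)
  s <- gen$samples
  sp1 <- buildScenario(s, scenarioSpec(1))
  sp2 <- buildScenario(s, scenarioSpec(2))
  sp3 <- buildScenario(s, scenarioSpec(3))
  # the test set is always the TKI stratum
  for (sp in list(sp1, sp2, sp3)) {
    expect_setequal(sp$test, which(s$source == "tki"))
    expect_length(intersect(sp$train, sp$test), 0)
    triple <- paste(s$uniprot_id, s$drug, s$mutation)
    expect_length(intersect(triple[sp$train], triple[sp$test]), 0)
  }
  # scenario 1 trains on non-TK platinum only; scenario 2 adds the rest of
  # platinum, so train(1) is contained in train(2)
  expect_true(all(sp1$train %in% sp2$train))
  expect_true(length(sp2$train) > length(sp1$train))
  expect_true(all(s$source[sp1$train] == "platinum"))
  expect_true(all(!s$tyrosine_kinase[sp1$train]))
  # scenario 3 trains on single substitutions only
  expect_true(all(s$mutation_type[sp3$train] == "single_substitution"))
  expect_true(all(s$source[sp3$train] != "tki"))
  s_no_tk <- s; s_no_tk$tyrosine_kinase <- NULL
  expect_error(buildScenario(s_no_tk, scenarioSpec(1)), "tyrosine_kinase")
  s_no_test <- s[s$source != "tki", ]
  expect_error(buildScenario(s_no_test, scenarioSpec(2)), "no TKI")
})

test_that("an oracle estimator scores rmse 0, pearson 1, auprc 1", {
  w <- c(1.5, -1, 0.8, 0, 0.5)
  gen <- genFeatureTable(200, weights = w, noiseSigma = 0, seed = 31)
  oracle <- list(oracle = list(name = "oracle", family = "oracle",
    fit = function(x, y) list(predict = function(nx)
      as.numeric(as.matrix(nx) %*% w))))
  rep <- runBenchmark(gen$samples, gen$features, oracle,
                      scenarioSpec(2, nRepetitions = 2))
  sm <- rep@summary
  expect_equal(sm$mean[sm$metric == "rmse"], 0, tolerance = 1e-10)
  expect_equal(sm$mean[sm$metric == "pearson"], 1, tolerance = 1e-10)
  expect_equal(sm$mean[sm$metric == "auprc"], 1)
  expect_equal(sm$sd, rep(0, 3))
  # scatter holds the predictions of both repetitions
  expect_equal(nrow(rep@scatter),
               2L * sum(gen$samples$source == "tki"))
  expect_equal(rep@scatter$pred, rep@scatter$truth, tolerance = 1e-10)
})

test_that("a constant predictor yields pearson 0 and finite rmse", {
  gen <- genFeatureTable(120, seed = 32)
  const <- list(const = list(name = "const", family = "baseline",
    fit = function(x, y) {
      m <- mean(y)
      list(predict = function(nx) rep(m, nrow(nx)))
    }))
  rep <- runBenchmark(gen$samples, gen$features, const,
                      scenarioSpec(3, nRepetitions = 1))
  sm <- rep@summary
  expect_equal(sm$mean[sm$metric == "pearson"], 0)
  expect_true(is.finite(sm$mean[sm$metric == "rmse"]))
  expect_equal(sm$sd, rep(0, 3))  # single repetition: sd defined as 0
})

test_that("a failing estimator yields NA metrics without aborting", {
  gen <- genFeatureTable(100, seed = 33)
  ests <- c(
    list(broken = list(name = "broken", family = "x",
                       fit = function(x, y) stop("boom"))),
    builtinEstimators("decision_tree"))
  expect_warning(rep <- runBenchmark(gen$samples, gen$features, ests,
                                     scenarioSpec(2, nRepetitions = 1)),
                 "broken failed")
  sm <- rep@summary
  expect_true(all(is.na(sm$mean[sm$estimator == "broken"])))
  expect_true(all(is.finite(sm$mean[sm$estimator == "decision_tree"])))
})

test_that("fixed seeds give identical reports", {
  gen <- genFeatureTable(150, seed = 34)
  ests <- builtinEstimators(c("decision_tree", "bagging"))
  r1 <- runBenchmark(gen$samples, gen$features, ests, scenarioSpec(2))
  r2 <- runBenchmark(gen$samples, gen$features, ests, scenarioSpec(2))
  expect_identical(r1@summary, r2@summary)
  expect_identical(r1@raw, r2@raw)
  expect_identical(r1@scatter, r2@scatter)
})

test_that("all ten built-in estimator slots run on a linear corpus", {
  ests <- builtinEstimators()
  expect_length(ests, 10L)
  expect_setequal(names(ests),
                  c("decision_tree", "random_forest", "extra_trees", "svr",
                    "elastic_net", "lasso", "bagging", "adaboost",
                    "gradient_boost", "mlp"))
  gen <- genFeatureTable(250, seed = 35)
  rep <- suppressWarnings(
    runBenchmark(gen$samples, gen$features, ests,
                 scenarioSpec(2, nRepetitions = 1)))
  sm <- rep@summary
  expect_true(all(is.finite(sm$mean)))
  expect_equal(sort(unique(sm$estimator)), sort(names(ests)))
  expect_error(builtinEstimators("nope"), "unknown estimator")
})

test_that("extra trees recover a strong linear signal", {
  gen <- genFeatureTable(2000, noiseSigma = 0.2, seed = 36)
  rep <- runBenchmark(gen$samples, gen$features,
                      builtinEstimators("extra_trees"),
                      scenarioSpec(3, nRepetitions = 2))
  sm <- rep@summary
  expect_true(sm$mean[sm$metric == "pearson"] >= 0.9)
})
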