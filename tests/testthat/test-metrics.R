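test_that("residuals, bias, precision, MSE and P30 match their definitions", {
  obs <- c(50, 60, 70)
  pred <- c(52, 58, 75)
  expect_equal(nbgfr_residuals(obs, pred), c(-2, 2, -5))
  expect_equal(nbgfr_residuals(47, 48.75), -1.75)
  expect_equal(nbgfr_bias(obs, pred), -2)
  expect_equal(nbgfr_bias(obs, obs), 0)
  # symmetric residuals have zero median
  expect_equal(nbgfr_bias(c(10, 10, 10, 10) + c(-4, -2, 2, 4),
                          c(10, 10, 10, 10)), 0)
  # linear-interpolation IQR on 1..4 is 3.25 - 1.75
  expect_equal(nbgfr_precision(c(1, 2, 3, 4), c(0, 0, 0, 0)), 1.5)
  expect_equal(nbgfr_precision(c(5, 5, 5), c(2, 2, 2)), 0)
  expect_equal(nbgfr_mse(c(13, 6), c(10, 10)), 12.5)
  expect_equal(nbgfr_mse(obs, obs), 0)
  expect_equal(nbgfr_mse(44, 41), 9)
  expect_equal(p30_accuracy(c(100, 100), c(129, 131)), 50)
  expect_equal(p30_accuracy(obs, obs), 100)
  expect_equal(p30_accuracy(100, 130), 100) # boundary is inclusive
  expect_equal(p30_accuracy(100, 130.0001), 0)
  expect_error(nbgfr_residuals(1:3, 1:4), "equal length")
  expect_error(nbgfr_residuals(c(1, NA), c(1, 2)), "missing")
})

test_that("Pearson r hits the exact endpoints and errors on zero variance", {
  obs <- c(30, 42, 55, 61, 78)
  expect_equal(pearson_r(obs, 3 + 0.8 * obs), 1)
  expect_equal(pearson_r(obs, 90 - 1.1 * obs), -1)
  pred <- c(35, 40, 50, 70, 71)
  expect_equal(pearson_r(obs, pred), oracle_pearson(obs, pred),
               tolerance = 1e-12)
  expect_error(pearson_r(obs, rep(5, 5)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least 3")
})

test_that("midrank AUC agrees with exhaustive pair counting", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 2.5)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(7, 7, 7, 7)), 0.5)
  # perfectly anti-ranked
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 2, 3, 4)), 0)
  set.seed(21)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4)) # force both classes
    scores <- round(rnorm(n), sample(0:2, 1)) # rounding induces ties
    expect_equal(roc_auc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.9)), "one outcome class")
})

test_that("midrank AUC agrees with pROC on a tied-score cohort", {
  skip_if_not_installed("pROC")
  set.seed(33)
  labels <- rbinom(80, 1, 0.45)
  labels[1:2] <- c(0, 1)
  scores <- round(rnorm(80), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
})

test_that("threshold AUC applies the strict preoperative subset rule", {
  egfr_pre <- c(40, 45, 46, 60, 70, 80)
  obs <- c(30, 40, 44, 46, 50, 60)
  pred <- c(28, 39, 40, 47, 52, 58)
  out <- roc_auc_nbgfr45(egfr_pre, obs, pred)
  expect_equal(out$n, 4) # 40 and the boundary 45 are excluded
  expect_equal(out$n_positive, 3) # observed 46, 50, 60
  expect_equal(out$auc, oracle_auc(obs[3:6] > 45, pred[3:6]))
  expect_error(roc_auc_nbgfr45(c(50, 60), c(50, 60), c(1, 2)),
               "one outcome class")
  expect_error(roc_auc_nbgfr45(c(10, 20), c(30, 50), c(1, 2)), "subset")
})

test_that("metrics are invariant to record order and translate correctly", {
  set.seed(5)
  case <- random_metric_case(40)
  perm <- sample(40)
  expect_equal(nbgfr_bias(case$obs[perm], case$pred[perm]),
               nbgfr_bias(case$obs, case$pred))
  expect_equal(nbgfr_mse(case$obs[perm], case$pred[perm]),
               nbgfr_mse(case$obs, case$pred))
  expect_equal(pearson_r(case$obs[perm], case$pred[perm]),
               pearson_r(case$obs, case$pred))
  # shifting observed and predicted together shifts bias by nothing and
  # leaves precision unchanged
  expect_equal(nbgfr_bias(case$obs + 7, case$pred + 7),
               nbgfr_bias(case$obs, case$pred))
  expect_equal(nbgfr_precision(case$obs + 7, case$pred + 7),
               nbgfr_precision(case$obs, case$pred))
  # shifting only predicted moves bias one-for-one
  expect_equal(nbgfr_bias(case$obs, case$pred + 3),
               nbgfr_bias(case$obs, case$pred) - 3)
})
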