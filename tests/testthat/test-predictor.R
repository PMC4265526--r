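pair_df <- function(d1, d2, t = "bt", p = "af") {
  out <- data.frame(id1 = paste0("a", seq_along(d1)),
                    id2 = paste0("b", seq_along(d1)),
                    bt = NA_real_, nw = NA_real_, bl = NA_real_,
                    af = NA_real_, stringsAsFactors = FALSE)
  out[[t]] <- d1
  out[[p]] <- d2
  out
}

test_that("percentile vector is the nearest-rank estimator of length m", {
  vals <- seq(0.01, 1, by = 0.01)
  expect_equal(percentile_vector(sample(vals), m = 100), sort(vals))
  expect_equal(percentile_vector(rep(0.4, 57)), rep(0.4, 100))
  pv <- percentile_vector(runif(1234))
  expect_length(pv, 100L)
  expect_true(all(diff(pv) >= 0))
  # nearest rank on a small sample: component i = sorted[ceiling(i*n/m)]
  x <- c(5, 1, 9)
  expect_equal(percentile_vector(x, m = 3), c(1, 5, 9))
  expect_equal(percentile_vector(x, m = 100),
               sort(x)[ceiling((1:100) * 3 / 100)])
  expect_error(percentile_vector(numeric(0)), "empty")
})

test_that("confusion counts enumerate the threshold rule", {
  d1 <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  d2 <- c(0.2, 0.1, 0.5, 0.9, 0.7, 1.0)
  # direct enumeration: positives (0.1,0.2) (0.2,0.1) (0.4,0.5) all called
  # positive; (0.6,0.9) (0.8,0.7) (1.0,1.0) all called negative
  cc <- confusion_at(pair_df(d1, d2), "bt", "af", alpha = 0.5, beta = 0.6)
  expect_equal(cc, c(tp = 3L, fp = 0L, tn = 3L, fn = 0L))
  expect_equal(sum(cc), 6L)

  # perfect predictor: predictor == target and beta == alpha
  cc <- confusion_at(pair_df(d1, d1), "bt", "af", 0.5, 0.5)
  expect_equal(unname(cc[c("fp", "fn")]), c(0L, 0L))
  # beta = 1 predicts everything positive
  cc <- confusion_at(pair_df(d1, d2), "bt", "af", 0.5, 1)
  expect_equal(unname(cc[c("fn", "tn")]), c(0L, 0L))

  miss <- pair_df(d1, d2); miss$af[2] <- NA
  expect_error(confusion_at(miss, "bt", "af", 0.5, 0.5), "missing")
})

test_that("tp+fn and tn+fp are invariant in beta, rates monotone in beta", {
  set.seed(201)
  d1 <- runif(300); d2 <- pmin(1, pmax(0, d1 + rnorm(300, 0, 0.2)))
  pairs <- pair_df(d1, d2)
  alpha <- 0.4
  betas <- seq(0, 1, by = 0.05)
  cc <- vapply(betas, function(b) confusion_at(pairs, "bt", "af", alpha, b),
               integer(4))
  expect_true(all(cc["tp", ] + cc["fn", ] == sum(d1 <= alpha)))
  expect_true(all(cc["tn", ] + cc["fp", ] == sum(d1 > alpha)))
  tpr <- cc["tp", ] / (cc["tp", ] + cc["fn", ])
  fpr <- cc["fp", ] / (cc["fp", ] + cc["tn", ])
  expect_true(all(diff(tpr) >= 0))
  expect_true(all(diff(fpr) >= 0))
})

test_that("ROC curve hits the derived points and the perfect-predictor AUC", {
  d1 <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  d2 <- c(0.2, 0.1, 0.5, 0.9, 0.7, 1.0)
  roc <- roc_curve(pair_df(d1, d2), "bt", "af", alpha = 0.5,
                   candidate_betas = sort(d2))
  # hand enumeration: positives {0.2,0.1,0.5}, negatives {0.9,0.7,1.0}
  expect_equal(roc$points$tpr, c(0, 1/3, 2/3, 3/3, 3/3, 3/3, 3/3, 1))
  expect_equal(roc$points$fpr, c(0, 0, 0, 0, 1/3, 2/3, 3/3, 1))
  expect_equal(roc$auc, 1)

  perfect <- roc_curve(pair_df(d1, d1), "bt", "af", 0.4, sort(d1))
  expect_equal(perfect$auc, 1)
  expect_error(roc_curve(pair_df(d1, d2), "bt", "af", 2, d2), "alpha")
  expect_error(roc_curve(pair_df(d1, d2), "bt", "af", 0.5, numeric(0)),
               "empty")
})

test_that("an independent predictor has AUC near one half", {
  set.seed(202)
  d1 <- runif(5000); d2 <- runif(5000)
  roc <- roc_curve(pair_df(d1, d2), "bt", "af", 0.3,
                   percentile_vector(d2))
  expect_lt(abs(roc$auc - 0.5), 0.05)
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  set.seed(203)
  for (i in 1:100) {
    d1 <- runif(50)
    d2 <- pmin(1, pmax(0, d1 + rnorm(50, 0, 0.3)))
    if (i %% 3 == 0) d2 <- round(d2, 1)  # force ties
    alpha <- runif(1, 0.2, 0.8)
    if (sum(d1 <= alpha) == 0 || sum(d1 > alpha) == 0) next
    roc <- roc_curve(pair_df(d1, d2), "bt", "af", alpha,
                     candidate_betas = sort(unique(d2)))
    expect_equal(roc$auc, oracle_auc_mw(d1, d2, alpha), tolerance = 1e-12)
  }
})

test_that("training a self-predictor recovers beta = alpha exactly", {
  set.seed(204)
  d1 <- runif(500)
  fit <- train_predictor(pair_df(d1, d1), "bt", "af")
  expect_s3_class(fit, "threshold_predictor")
  expect_length(fit$alpha, 100L)
  expect_length(fit$beta, 100L)
  expect_equal(fit$beta, fit$alpha)
  expect_true(all(fit$auc == 1))
  for (i in c(1, 37, 100)) {
    cc <- confusion_at(pair_df(d1, d1), "bt", "af",
                       fit$alpha[i], fit$beta[i])
    expect_equal(unname(cc[c("fp", "fn")]), c(0L, 0L))
  }
})

test_that("an anti-predictor never beats chance at any level", {
  set.seed(205)
  d1 <- runif(400)
  fit <- train_predictor(pair_df(d1, 1 - d1), "bt", "af")
  # levels with alpha = max(d1) have no negatives and are trivially perfect
  informative <- fit$alpha < max(d1)
  expect_true(any(informative))
  expect_true(all(fit$auc[informative] <= 0.5 + 1e-9))
})

test_that("training rejects degenerate and undersized samples", {
  expect_error(train_predictor(pair_df(rep(0.5, 200), runif(200)),
                               "bt", "af"), "degenerate")
  expect_error(train_predictor(pair_df(runif(50), runif(50)), "bt", "af"),
               "at least m")
})

test_that("training is invariant under monotone predictor transforms", {
  set.seed(206)
  d1 <- runif(300); d2 <- pmin(1, pmax(0, d1 + rnorm(300, 0, 0.15)))
  fit <- train_predictor(pair_df(d1, d2), "bt", "af")
  for (g in list(function(x) x^3, function(x) 1 - exp(-3 * x))) {
    fit_g <- train_predictor(pair_df(d1, g(d2)), "bt", "af")
    expect_equal(fit_g$beta_index, fit$beta_index)
    expect_equal(fit_g$beta, g(fit$beta))
    expect_equal(fit_g$auc, fit$auc, tolerance = 1e-12)
  }
})

test_that("evaluate_level reports rates and NA on an empty class", {
  set.seed(207)
  d1 <- runif(250)
  fit <- train_predictor(pair_df(d1, d1), "bt", "af")
  ev <- evaluate_level(fit, pair_df(d1, d1), 40)
  expect_equal(ev$tp_rate, 1)
  expect_equal(ev$tn_rate, 1)
  expect_error(evaluate_level(fit, pair_df(d1, d1), 0), "level")

  # a test sample with no pair below alpha_1 leaves the rate undefined
  shifted <- pair_df(pmin(1, d1 + fit$alpha[1] + 0.01), d1)
  ev <- evaluate_level(fit, shifted, 1)
  expect_true(is.na(ev$tp_rate))
})

test_that("cross-validation on identical self-predicting samples is exact", {
  set.seed(208)
  d1 <- runif(300)
  samples <- lapply(1:6, function(i) pair_df(d1, d1))
  cv <- cross_validate(samples, "bt", "af",
                       reference_values = c(0.105, 0.15, 0.205, 0.25))
  expect_equal(nrow(cv$per_fold), 24L)  # 6 training rows x 4 references
  expect_true(all(cv$per_fold$tp_pct == 100))
  expect_true(all(cv$per_fold$tn_pct == 100))
  expect_true(all(cv$average$total_pct == 100))
  expect_error(cross_validate(samples[1], "bt", "af"), ">= 2")
})

test_that("cross-validation generalizes across i.i.d. samples", {
  set.seed(209)
  mk <- function() {
    d1 <- runif(400)
    pair_df(d1, pmin(1, pmax(0, d1 + rnorm(400, 0, 0.1))))
  }
  cv <- cross_validate(lapply(1:3, function(i) mk()), "bt", "af",
                       reference_values = c(0.2, 0.4))
  expect_equal(nrow(cv$per_fold), 6L)
  # a predictor this correlated must do far better than chance out of fold
  expect_true(all(cv$average$tp_pct > 60))
  expect_true(all(cv$average$tn_pct > 60))
})

test_that("Pearson matrix is symmetric with unit diagonal", {
  set.seed(210)
  n <- 40
  pairs <- data.frame(id1 = paste0("a", 1:n), id2 = paste0("b", 1:n),
                      bt = runif(n), nw = runif(n), bl = runif(n),
                      af = runif(n), stringsAsFactors = FALSE)
  pairs$af <- 1 - pairs$bt   # perfectly anti-correlated pair of columns
  pm <- pearson_matrix(pairs)
  expect_equal(diag(pm), c(bt = 1, nw = 1, bl = 1, af = 1))
  expect_equal(pm, t(pm))
  expect_equal(pm["bt", "af"], -1)

  # direct product-moment formula on a 5-pair hand table
  five <- pairs[1:5, ]
  pm5 <- pearson_matrix(five)
  x <- five$bt; y <- five$nw
  expect_equal(pm5["bt", "nw"],
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))

  pairs$nw <- 0.7
  expect_error(pearson_matrix(pairs), "zero-variance.*nw")
})
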