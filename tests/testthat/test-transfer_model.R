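test_that("elastic net limits: zero penalty is OLS, huge penalty is intercept-only", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5), 200, 5)
  beta <- c(1.5, -2, 0.5, 0, 1)
  y <- drop(X %*% beta) + rnorm(200, sd = 0.1)
  fit0 <- fit_elastic_net(X, y, params = elastic_net_params(penalty_strength = 0))
  ols <- lm(y ~ X)
  expect_equal(fit0$coef, unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-6)

  w <- runif(200, 0.5, 2)
  fit_big <- fit_elastic_net(X, y, sample_weights = w,
                             params = elastic_net_params(penalty_strength = 1e6))
  expect_equal(fit_big$coef, rep(0, 5), tolerance = 1e-8)
  expect_equal(fit_big$intercept, weighted.mean(y, w), tolerance = 1e-6)

  fit_rec <- fit_elastic_net(X, drop(X %*% beta),
                             params = elastic_net_params(penalty_strength = 1e-6))
  expect_equal(fit_rec$coef, beta, tolerance = 1e-2)
})

test_that("degenerate elastic-net inputs are handled", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_elastic_net(X[, 0, drop = FALSE], rnorm(10)), "feature")
  flat <- fit_elastic_net(X, rep(3, 10))
  expect_equal(flat$coef, c(0, 0))
  expect_equal(flat$intercept, 3)
  expect_error(fit_elastic_net(X, c(rnorm(9), NA)), "non-finite")
})

test_that("boost round reproduces the scalar hand computation", {
  # 2 source + 2 target instances, hand-set absolute errors
  w <- rep(0.25, 4)
  is_src <- c(TRUE, TRUE, FALSE, FALSE)
  abs_err <- c(2, 0, 1, 0.5)
  n_S <- 2; N <- 10
  beta_S <- 1 / (1 + sqrt(2 * log(n_S) / N))
  upd <- boost_round(w, is_src, abs_err, beta_S)
  # scalar recomputation of the update formulas
  e <- abs_err / 2
  eps_t <- (0.25 * 0.5 + 0.25 * 0.25) / 0.5
  expect_equal(upd$eps_t, eps_t)
  beta_t <- eps_t / (1 - eps_t)
  expect_equal(upd$beta_t, beta_t)
  w_hand <- c(0.25 * beta_S ^ 1, 0.25 * beta_S ^ 0,
              0.25 * beta_t ^ -0.5, 0.25 * beta_t ^ -0.25)
  expect_equal(upd$weights, w_hand / sum(w_hand))
  expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
})

test_that("boost round edge behavior matches the update rules", {
  w <- c(0.3, 0.2, 0.3, 0.2)
  is_src <- c(TRUE, TRUE, FALSE, FALSE)
  # equal errors keep within-set relative weights
  upd <- boost_round(w, is_src, rep(1.3, 4), beta_source = 0.7)
  expect_equal(upd$weights[1] / upd$weights[2], 0.3 / 0.2)
  expect_equal(upd$weights[3] / upd$weights[4], 0.3 / 0.2)
  # eps_t >= 0.5 caps the estimator confidence at zero
  expect_equal(upd$beta_t, 1)
  # a source instance with maximal error loses weight, zero error keeps it
  upd2 <- boost_round(w, is_src, c(1, 0, 0.2, 0.1), beta_source = 0.7)
  expect_lt(upd2$weights[1] / upd2$weights[2], w[1] / w[2])
  # perfect round signals early termination
  upd3 <- boost_round(w, is_src, rep(0, 4), beta_source = 0.7)
  expect_true(upd3$perfect)
})

test_that("weights stay on the probability simplex across random rounds", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    w <- runif(n); w <- w / sum(w)
    is_src <- runif(n) < 0.5
    if (all(is_src)) is_src[1] <- FALSE
    upd <- boost_round(w, is_src, runif(n, 0, 3), beta_source = runif(1, 0.5, 0.95))
    expect_equal(sum(upd$weights), 1, tolerance = 1e-12)
    expect_true(all(upd$weights >= 0))
  }
})

test_that("target weight mass is non-decreasing while eps_t < 0.5", {
  set.seed(9)
  w <- rep(1 / 10, 10)
  is_src <- rep(c(TRUE, FALSE), each = 5)
  # frozen toy errors: sources predicted poorly, targets well
  abs_err <- c(runif(5, 1, 2), runif(5, 0, 0.4))
  for (round in 1:5) {
    upd <- boost_round(w, is_src, abs_err, beta_source = 0.8)
    expect_lt(upd$eps_t, 0.5)
    expect_gte(sum(upd$weights[!is_src]), sum(w[!is_src]) - 1e-12)
    w <- upd$weights
  }
})

test_that("weighted median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(5), c(2)), 5)
  expect_equal(weighted_median(c(1, 2, 9), rep(1, 3)), 2)
  expect_equal(weighted_median(c(1, 2, 9), c(0.7, 0.2, 0.1)), 1)
  expect_equal(weighted_median(c(9, 1, 2), c(0.1, 0.7, 0.2)), 1)
})

test_that("fitting is deterministic and prediction uses the kept estimators", {
  set.seed(10)
  XS <- matrix(rnorm(100 * 6), 100, 6); colnames(XS) <- paste0("f", 1:6)
  XT <- matrix(rnorm(30 * 6), 30, 6); colnames(XT) <- paste0("f", 1:6)
  yS <- drop(XS %*% rnorm(6)) + rnorm(100, sd = 0.2)
  yT <- drop(XT %*% rnorm(6)) + rnorm(30, sd = 0.2)
  m1 <- tradaboost_fit(XS, yS, XT, yT)
  m2 <- tradaboost_fit(XS, yS, XT, yT)
  expect_identical(m1, m2)
  expect_identical(predict(m1, XT), predict(m2, XT))
  expect_length(m1$estimators, 5)       # last ceil(10/2) rounds kept
  expect_true(all(m1$estimator_weights >= 0))
  # column mismatch errors
  Xbad <- XT; colnames(Xbad) <- paste0("g", 1:6)
  expect_error(predict(m1, Xbad), "missing feature")
  expect_error(tradaboost_fit(XS[, 1:5], yS, XT, yT), "mismatch")
})

test_that("an empty source reduces to boosting on the target alone", {
  set.seed(11)
  XT <- matrix(rnorm(40 * 4), 40, 4); colnames(XT) <- paste0("f", 1:4)
  yT <- drop(XT %*% c(1, -1, 0.5, 0)) + rnorm(40, sd = 0.1)
  m <- tradaboost_fit(XT[0, , drop = FALSE], numeric(0), XT, yT,
                      en = elastic_net_params(penalty_strength = 0.01))
  pred <- predict(m, XT)
  expect_gt(cor(pred, yT), 0.95)
  expect_length(pred, 40)
})

test_that("matched source and target support accurate held-out prediction", {
  set.seed(12)
  p <- 10
  beta <- rnorm(p)
  gen <- function(n) {
    X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
    list(X = X, y = drop(X %*% beta) + rnorm(n, sd = 0.1))
  }
  S <- gen(800); T_ <- gen(200); E <- gen(200)
  m <- tradaboost_fit(S$X, S$y, T_$X, T_$y,
                      en = elastic_net_params(penalty_strength = 0.01))
  pred <- predict(m, E$X)
  r2 <- 1 - sum((pred - E$y) ^ 2) / sum((E$y - mean(E$y)) ^ 2)
  expect_gt(r2, 0.9)
})

test_that("fitted models survive a JSON round trip", {
  set.seed(13)
  XS <- matrix(rnorm(60 * 4), 60, 4); colnames(XS) <- paste0("f", 1:4)
  XT <- matrix(rnorm(20 * 4), 20, 4); colnames(XT) <- paste0("f", 1:4)
  m <- tradaboost_fit(XS, drop(XS %*% rnorm(4)) + rnorm(60, sd = .2),
                      XT, drop(XT %*% rnorm(4)) + rnorm(20, sd = .2))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict(m2, XT), predict(m, XT), tolerance = 1e-12)
})
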