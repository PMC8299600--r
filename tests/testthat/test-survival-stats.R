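# Survival statistics: Cox fits, screening, KM/log-rank, mean split,
# correlations, group comparison.

test_that("univariate Cox recovers a planted coefficient", {
  set.seed(101)
  n <- 2000
  x <- rnorm(n)
  sv <- simulate_survival(x, beta = 0.5, h0 = 1 / 400)
  fit <- cox_univariate(x, sv$os_days, sv$os_event)
  expect_true(fit$converged)
  expect_gt(fit$beta, 0.4)
  expect_lt(fit$beta, 0.6)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci95[1] < fit$hr && fit$hr < fit$ci95[2])
  # degenerate: zero-variance feature flagged, not an error
  flat <- cox_univariate(rep(1, n), sv$os_days, sv$os_event)
  expect_false(flat$converged)
  expect_true(is.na(flat$p))
})

test_that("Cox estimates are nearly unbiased across effect sizes", {
  set.seed(202)
  for (beta in c(-1, 0, 1)) {
    n <- 3000
    x <- rnorm(n)
    sv <- simulate_survival(x, beta = beta, h0 = 1 / 400,
                            censor_window = 1200)  # ~30% censoring
    fit <- cox_univariate(x, sv$os_days, sv$os_event)
    expect_lt(abs(fit$beta - beta), 0.08)
  }
})

test_that("Wald p-values are calibrated under the null", {
  set.seed(303)
  ps <- replicate(200, {
    x <- rnorm(120)
    sv <- simulate_survival(x, beta = 0, h0 = 1 / 400,
                            censor_window = 1500)
    cox_univariate(x, sv$os_days, sv$os_event)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("screening selects by Wald p in vocabulary order", {
  set.seed(7)
  n <- 250
  x <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(NULL, sprintf("f%02d", 1:30)))
  x[, 17] <- x[, 17] * 0  # constant column: never selected
  sv <- simulate_survival(x[, 5], beta = 1, h0 = 1 / 400,
                          censor_window = 1500)
  sc <- select_valid_features(x, sv$os_days, sv$os_event)
  expect_true("f05" %in% sc$valid)
  expect_false("f17" %in% sc$valid)
  expect_identical(sc$valid,
                   sc$table$feature[sc$table$valid])  # vocabulary order
  # the cap keeps the smallest p-values
  sc2 <- select_valid_features(x, sv$os_days, sv$os_event,
                               max_features = 1)
  expect_identical(sc2$valid, "f05")
  # empty selection warns but returns
  y <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  svn <- simulate_survival(rep(0, 20), 0, 1 / 400)
  expect_warning(
    sc3 <- select_valid_features(y, svn$os_days, svn$os_event,
                                 alpha = 1e-6), "no valid")
  expect_length(sc3$valid, 0)
})

test_that("correlation matrix has unit diagonal and masks degenerate cols", {
  set.seed(8)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, 3] <- -x[, 1]
  cm <- feature_correlation_matrix(x)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["a", "c"], -1)
  expect_true(isSymmetric(cm))
  # independent columns are near-uncorrelated at n = 5000
  y <- matrix(rnorm(10000), 5000, 2, dimnames = list(NULL, c("u", "v")))
  expect_lt(abs(feature_correlation_matrix(y)["u", "v"]), 0.05)
  # zero-variance column masked
  x[, 2] <- 0
  cm2 <- suppressWarnings(feature_correlation_matrix(x))
  expect_true(is.na(cm2["a", "b"]))
})

test_that("KM estimate matches the hand product-limit computation", {
  km <- km_estimate(1:5, rep(1L, 5))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$survival[km$time == 3], 0.4)
  expect_equal(km$n_at_risk, 5:1)
  # no censoring: KM equals the empirical survival function
  set.seed(9)
  t <- rexp(50)
  km2 <- km_estimate(t, rep(1L, 50))
  emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("log-rank matches a brute-force observed/expected computation", {
  set.seed(10)
  os <- c(rexp(12, 1 / 200), rexp(8, 1 / 100))
  ev <- rbinom(20, 1, 0.8)
  grp <- rep(c("a", "b"), c(12, 8))
  ev[1] <- 1L  # ensure at least one event
  got <- logrank_test(os, ev, grp)
  # brute force over distinct event times
  times <- sort(unique(os[ev == 1]))
  o1 <- e1 <- v <- 0
  for (tt in times) {
    at1 <- sum(os >= tt & grp == "a")
    at2 <- sum(os >= tt & grp == "b")
    d1 <- sum(os == tt & ev == 1 & grp == "a")
    d2 <- sum(os == tt & ev == 1 & grp == "b")
    n <- at1 + at2
    d <- d1 + d2
    o1 <- o1 + d1
    e1 <- e1 + d * at1 / n
    if (n > 1) v <- v + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  expect_equal(got$chi2, chi2, tolerance = 1e-8)
  # identical groups: chi2 = 0, p = 1
  same <- logrank_test(c(os, os), c(ev, ev), rep(c("x", "y"), each = 20))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-9)
  # label swap invariance
  swap <- logrank_test(os, ev, ifelse(grp == "a", "b", "a"))
  expect_equal(swap$p, got$p)
})

test_that("mean split dichotomizes at the mean with ties to low", {
  sv <- simulate_survival(rep(0, 4), 0, 1 / 100)
  ms <- mean_split_stratify(c(1, 2, 3, 100), sv$os_days,
                            pmax(sv$os_event, 1L))
  expect_equal(which(ms$high), 4L)
  expect_error(mean_split_stratify(rep(2, 4), sv$os_days, sv$os_event),
               "empty group")
  # power: HR 3 groups separated by the value, n = 200
  set.seed(12)
  hits <- replicate(60, {
    val <- rep(c(0, 1), each = 100)
    s <- simulate_survival(val, beta = log(3), h0 = 1 / 400,
                           censor_window = 1500)
    mean_split_stratify(val + rnorm(200, 0, 1e-3), s$os_days,
                        s$os_event)$logrank$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("adjusted Cox handles orthogonal covariates and collinearity", {
  set.seed(13)
  n <- 1500
  x <- rnorm(n)
  covs <- data.frame(age = rnorm(n), load = rnorm(n))
  sv <- simulate_survival(x, beta = 0.6, h0 = 1 / 400,
                          censor_window = 1500)
  un <- cox_univariate(x, sv$os_days, sv$os_event)
  ad <- cox_adjusted(x, covs, sv$os_days, sv$os_event)
  expect_true(ad$converged)
  expect_lt(abs(ad$beta[["x"]] - un$beta), 0.1)
  # duplicated feature as covariate: flagged non-identifiable
  dup <- cox_adjusted(x, data.frame(again = x), sv$os_days, sv$os_event)
  expect_false(dup$converged)
})

test_that("group comparison is a symmetric unpaired t-test", {
  set.seed(14)
  a <- rnorm(100)
  b <- rnorm(100, 1)
  g1 <- group_compare(a, b)
  g2 <- group_compare(b, a)
  expect_equal(g1$p, g2$p)
  expect_equal(g1$t, -g2$t)
  expect_lt(g1$p, 1e-6)
  same <- group_compare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
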