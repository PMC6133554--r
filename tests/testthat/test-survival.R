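# Cox model, Kaplan-Meier and log-rank against enumeration oracles and
# recovery from the synthetic generator's known hazards.

test_that("Cox estimate matches the grid-search partial-likelihood oracle", {
  # two groups, no ties: A events at 1, 3; B events at 2, 4
  time <- c(1, 3, 2, 4)
  event <- rep(TRUE, 4)
  x <- c(0, 0, 1, 1)
  dat <- data.frame(time = time, event = event, x = x)
  fit <- fit_cox(dat, covariates = "x")
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) oracle_efron_loglik(b, x, time, event),
               numeric(1))
  b_star <- grid[which.max(ll)]
  expect_equal(fit$coefficients$estimate, b_star, tolerance = 1e-3)
})

test_that("Cox gradient vanishes at the estimate and the Hessian is negative definite", {
  set.seed(1)
  n <- 80
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  time <- rexp(n, 0.1 * exp(0.5 * x1))
  dat <- data.frame(time = time, event = TRUE, x1 = x1, x2 = x2)
  fit <- fit_cox(dat, covariates = c("x1", "x2"))
  beta <- fit$coefficients$estimate
  X <- cbind(x1, x2)
  g <- oracle_efron_gradient(beta, X, time, dat$event)
  # numeric central differences resolve to ~1e-5; the fit converges with
  # eps = 1e-12 so the residual gradient is below that resolution
  expect_lt(sqrt(sum(g^2)), 1e-4)
  # Hessian via numeric differentiation of the gradient: negative definite
  h <- 1e-4
  H <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    H[, j] <- (oracle_efron_gradient(beta + e, X, time, dat$event) -
                 oracle_efron_gradient(beta - e, X, time, dat$event)) / (2 * h)
  }
  expect_true(all(eigen((H + t(H)) / 2, only.values = TRUE)$values < 0))
})

test_that("a null binary covariate is covered by the CI at nominal rate", {
  covered <- 0
  for (i in 1:100) {
    set.seed(2000 + i)
    n <- 60
    dat <- data.frame(time = rexp(n, 0.2), event = TRUE,
                      x = rep(0:1, n / 2))
    fit <- fit_cox(dat, covariates = "x")
    cf <- fit$coefficients
    covered <- covered + (cf$ci_low <= 1 && cf$ci_high >= 1)
  }
  expect_gte(covered, 93)
})

test_that("a true log-HR of 1 is recovered with small bias", {
  ests <- vapply(1:25, function(i) {
    co <- simulate_cohort(
      600, survival = survival_spec(log_hr = c("CD8-hot_CD163-hot" = 1)),
      seed = 3000 + i)
    fit <- fit_cox(co$clinical, reference = "CD8-cold_CD163-cold")
    cf <- fit$coefficients
    cf$estimate[cf$term == "phenotypeCD8-hot_CD163-hot"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1), 0.1)
})

test_that("KM equals the empirical survival function without censoring", {
  # n = 4, distinct event times
  dat <- data.frame(time = c(2, 5, 7, 9), event = TRUE)
  km <- km_estimate(dat)
  expect_equal(km$survival, c(3, 2, 1, 0) / 4)
  # general: no censoring -> empirical survival at event times
  set.seed(4)
  t2 <- rexp(40)
  km2 <- km_estimate(data.frame(time = t2, event = TRUE))
  emp <- vapply(km2$time, function(tt) mean(t2 > tt), numeric(1))
  expect_equal(km2$survival, emp)
})

test_that("all-censored data keep survival at 1", {
  dat <- data.frame(time = c(1, 2, 3), event = FALSE)
  km <- km_estimate(dat)
  expect_true(all(km$survival == 1))
})

test_that("KM with censoring matches the manual risk-set oracle", {
  # worked 6-patient example: events at 1, 4, 6; censored at 2, 5, 7
  dat <- data.frame(time = c(1, 2, 4, 5, 6, 7),
                    event = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  km <- km_estimate(dat)
  ev <- km[km$n_event > 0, ]
  # by hand: S(1) = 5/6, S(4) = 5/6 * 3/4, S(6) = 5/6 * 3/4 * 1/2
  expect_equal(ev$survival[ev$time == 1], 5 / 6)
  expect_equal(ev$survival[ev$time == 4], 5 / 6 * 3 / 4)
  expect_equal(ev$survival[ev$time == 6], 5 / 6 * 3 / 4 * 1 / 2)
  oracle <- oracle_km(dat$time, dat$event)
  expect_equal(ev$survival, oracle$surv)
})

test_that("log-rank is null on paired identical event-time groups", {
  dat <- data.frame(time = rep(c(1, 3, 5, 8), 2), event = TRUE)
  res <- logrank_test(dat, rep(c("A", "B"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_equal(res$df, 1)
})

test_that("log-rank equals the tabulation oracle on a 10-patient example", {
  set.seed(5)
  time <- c(1.2, 2.5, 3.1, 4.7, 5.3, 0.8, 1.9, 3.6, 6.2, 7.4)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  group <- rep(c("A", "B"), each = 5)
  res <- logrank_test(data.frame(time = time, event = event), group)
  expect_equal(res$statistic, oracle_logrank_2group(time, event, group),
               tolerance = 1e-10)
})

test_that("two-group log-rank equals the Cox score test on untied data", {
  set.seed(6)
  n <- 60
  dat <- data.frame(time = rexp(n, 0.2 * exp(0.4 * rep(0:1, n / 2))),
                    event = TRUE, x = rep(0:1, n / 2))
  lr <- logrank_test(dat, dat$x)
  fit <- fit_cox(dat, covariates = "x")
  expect_equal(lr$statistic, fit$score_test, tolerance = 1e-6)
})

test_that("log-rank has power against a 3-fold hazard ratio", {
  rejections <- 0
  for (i in 1:100) {
    set.seed(7000 + i)
    n <- 200
    g <- rep(0:1, each = n)
    t <- rexp(2 * n, 0.1 * exp(log(3) * g))
    res <- logrank_test(data.frame(time = t, event = TRUE), g)
    rejections <- rejections + (res$p < 0.05)
  }
  expect_gte(rejections, 95)
})

test_that("single-group log-rank and degenerate Cox inputs error", {
  dat <- data.frame(time = 1:4, event = TRUE)
  expect_error(logrank_test(dat, rep("A", 4)), "2 groups")
  expect_error(fit_cox(data.frame(time = 1:4, event = c(TRUE, FALSE, FALSE, FALSE),
                                  x = 1:4), covariates = "x"), "2 events")
  expect_error(fit_cox(data.frame(time = 1:4, event = TRUE, x = 1),
                       covariates = "x"), "constant")
  expect_error(fit_cox(data.frame(time = c(-1, 2, 3), event = TRUE, x = 1:3),
                       covariates = "x"), "> 0")
})

test_that("the phenotype hazard table recovers a planted HR of 2", {
  co <- simulate_cohort(
    2000,
    phenotype_probs = c(0.4, rep(0.15, 2), rep(0.05, 6)),
    survival = survival_spec(log_hr = c("CD8-cold_CD163-hot" = log(2))),
    seed = 8)
  ht <- phenotype_hazard_table(co$clinical)
  cell <- ht$table[ht$table$phenotype == "CD8-cold_CD163-hot", ]
  expect_gt(cell$hr, 1.7)
  expect_lt(cell$hr, 2.4)
  ref <- ht$table[ht$table$reference, ]
  expect_equal(ref$hr, 1)
  expect_equal(sum(ht$table$n), 2000)
})

test_that("empty phenotype cells never receive an HR", {
  co <- simulate_cohort(
    300, phenotype_probs = c(0.5, 0.5, rep(0, 7)), seed = 9)
  ht <- phenotype_hazard_table(co$clinical)
  empty <- ht$table[ht$table$n == 0, ]
  expect_true(nrow(empty) > 0)
  expect_true(all(is.na(empty$hr)))
})

test_that("an all-reference cohort yields only the reference cell", {
  co <- simulate_cohort(100, phenotype_probs = c(1, rep(0, 8)), seed = 10)
  ht <- phenotype_hazard_table(co$clinical)
  expect_null(ht$fit)
  expect_equal(sum(!is.na(ht$table$hr)), 1)
  expect_equal(ht$table$hr[ht$table$reference], 1)
})

test_that("univariate density-survival mirrors a null association", {
  set.seed(11)
  co <- simulate_cohort(400, seed = 12)
  dens <- data.frame(
    patient_id = rep(co$clinical$patient_id, 2),
    marker = rep(c("CD8", "CD163"), each = 400),
    compartment = "TU_CORE",
    density = rexp(800, 1 / 40))
  res <- density_survival(co$clinical, dens)
  expect_equal(nrow(res), 2)
  expect_true(all(abs(res$hr - 1) < 0.01))
  expect_true(all(res$p > 0.001))
})
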