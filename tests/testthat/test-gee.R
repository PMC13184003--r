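test_that("the saturated two-by-two fit reproduces the cross-product ratio", {
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 190))
  x <- c(rep(1, 100), rep(0, 200))
  fit <- fit_logistic_gee(y, cbind(intercept = 1, exposure = x),
                          cluster = seq_along(y))
  expect_equal(fit$or_table$or[2], 4.75, tolerance = 1e-8)
  # aggregated rows with frequency weights give the same answer
  fit_w <- fit_logistic_gee(c(1, 0, 1, 0), cbind(1, c(1, 1, 0, 0)),
                            cluster = 1:4, weights = c(20, 80, 10, 190))
  expect_equal(fit_w$or_table$or[2], 4.75, tolerance = 1e-8)
})

test_that("singleton clusters reduce the sandwich to the observation-wise robust covariance", {
  set.seed(11)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  X <- cbind(intercept = 1, x = x)
  fit <- fit_logistic_gee(y, X, cluster = seq_len(n))
  # hand-computed HC0: bread from the IRLS weights, meat from raw scores
  g <- glm(y ~ x, family = binomial(),
           control = glm.control(epsilon = 1e-12))
  mu <- fitted(g)
  bread <- solve(crossprod(X * sqrt(mu * (1 - mu))))
  scores <- X * (y - mu)
  hc0 <- bread %*% crossprod(scores) %*% bread
  expect_lt(max(abs(fit$vcov - hc0)), 1e-10)
  # point estimates coincide with plain logistic ML
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-8)
})

test_that("duplicating observations within clusters changes nothing", {
  set.seed(12)
  n <- 300
  cl <- rep(1:60, each = 5)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x))
  X <- cbind(1, x)
  f1 <- fit_logistic_gee(y, X, cl)
  f2 <- fit_logistic_gee(rep(y, 2), rbind(X, X), rep(cl, 2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$vcov, f2$vcov, tolerance = 1e-10)
  # independent route: the clustered meat-and-bread from the sandwich
  # package on a plain glm fit agrees
  g <- glm(y ~ x, family = binomial(),
           control = glm.control(epsilon = 1e-12))
  vc_ref <- sandwich::vcovCL(g, cluster = factor(cl), type = "HC0",
                             cadjust = FALSE)
  expect_equal(unname(f1$vcov), unname(vc_ref), tolerance = 1e-7)
})

test_that("degenerate designs raise errors", {
  y <- c(1, 0, 1, 0)
  expect_error(fit_logistic_gee(y, cbind(1, c(1, 1, 1, 1)), 1:4),
               "rank deficient")
  # complete separation
  xs <- c(rep(1, 30), rep(0, 30))
  expect_error(fit_logistic_gee(xs, cbind(1, xs), seq_along(xs)),
               "separation")
})

test_that("the Wald interval excludes one exactly when |z| > 1.96", {
  set.seed(13)
  for (i in 1:20) {
    n <- 400
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 0.25 * x))
    fit <- fit_logistic_gee(y, cbind(1, exposure = x), seq_len(n))
    row <- fit$or_table[2, ]
    zstat <- abs(row$beta) / row$robust_se
    expect_equal(row$ci_low > 1 || row$ci_high < 1, zstat > qnorm(0.975))
  }
})

test_that("natural spline basis has the right dimension and tail behavior", {
  sb <- natural_spline_basis(1973:2001, df = 5)
  expect_equal(ncol(sb$basis), 5L)
  # any basis combination is linear beyond the boundary knots
  v <- predict_spline_basis(sb, seq(2002, 2012, by = 0.25)) %*% runif(5)
  expect_lt(max(abs(diff(v, differences = 2))), 1e-8)
  # a linear response lies in the span
  x <- 1973:2001
  yl <- 3 * x - 7
  expect_lt(max(abs(fitted(lm(yl ~ sb$basis)) - yl)), 1e-8)
  expect_error(natural_spline_basis(c(1, 2, 3), df = 5), "distinct")
})

test_that("within-individual models respect restrictions and suppression", {
  set.seed(14)
  n <- 5000
  d <- data.table::data.table(
    exposure = rbinom(n, 1, 0.1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_year = sample(1973:2001, n, replace = TRUE),
    cluster = rep(1:(n / 2), each = 2))
  d$outcome <- rbinom(n, 1, plogis(-2 + 1 * d$exposure))
  fit <- within_individual_or(d)
  expect_false(fit$suppressed)
  expect_equal(fit$or_table$term[2], "exposure")
  # female-only: males leave the design and sex drops out
  fit_f <- within_individual_or(d, female_only = TRUE)
  expect_false(any(grepl("female", fit_f$or_table$term)))
  expect_lt(fit_f$n, n)
  # suppression with fewer than five doubly-diagnosed persons
  d2 <- data.table::copy(d)
  d2$outcome[d2$exposure == 1] <- 0
  fit_s <- within_individual_or(d2)
  expect_true(fit_s$suppressed)
})

test_that("familial co-aggregation is symmetric in double-entered orientation", {
  set.seed(15)
  m <- 4000
  pd <- data.table::data.table(
    exposure_a = rbinom(m, 1, 0.15),
    outcome_b = rbinom(m, 1, 0.2),
    sex_a = sample(c("male", "female"), m, TRUE),
    sex_b = sample(c("male", "female"), m, TRUE),
    birth_year_a = sample(1973:2001, m, TRUE),
    birth_year_b = sample(1973:2001, m, TRUE),
    cluster = rep(1:(m / 2), 2))
  swapped <- data.table::data.table(
    exposure_a = pd$exposure_a, outcome_b = pd$outcome_b,
    sex_a = pd$sex_a, sex_b = pd$sex_b,
    birth_year_a = pd$birth_year_a, birth_year_b = pd$birth_year_b,
    cluster = pd$cluster)[rev(seq_len(m))]
  f1 <- familial_coaggregation_or(pd)
  f2 <- familial_coaggregation_or(swapped)
  expect_equal(f1$or_table$or, f2$or_table$or, tolerance = 1e-8)
  expect_equal(sqrt(diag(f1$vcov)), sqrt(diag(f2$vcov)), tolerance = 1e-8)
})

test_that("descriptive tables compute row and column percentages safely", {
  cohort <- data.table::data.table(
    person_id = 1:1000, sex = rep(c("male", "female"), 500),
    birth_year = rep(1973:1992, 50),
    exposure = c(rep(1, 10), rep(0, 990)))
  ph <- list(common = c(rep(1, 200), rep(0, 800)),
             absent = rep(0, 1000))
  d <- descriptive_table(cohort, ph)
  expect_equal(d$n_total[d$label == "N"], 1000L)
  expect_equal(d$pct_exposed[d$label == "N"], 1)
  zero <- d[d$label == "absent", ]
  expect_equal(zero$pct_exposed, 0)
  expect_equal(zero$pct_unexposed, 0)
})
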