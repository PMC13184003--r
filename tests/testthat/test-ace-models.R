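test_that("univariate WLS solves the sibling moment equations exactly", {
  kns <- c("full_sib", "maternal_half_sib", "paternal_half_sib")
  fit <- fit_univariate_ace(c(0.30, 0.175, 0.125), kinship = kns)
  expect_equal(fit$a2, 0.5, tolerance = 1e-10)
  expect_equal(fit$c2, 0.05, tolerance = 1e-10)
  expect_equal(fit$e2, 0.45, tolerance = 1e-10)
  expect_lt(fit$objective, 1e-20)

  null <- fit_univariate_ace(c(0, 0, 0), kinship = kns)
  expect_equal(c(null$a2, null$c2, null$e2), c(0, 0, 1), tolerance = 1e-12)

  # equal weights: matches the normal-equation solution computed directly
  r <- c(0.31, 0.16, 0.12)
  X <- cbind(c(0.5, 0.25, 0.25), c(1, 1, 0))
  beta <- solve(t(X) %*% X, t(X) %*% r)
  fit2 <- fit_univariate_ace(r, kinship = kns)
  expect_lt(max(abs(c(fit2$a2, fit2$c2) - beta)), 1e-10)

  expect_error(fit_univariate_ace(c(0.3, 0.2),
                                  alpha = c(0.5, 0.5), gamma = c(1, 1)),
               "identifiable")
})

test_that("the univariate fit is unconstrained while the bivariate loadings are not", {
  # correlations implying negative c2 are fitted as such
  kns <- c("full_sib", "maternal_half_sib", "paternal_half_sib")
  fit <- fit_univariate_ace(c(0.25, 0.10, 0.15), kinship = kns)
  expect_lt(fit$c2, 0)
  # bivariate loadings stay in bounds by construction
  p <- biv_ace_params(ace_params(0.4, 0.1), ace_params(0.3, 0.2),
                      rA = 0.6, rC = -0.3, rE = 0.2)
  bf <- fit_bivariate_ace(implied_pair_structure(p))
  th <- bf$theta[c("a1", "c1", "a2", "c2")]
  expect_true(all(th >= 0 & th <= 1))
})

test_that("noiseless structures are inverted to the generating parameters", {
  set.seed(31)
  for (i in 1:12) {
    a2s <- runif(2, 0.1, 0.7)
    c2s <- runif(2, 0.05, 0.3)
    rs <- runif(3, -0.9, 0.9)
    p <- biv_ace_params(ace_params(a2s[1], c2s[1]),
                        ace_params(a2s[2], c2s[2]),
                        rA = rs[1], rC = rs[2], rE = rs[3])
    fit <- fit_bivariate_ace(implied_pair_structure(p))
    expect_true(fit$converged)
    truth <- c(sqrt(a2s[1]), sqrt(c2s[1]), sqrt(a2s[2]), sqrt(c2s[2]), rs)
    expect_lt(max(abs(fit$theta[c("a1", "c1", "a2", "c2", "rA", "rC",
                                  "rE")] - truth)), 1e-6)
  }
})

test_that("fixing C to zero reproduces a C-free truth with fewer parameters", {
  p <- biv_ace_params(ace_params(0.6, 0), ace_params(0.4, 0),
                      rA = 0.5, rC = 0, rE = 0.3)
  st <- implied_pair_structure(p)
  free <- fit_bivariate_ace(st)
  fixed <- fit_bivariate_ace(st, fix_c = TRUE)
  expect_true(fixed$fixed_c)
  expect_equal(length(fixed$free), 4L)
  expect_equal(unname(fixed$theta[c("a1", "a2", "rA", "rE")]),
               c(sqrt(0.6), sqrt(0.4), 0.5, 0.3), tolerance = 1e-6)
  expect_equal(unname(free$theta[c("a1", "a2", "rA", "rE")]),
               unname(fixed$theta[c("a1", "a2", "rA", "rE")]),
               tolerance = 1e-4)
})

test_that("the phenotypic-correlation decomposition sums to one and allows negatives", {
  p <- biv_ace_params(ace_params(0.5, 0.1), ace_params(0.5, 0.1),
                      rA = 0.8, rC = 0.5, rE = 0.25)
  fit <- fit_bivariate_ace(implied_pair_structure(p))
  dec <- decompose_phenotypic_correlation(fit)
  expect_equal(unname(dec),
               c(0.40, 0.05, 0.10) / 0.55, tolerance = 1e-5)
  expect_equal(sum(dec), 1, tolerance = 1e-8)

  # a negative rC pathway with small positive r_ph gives bivC < 0
  pneg <- biv_ace_params(ace_params(0.5, 0.2), ace_params(0.5, 0.2),
                         rA = 0.35, rC = -0.6, rE = 0.1)
  expect_gt(phenotypic_correlation(pneg), 0)
  fneg <- fit_bivariate_ace(implied_pair_structure(pneg))
  dneg <- decompose_phenotypic_correlation(fneg)
  expect_lt(dneg[["bivC"]], 0)
  expect_equal(sum(dneg), 1, tolerance = 1e-8)

  # a pure-A overlap puts everything on bivA
  pa <- biv_ace_params(ace_params(0.5, 0.1), ace_params(0.5, 0.1),
                       rA = 0.8, rC = 0, rE = 0)
  fa <- fit_bivariate_ace(implied_pair_structure(pa))
  expect_equal(decompose_phenotypic_correlation(fa)[["bivA"]], 1,
               tolerance = 1e-6)
})

test_that("increasing rA raises the implied cross-relative cross-trait correlation", {
  mk <- function(rA) biv_ace_params(ace_params(0.5, 0.1),
                                    ace_params(0.4, 0.2),
                                    rA = rA, rC = 0.3, rE = 0.1)
  for (kn in c("MZ_twin", "full_sib", "maternal_half_sib",
               "paternal_half_sib", "cousin")) {
    vals <- vapply(c(0.2, 0.5, 0.8), function(r)
      expected_cross_trait_correlation(mk(r), kn), 0)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("delta-method CI widths scale with the injected moment noise", {
  p <- biv_ace_params(ace_params(0.5, 0.1), ace_params(0.5, 0.1),
                      rA = 0.8, rC = 0.5, rE = 0.25)
  st1 <- implied_pair_structure(p, var = 1e-4)
  st2 <- implied_pair_structure(p, var = 4e-4)
  w1 <- fit_bivariate_ace(st1)$derived
  w2 <- fit_bivariate_ace(st2)$derived
  ratio <- (w2$ci_high - w2$ci_low) / (w1$ci_high - w1$ci_low)
  expect_equal(unname(ratio[is.finite(ratio)]),
               rep(2, sum(is.finite(ratio))), tolerance = 1e-2)
})

test_that("rA is recovered from simulated binary sibling pairs", {
  p <- default_biv_params()  # rA = 0.74, a2 = 0.5, c2 = 0.05
  pd <- sem_pair_data(p, n_pairs = 20000, prevalence = c(0.2, 0.2),
                      seed = 321)
  st <- pair_polychoric_structure(pd)
  fit <- fit_bivariate_ace(st)
  expect_true(fit$converged)
  d <- fit$derived
  rA <- d[d$quantity == "rA", ]
  expect_lt(abs(rA$estimate - 0.74), 3 * rA$se)
  expect_equal(sum(decompose_phenotypic_correlation(fit)), 1,
               tolerance = 1e-8)
})

test_that("screening applies the correlation and pair-count rules inclusively", {
  expect_false(screen_phenotypes(0.09, 100, 100)$include)
  expect_equal(screen_phenotypes(0.09, 100, 100)$reasons,
               "within_individual_correlation_below_threshold")
  expect_false(screen_phenotypes(0.25, 4, 100)$include)
  expect_false(screen_phenotypes(0.25, 100, 4)$include)
  expect_true(screen_phenotypes(0.10, 5, 5)$include)
})
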