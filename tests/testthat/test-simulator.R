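test_that("family structures are generated as declared", {
  mk <- function(type) {
    mix <- setNames(rep(0, 6), c("full_sib", "maternal_half_sib",
                                 "paternal_half_sib", "mz_twin", "dz_twin",
                                 "cousin"))
    mix[type] <- 1
    simulate_pedigrees(simulation_config(n_families = 1, family_mix = mix,
                                         seed = 7))
  }
  ped <- mk("full_sib")
  kids <- ped$persons[ped$persons$role == "child", ]
  links <- ped$parents[match(kids$person_id, ped$parents$person_id), ]
  expect_equal(nrow(kids), 2L)
  expect_equal(links$mother_id[1], links$mother_id[2])
  expect_equal(links$father_id[1], links$father_id[2])

  ped <- mk("maternal_half_sib")
  kids <- ped$persons[ped$persons$role == "child", ]
  links <- ped$parents[match(kids$person_id, ped$parents$person_id), ]
  expect_equal(links$mother_id[1], links$mother_id[2])
  expect_false(links$father_id[1] == links$father_id[2])

  ped <- mk("mz_twin")
  expect_equal(nrow(ped$zygosity), 2L)
  expect_equal(unique(ped$zygosity$zygosity), "MZ")
  kids <- ped$persons[ped$persons$role == "child", ]
  expect_equal(kids$birth_date[1], kids$birth_date[2])
  expect_equal(kids$sex[1], kids$sex[2])
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(family_mix = c(full_sib = 0.5)),
               "sum to 1")
  expect_error(simulation_config(prevalence = c(0, 0.1)), "strictly")
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_families = 1000, seed = 123)
  a <- simulate_registry(cfg)
  b <- simulate_registry(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$parents, b$parents)
  expect_identical(a$diagnoses, b$diagnoses)
})

test_that("MZ co-twins get identical liabilities under pure additive variance", {
  p <- biv_ace_params(ace_params(1, 0), ace_params(1, 0),
                      rA = 0.5, rC = 0, rE = 0)
  s <- simulate_sibling_pairs("MZ_twin", 200, p, seed = 3)
  expect_equal(unname(s$liab_a), unname(s$liab_b), tolerance = 1e-12)
})

test_that("sibling liability correlations match alpha*a2 + gamma*c2", {
  p <- biv_ace_params(ace_params(0.5, 0.2, 0.3), ace_params(0.4, 0.1, 0.5),
                      rA = 0.8, rC = 0.5, rE = 0.25)
  n <- 50000
  mc3 <- 3 / sqrt(n)
  for (kn in c("full_sib", "maternal_half_sib", "paternal_half_sib",
               "cousin")) {
    s <- simulate_sibling_pairs(kn, n, p, seed = 42)
    expect_lt(abs(cor(s$liab_a[, 1], s$liab_b[, 1]) -
                    expected_pair_correlation(0.5, 0.2, kn)), mc3)
    expect_lt(abs(cor(s$liab_a[, 2], s$liab_b[, 2]) -
                    expected_pair_correlation(0.4, 0.1, kn)), mc3)
    rx <- (cor(s$liab_a[, 1], s$liab_b[, 2]) +
             cor(s$liab_a[, 2], s$liab_b[, 1])) / 2
    expect_lt(abs(rx - expected_cross_trait_correlation(p, kn)), mc3)
  }
})

test_that("marginal liability variance is one and independent traits stay uncorrelated", {
  p0 <- biv_ace_params(ace_params(0.5, 0.2), ace_params(0.4, 0.1),
                       rA = 0, rC = 0, rE = 0)
  s <- simulate_sibling_pairs("full_sib", 30000, p0, seed = 8)
  L <- rbind(s$liab_a, s$liab_b)
  expect_lt(abs(var(L[, 1]) - 1), 3 * sqrt(2 / nrow(L)))
  expect_lt(abs(var(L[, 2]) - 1), 3 * sqrt(2 / nrow(L)))
  expect_lt(abs(cor(L[, 1], L[, 2])), 3 / sqrt(nrow(L)))
})

test_that("liability thresholds invert the target prevalence", {
  expect_equal(threshold_for_prevalence(0.5), 0)
  expect_equal(threshold_for_prevalence(0.009), 2.3656, tolerance = 5e-4)
  expect_equal(threshold_for_prevalence(0.159), 1.0, tolerance = 5e-3)
  expect_error(threshold_for_prevalence(0), "strictly")
  expect_error(threshold_for_prevalence(1.2), "strictly")
})

test_that("observed prevalence hits the target without covariate effects", {
  cfg <- simulation_config(n_families = 25000, prevalence = c(0.05, 0.1),
                           sex_shift = c(0, 0), death_rate = 0,
                           emigration_rate = 0, malformation_rate = 0,
                           seed = 5)
  reg <- simulate_registry(cfg)
  dx1 <- unique(reg$diagnoses[reg$diagnoses$code %in%
                                c("301D", "301J", "F60.3"), ]$person_id)
  n <- nrow(reg$persons)
  prev <- length(dx1) / n
  expect_lt(abs(prev - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("a negative female threshold shift raises female prevalence", {
  cfg <- simulation_config(n_families = 20000, prevalence = c(0.02, 0.1),
                           sex_shift = c(-0.5, 0), death_rate = 0,
                           emigration_rate = 0, seed = 6)
  reg <- simulate_registry(cfg)
  dx1 <- unique(reg$diagnoses[reg$diagnoses$code %in%
                                c("301D", "301J", "F60.3"), ]$person_id)
  p <- reg$persons
  prev_f <- mean(p$person_id[p$sex == "female"] %in% dx1)
  prev_m <- mean(p$person_id[p$sex == "male"] %in% dx1)
  expect_gt(prev_f, prev_m)
  # and the base threshold is recalibrated so the marginal still holds
  expect_lt(abs(mean(p$person_id %in% dx1) - 0.02),
            3 * sqrt(0.02 * 0.98 / nrow(p)))
})

test_that("registry tables round-trip through disk losslessly", {
  cfg <- simulation_config(n_families = 300, seed = 9)
  reg <- simulate_registry(cfg)
  dir <- tempfile("regrt")
  write_registry(reg, dir)
  back <- read_registry(dir)
  expect_equal(nrow(back$persons), nrow(reg$persons))
  expect_equal(back$persons$birth_date,
               reg$persons$birth_date[match(back$persons$person_id,
                                            reg$persons$person_id)])
  expect_equal(data.table::setorder(back$diagnoses, person_id, date, code),
               data.table::setorder(
                 reg$diagnoses[, names(back$diagnoses), with = FALSE],
                 person_id, date, code))
  # empty diagnosis table still writes a valid header-only file
  empty <- reg
  empty$diagnoses <- reg$diagnoses[0]
  dir2 <- tempfile("regrt2")
  write_registry(empty, dir2)
  expect_equal(nrow(read_registry(dir2)$diagnoses), 0L)
})

test_that("liabilities under a liability-degenerate model produce no events below threshold", {
  cfg <- simulation_config(n_families = 2000, seed = 10)
  ped <- simulate_pedigrees(cfg)
  liab <- simulate_liabilities(ped, cfg$params, seed = 99)
  reg <- liabilities_to_registry(liab, ped, cfg)
  tau1 <- threshold_for_prevalence(cfg$prevalence[1]) +
    cfg$sex_shift[1] * (ped$persons$sex == "female")
  # recalibrated base threshold shifts marginally; below-threshold persons
  # at the *lowest* per-person threshold minus a margin must have no events
  low <- liab[, 1] < min(tau1) - 0.5
  dx1 <- unique(reg$diagnoses[reg$diagnoses$code %in%
                                c("301D", "301J", "F60.3"), ]$person_id)
  expect_false(any(ped$persons$person_id[low] %in% dx1))
})
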