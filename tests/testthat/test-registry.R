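test_that("registry files are validated on read", {
  dir <- tiny_registry_dir()
  reg <- read_registry(dir)
  expect_s3_class(reg$persons$birth_date, "Date")
  expect_equal(nrow(reg$persons), 9L)

  # diagnosis pointing at an unknown person
  bad <- tiny_registry_dir(extra_diagnoses = data.table::data.table(
    person_id = 999L, icd_revision = 10L, code = "F32",
    date = as.Date("2000-01-01"), source = "inpatient"))
  expect_error(read_registry(bad), "unknown person_id 999")

  # malformed date
  dir3 <- tiny_registry_dir()
  dx <- data.table::fread(file.path(dir3, "diagnoses.tsv"),
                          colClasses = "character")
  dx$date[1] <- "1987-13-01"
  data.table::fwrite(dx, file.path(dir3, "diagnoses.tsv"), sep = "\t")
  expect_error(read_registry(dir3), "date '1987-13-01'")

  # missing column
  dir4 <- tiny_registry_dir()
  pp <- data.table::fread(file.path(dir4, "persons.tsv"))
  pp$sex <- NULL
  data.table::fwrite(pp, file.path(dir4, "persons.tsv"), sep = "\t")
  expect_error(read_registry(dir4), "missing column.*sex")
})

test_that("a person cannot be its own ancestor", {
  dir <- tiny_registry_dir()
  par <- data.table::fread(file.path(dir, "parents.tsv"))
  par <- rbind(par, data.table::data.table(person_id = 1L, mother_id = 3L,
                                           father_id = NA_integer_))
  data.table::fwrite(par, file.path(dir, "parents.tsv"), sep = "\t", na = "")
  expect_error(read_registry(dir), "own ancestor")
})

test_that("cohort exclusions follow the birth-window, mother, malformation and age rules", {
  persons <- data.table::data.table(
    person_id = 1:6,
    sex = "female",
    birth_date = as.Date(c("1980-01-01", "1980-01-01", "1980-01-01",
                           "1972-12-31", "1980-01-01", "1980-01-01")),
    death_date = as.Date(c(NA, "1997-11-30", NA, NA, NA, NA)),
    immigration_date = as.Date(NA),
    emigration_date = as.Date(c(NA, NA, "2000-06-01", NA, NA, NA)),
    malformation_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  parents <- data.table::data.table(person_id = 1:5, mother_id = 10L,
                                    father_id = 11L)
  extra <- data.table::data.table(
    person_id = 10:11, sex = c("female", "male"),
    birth_date = as.Date("1950-01-01"), death_date = as.Date(NA),
    immigration_date = as.Date(NA), emigration_date = as.Date(NA),
    malformation_flag = FALSE)
  reg <- list(persons = rbind(persons, extra), parents = parents)
  cohort <- apply_cohort_exclusions(reg)
  # kept: 1 (clean); excluded: 2 (died at 17.9), 3 retained (emigrated at
  # 20), 4 (born before window), 5 (malformation), 6 (no known mother)
  expect_setequal(cohort$person_id, c(1L, 3L))
  ex <- attr(cohort, "exclusions")
  expect_equal(unname(ex["died_before_18"]), 1L)
  expect_equal(unname(ex["malformation"]), 1L)
})

test_that("lifetime ascertainment respects code eras and sources", {
  dir <- tiny_registry_dir(extra_diagnoses = data.table::data.table(
    person_id = c(9L, 9L),
    icd_revision = c(10L, 10L),
    code = c("X60", "X60"),
    date = as.Date(c("2010-01-01", "2015-01-01")),
    source = c("inpatient", "cause_of_death")))
  reg <- read_registry(dir)
  bpd <- phenotype_definition("bpd", "psychiatric",
                              icd9 = c("301D", "301J"), icd10 = "F60.3")
  a <- ascertain_phenotype(reg$persons, bpd, reg$diagnoses)
  # person 3: F60.3 in 1999 (ICD-10 era); person 4: 301D in 1995 (ICD-9)
  expect_equal(a$indicator[match(3:4, a$person_id)], c(1L, 1L))
  expect_equal(a$indicator[match(8L, a$person_id)], 0L)

  suicide <- phenotype_definition("suicide", "behavioral", icd10 = "X6",
                                  cause_of_death_source = TRUE)
  s <- ascertain_phenotype(reg$persons, suicide, reg$diagnoses)
  # only the cause-of-death row counts, not the inpatient X60
  expect_equal(s$first_date[match(9L, s$person_id)], as.Date("2015-01-01"))
  inp_only <- phenotype_definition("selfharm", "behavioral", icd10 = "X6")
  i <- ascertain_phenotype(reg$persons, inp_only, reg$diagnoses)
  expect_equal(i$first_date[match(9L, i$person_id)], as.Date("2010-01-01"))

  fo <- phenotype_definition("pcos", "somatic", icd10 = "E28.2",
                             female_only = TRUE)
  f <- ascertain_phenotype(reg$persons, fo, reg$diagnoses)
  expect_true(all(is.na(f$indicator[reg$persons$sex == "male"])))
  expect_true(all(!is.na(f$indicator[reg$persons$sex == "female"])))
})

test_that("follow-up windows honor the first-of and last-of rules", {
  persons <- data.table::data.table(
    person_id = 1:3, sex = "male",
    birth_date = as.Date(c("1980-06-01", "1990-01-01", "1990-01-01")),
    death_date = as.Date(NA), immigration_date = as.Date(NA),
    emigration_date = as.Date(c(NA, NA, "2004-05-01")),
    malformation_flag = FALSE)
  fd <- data.table::data.table(
    person_id = 1:3,
    first_date = as.Date(c(NA, "2005-03-02", "2005-03-02")))
  fu <- compute_follow_up(persons, fd)
  expect_equal(fu$start, as.Date(c("1987-01-01", "1990-01-01",
                                   "1990-01-01")))
  expect_equal(fu$end, as.Date(c("2020-12-31", "2005-03-02",
                                 "2004-05-01")))
  expect_equal(fu$event, c(0L, 1L, 0L))
  # degenerate window: emigration before the registry start
  p2 <- persons[1]
  p2$emigration_date <- as.Date("1986-01-01")
  fu2 <- compute_follow_up(p2, data.table::data.table(
    person_id = 1L, first_date = as.Date(NA)))
  expect_true(fu2$degenerate)
  expect_true(is.na(fu2$event))
})

test_that("relative pairs are classified and double-entered correctly", {
  dir <- tiny_registry_dir()
  reg <- read_registry(dir)
  cohort <- data.table::data.table(person_id = c(3L, 4L, 8L, 9L))
  pairs <- enumerate_relative_pairs(reg, cohort)
  within <- pairs[pairs$generation == "within", ]
  expect_equal(sort(unique(within$kinship)),
               c("full_sib", "paternal_half_sib"))
  # double entry: each unique pair appears in both orientations
  fs <- within[within$kinship == "full_sib", ]
  expect_equal(nrow(fs), 2L)
  expect_setequal(fs$id_a, c(3L, 4L))
  ph <- within[within$kinship == "paternal_half_sib", ]
  expect_equal(nrow(ph), 2L)
  expect_equal(unique(ph$alpha), 0.25)
  expect_equal(unique(ph$gamma), 0)
  # between generation: parents born in the 1950s qualify, emitted once,
  # older relative on the exposure side
  pc <- pairs[pairs$kinship == "parent_child", ]
  expect_true(all(pc$id_a %in% c(1L, 2L, 5L, 6L, 7L)))
  expect_true(all(pc$id_b %in% cohort$person_id))
  # a parent born before 1933 drops the pair
  pairs2 <- enumerate_relative_pairs(
    reg, cohort, relative_birth_floor = as.Date("1960-01-01"))
  pc2 <- pairs2[pairs2$kinship == "parent_child", ]
  expect_true(all(pc2$id_a == 7L))
})

test_that("twins with unknown zygosity stay full siblings but leave the twin sets", {
  dir <- tiny_registry_dir()
  zy <- data.table::data.table(person_id = c(3L, 4L), twin_pair_id = 1L,
                               zygosity = "UN")
  data.table::fwrite(zy, file.path(dir, "zygosity.tsv"), sep = "\t")
  reg <- read_registry(dir)
  pairs <- enumerate_relative_pairs(
    reg, data.table::data.table(person_id = c(3L, 4L)))
  expect_false(any(pairs$kinship %in% c("MZ_twin", "DZ_twin")))
  expect_equal(sum(pairs$kinship == "full_sib"), 2L)
  # known zygosity reclassifies
  data.table::fwrite(data.table::data.table(person_id = c(3L, 4L),
                                            twin_pair_id = 1L,
                                            zygosity = "MZ"),
                     file.path(dir, "zygosity.tsv"), sep = "\t")
  reg2 <- read_registry(dir)
  pairs2 <- enumerate_relative_pairs(
    reg2, data.table::data.table(person_id = c(3L, 4L)))
  expect_equal(sum(pairs2$kinship == "MZ_twin"), 2L)
  expect_equal(sum(pairs2$kinship == "full_sib"), 0L)
})

test_that("kinship classification matches the generating family structure", {
  cfg <- simulation_config(n_families = 400, seed = 21)
  reg <- simulate_registry(cfg)
  kids <- reg$persons[reg$persons$role == "child", ]
  pairs <- enumerate_relative_pairs(
    list(persons = reg$persons, parents = reg$parents,
         zygosity = reg$zygosity),
    data.table::data.table(person_id = kids$person_id))
  within <- pairs[pairs$generation == "within", ]
  within <- within[within$id_a < within$id_b, ]
  # map each within-generation pair back to its family's structural type
  fam <- kids$family_id[match(within$id_a, kids$person_id)]
  same_family <- fam == kids$family_id[match(within$id_b, kids$person_id)]
  expect_true(all(within$kinship[!same_family] == "cousin"))
  counts <- table(reg$persons$family_id[match(kids$person_id,
                                              reg$persons$person_id)])
  expect_true(all(counts == 2))
})

test_that("one sibling pair per kinship type per cluster, chosen by age gap then seniority", {
  persons <- data.table::data.table(
    person_id = 1:7, sex = "female",
    birth_date = as.Date(c("1980-01-01", "1983-01-01", "1984-01-01",
                           "1980-01-01", "1980-01-11", "1980-01-21",
                           "1990-01-01")))
  mk_pairs <- function(ids) {
    cmb <- t(combn(ids, 2))
    data.table::data.table(id_a = cmb[, 1], id_b = cmb[, 2],
                           kinship = "full_sib")
  }
  # cluster one: births 1980, 1983, 1984 -> closest gap is (1983, 1984)
  sel1 <- select_unique_sibling_pairs(mk_pairs(1:3), persons)
  expect_equal(sort(c(sel1$id_a, sel1$id_b)), c(2L, 3L))
  # equal ten-day gaps -> tie broken toward the pair with the oldest member
  sel2 <- select_unique_sibling_pairs(mk_pairs(4:6), persons)
  expect_equal(sort(c(sel2$id_a, sel2$id_b)), c(4L, 5L))
  # a singleton child yields no pair
  sel3 <- select_unique_sibling_pairs(
    data.table::data.table(id_a = integer(), id_b = integer(),
                           kinship = character()), persons)
  expect_equal(nrow(sel3), 0L)
  # deterministic under a fixed seed
  both <- data.table::rbindlist(list(mk_pairs(1:3), mk_pairs(4:6)))
  s1 <- select_unique_sibling_pairs(both, persons, seed = 42)
  s2 <- select_unique_sibling_pairs(both, persons, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2L)  # one pair per cluster
})
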