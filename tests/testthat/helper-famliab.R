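# shared fixtures: tiny hand-built registry tables and default parameters

default_biv_params <- function()
  biv_ace_params(ace_params(0.5, 0.05), ace_params(0.5, 0.05),
                 rA = 0.74, rC = 0.5, rE = 0.25)

# a minimal two-family registry written as TSVs: one full-sib family
# (parents 1,2; children 3,4) and one paternal-half-sib family
# (father 5; mothers 6,7; children 8,9), plus a handful of diagnoses
tiny_registry_dir <- function(extra_diagnoses = NULL) {
  dir <- tempfile("tinyreg")
  persons <- data.table::data.table(
    person_id = 1:9,
    sex = c("male", "female", "female", "male", "male", "female", "female",
            "female", "male"),
    birth_date = as.Date(c("1950-01-01", "1952-05-20", "1980-06-01",
                           "1983-03-15", "1951-07-07", "1955-02-02",
                           "1960-10-10", "1985-01-01", "1990-12-31")),
    death_date = as.Date(NA),
    immigration_date = as.Date(NA),
    emigration_date = as.Date(NA),
    malformation_flag = FALSE)
  parents <- data.table::data.table(
    person_id = c(3L, 4L, 8L, 9L),
    mother_id = c(2L, 2L, 6L, 7L),
    father_id = c(1L, 1L, 5L, 5L))
  zygosity <- data.table::data.table(person_id = integer(),
                                     twin_pair_id = integer(),
                                     zygosity = character())
  diagnoses <- data.table::data.table(
    person_id = c(3L, 4L, 8L),
    icd_revision = c(10L, 9L, 10L),
    code = c("F60.3", "301D", "F32.1"),
    date = as.Date(c("1999-05-01", "1995-03-02", "2005-03-02")),
    source = c("outpatient", "inpatient", "outpatient"))
  if (!is.null(extra_diagnoses))
    diagnoses <- data.table::rbindlist(list(diagnoses, extra_diagnoses),
                                       use.names = TRUE)
  write_registry(list(persons = persons, parents = parents,
                      zygosity = zygosity, diagnoses = diagnoses), dir)
  dir
}

# binary sibling-pair data for the three SEM kinship groups under a known
# generating model, with constant thresholds from the target prevalence
sem_pair_data <- function(params, n_pairs, prevalence, seed) {
  kns <- c("full_sib", "maternal_half_sib", "paternal_half_sib")
  tau <- threshold_for_prevalence(prevalence)
  rows <- lapply(seq_along(kns), function(i) {
    s <- simulate_sibling_pairs(kns[i], n_pairs, params,
                                seed = seed + i, prevalence = prevalence)
    data.table::data.table(kinship = kns[i],
                           y1_a = s$y_a[, 1], y2_a = s$y_a[, 2],
                           y1_b = s$y_b[, 1], y2_b = s$y_b[, 2],
                           tau1_a = tau[1], tau2_a = tau[2],
                           tau1_b = tau[1], tau2_b = tau[2])
  })
  data.table::rbindlist(rows)
}
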