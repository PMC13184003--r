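# Synthetic multigenerational registry generator.
#
# Families are generated by structural type (full-sib, maternal/paternal
# half-sib, MZ/DZ twin, cousin), liabilities by gene dropping a bivariate
# additive-genetic vector through the pedigree, adding a household-shared
# common-environment vector and a person-specific unique-environment vector.
# Binary lifetime diagnoses arise from a liability-threshold link with
# probit-scale sex and birth-year shifts; censoring by death/emigration.

.stage_offsets <- c(pedigree = 101L, liabilities = 211L, registry = 307L)

#' Simulation configuration for the synthetic registry
#'
#' @param n_families Number of independent families.
#' @param family_mix Named proportions over family structural types
#'   (`full_sib`, `maternal_half_sib`, `paternal_half_sib`, `mz_twin`,
#'   `dz_twin`, `cousin`); must sum to 1.
#' @param params A [biv_ace_params] object: the generating ACE structure.
#' @param prevalence Length-2 vector of lifetime prevalence targets in (0,1)
#'   for the two traits (defaults 0.009 and 0.089, a rare exposure disorder
#'   and a common outcome disorder).
#' @param sex_shift Length-2 probit-scale shift added to the diagnosis
#'   threshold of females (negative values raise female prevalence).
#' @param birth_year_coef Length-2 per-year probit drift of the threshold,
#'   centred on the middle of `birth_year_range`.
#' @param birth_year_range Two integers; children are born uniformly within.
#' @param death_rate,emigration_rate Constant yearly hazards of death and of
#'   first emigration.
#' @param malformation_rate Probability that a child carries the congenital
#'   malformation flag (excluded from the cohort downstream).
#' @param trait_codes List of two lists with elements `name`, `icd9`,
#'   `icd10`: the code sets used to emit diagnosis rows.
#' @param seed Integer seed; fixes all randomness. Each simulation stage
#'   draws from its own stream seeded by `seed` plus a fixed stage offset.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_families = 5000,
                              family_mix = c(full_sib = 0.62,
                                             maternal_half_sib = 0.10,
                                             paternal_half_sib = 0.10,
                                             mz_twin = 0.01,
                                             dz_twin = 0.02,
                                             cousin = 0.15),
                              params = biv_ace_params(
                                ace_params(0.5, 0.05),
                                ace_params(0.5, 0.05),
                                rA = 0.74, rC = 0.5, rE = 0.25),
                              prevalence = c(0.009, 0.089),
                              sex_shift = c(-0.6, -0.2),
                              birth_year_coef = c(0, 0),
                              birth_year_range = c(1973L, 2001L),
                              death_rate = 3e-4,
                              emigration_rate = 2e-3,
                              malformation_rate = 0.01,
                              trait_codes = list(
                                list(name = "bpd",
                                     icd9 = c("301D", "301J"),
                                     icd10 = "F60.3"),
                                list(name = "depression",
                                     icd9 = "311",
                                     icd10 = c("F32", "F33"))),
                              seed = 1L) {
  types <- c("full_sib", "maternal_half_sib", "paternal_half_sib",
             "mz_twin", "dz_twin", "cousin")
  if (is.null(names(family_mix)) || !all(names(family_mix) %in% types))
    stop("family_mix must be named with known family types")
  if (abs(sum(family_mix) - 1) > 1e-8)
    stop("family_mix proportions must sum to 1")
  if (any(family_mix < 0)) stop("family_mix proportions must be >= 0")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence targets must lie strictly in (0, 1)")
  stopifnot(inherits(params, "biv_ace_params"),
            length(prevalence) == 2L, length(sex_shift) == 2L,
            length(birth_year_coef) == 2L, length(trait_codes) == 2L,
            n_families >= 1)
  mix <- setNames(numeric(length(types)), types)
  mix[names(family_mix)] <- family_mix
  structure(list(n_families = as.integer(n_families), family_mix = mix,
                 params = params, prevalence = prevalence,
                 sex_shift = sex_shift, birth_year_coef = birth_year_coef,
                 birth_year_range = as.integer(birth_year_range),
                 death_rate = death_rate, emigration_rate = emigration_rate,
                 malformation_rate = malformation_rate,
                 trait_codes = trait_codes, seed = as.integer(seed)),
            class = "sim_config")
}

.runif_date <- function(n, year_lo, year_hi) {
  lo <- as.integer(as.Date(paste0(year_lo, "-01-01")))
  hi <- as.integer(as.Date(paste0(year_hi, "-12-31")))
  as.Date(lo + floor(runif(n) * (hi - lo + 1)), origin = "1970-01-01")
}

.rsex <- function(n) c("male", "female")[1L + (runif(n) < 0.5)]

#' Generate a synthetic multigenerational pedigree
#'
#' Builds persons, parent-link and twin-zygosity tables for `n_families`
#' independent families drawn from the configured structural mix. Every
#' child has exactly one mother and one father; half-sibships arise by
#' re-partnering; cousin families span three generations. Parents are born
#' 20-40 years before their oldest child, outside the cohort birth window.
#'
#' @param config A [simulation_config()] object.
#' @return List with `data.table`s `persons` (with internal bookkeeping
#'   columns `family_id` and `role`), `parents`, `zygosity`.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .stage_offsets[["pedigree"]])
  counts <- as.vector(stats::rmultinom(1, config$n_families,
                                       config$family_mix))
  names(counts) <- names(config$family_mix)
  yl <- config$birth_year_range[1]; yh <- config$birth_year_range[2]
  persons <- list(); parents <- list(); zyg <- list()
  next_id <- 0L; next_fam <- 0L; next_twin <- 0L

  new_ids <- function(n) { ids <- next_id + seq_len(n); next_id <<- next_id + n; ids }

  add_block <- function(type, m) {
    if (m == 0L) return(invisible(NULL))
    fam <- next_fam + seq_len(m); next_fam <<- next_fam + m
    child_bd1 <- .runif_date(m, yl, yh)
    child_bd2 <- .runif_date(m, yl, yh)
    parent_bd <- function(child_bd)
      child_bd - round(365.25 * runif(length(child_bd), 20, 40))
    mk <- function(id, fam_id, sex, bd, role)
      data.table::data.table(person_id = id, family_id = fam_id, sex = sex,
                             birth_date = bd, role = role)
    if (type %in% c("full_sib", "mz_twin", "dz_twin")) {
      if (type != "full_sib") child_bd2 <- child_bd1
      fa <- new_ids(m); mo <- new_ids(m); c1 <- new_ids(m); c2 <- new_ids(m)
      sex1 <- .rsex(m)
      sex2 <- if (type == "mz_twin") sex1 else .rsex(m)
      eldest <- pmin(child_bd1, child_bd2)
      persons[[length(persons) + 1L]] <<- data.table::rbindlist(list(
        mk(fa, fam, "male", parent_bd(eldest), "parent"),
        mk(mo, fam, "female", parent_bd(eldest), "parent"),
        mk(c1, fam, sex1, child_bd1, "child"),
        mk(c2, fam, sex2, child_bd2, "child")))
      parents[[length(parents) + 1L]] <<- data.table::data.table(
        person_id = c(c1, c2), mother_id = c(mo, mo), father_id = c(fa, fa))
      if (type != "full_sib") {
        tp <- next_twin + seq_len(m); next_twin <<- next_twin + m
        zyg[[length(zyg) + 1L]] <<- data.table::data.table(
          person_id = c(c1, c2), twin_pair_id = c(tp, tp),
          zygosity = if (type == "mz_twin") "MZ" else "DZ")
      }
    } else if (type %in% c("maternal_half_sib", "paternal_half_sib")) {
      shared <- new_ids(m); o1 <- new_ids(m); o2 <- new_ids(m)
      c1 <- new_ids(m); c2 <- new_ids(m)
      eldest <- pmin(child_bd1, child_bd2)
      if (type == "maternal_half_sib") {
        ssex <- "female"; osex <- "male"
        mo1 <- shared; fa1 <- o1; mo2 <- shared; fa2 <- o2
      } else {
        ssex <- "male"; osex <- "female"
        mo1 <- o1; fa1 <- shared; mo2 <- o2; fa2 <- shared
      }
      persons[[length(persons) + 1L]] <<- data.table::rbindlist(list(
        mk(shared, fam, ssex, parent_bd(eldest), "parent"),
        mk(o1, fam, osex, parent_bd(child_bd1), "parent"),
        mk(o2, fam, osex, parent_bd(child_bd2), "parent"),
        mk(c1, fam, .rsex(m), child_bd1, "child"),
        mk(c2, fam, .rsex(m), child_bd2, "child")))
      parents[[length(parents) + 1L]] <<- data.table::data.table(
        person_id = c(c1, c2), mother_id = c(mo1, mo2),
        father_id = c(fa1, fa2))
    } else if (type == "cousin") {
      # grandparents -> two sister mothers -> one child each
      gf <- new_ids(m); gm <- new_ids(m)
      p1 <- new_ids(m); p2 <- new_ids(m)  # sisters, mothers of the cousins
      s1 <- new_ids(m); s2 <- new_ids(m)  # unrelated spouses
      c1 <- new_ids(m); c2 <- new_ids(m)
      eldest <- pmin(child_bd1, child_bd2)
      pb1 <- parent_bd(child_bd1); pb2 <- parent_bd(child_bd2)
      gb <- parent_bd(pmin(pb1, pb2))
      persons[[length(persons) + 1L]] <<- data.table::rbindlist(list(
        mk(gf, fam, "male", gb, "grandparent"),
        mk(gm, fam, "female", gb, "grandparent"),
        mk(p1, fam, "female", pb1, "parent"),
        mk(p2, fam, "female", pb2, "parent"),
        mk(s1, fam, "male", pb1, "parent"),
        mk(s2, fam, "male", pb2, "parent"),
        mk(c1, fam, .rsex(m), child_bd1, "child"),
        mk(c2, fam, .rsex(m), child_bd2, "child")))
      parents[[length(parents) + 1L]] <<- data.table::data.table(
        person_id = c(p1, p2, c1, c2),
        mother_id = c(gm, gm, p1, p2),
        father_id = c(gf, gf, s1, s2))
    }
    invisible(NULL)
  }
  for (ty in names(counts)) add_block(ty, counts[[ty]])
  persons <- data.table::rbindlist(persons)
  persons[, malformation_flag := runif(.N) < config$malformation_rate]
  persons[role != "child", malformation_flag := FALSE]
  parents <- data.table::rbindlist(parents)
  zygosity <- if (length(zyg)) data.table::rbindlist(zyg) else
    data.table::data.table(person_id = integer(), twin_pair_id = integer(),
                           zygosity = character())
  data.table::setkey(persons, person_id)
  list(persons = persons, parents = parents, zygosity = zygosity)
}

#' Gene-drop bivariate liabilities through a pedigree
#'
#' Founders draw additive-genetic 2-vectors from a zero-mean bivariate
#' normal with correlation `rA`; each non-founder receives the mean of its
#' parents' vectors plus segregation noise with covariance `0.5 * R_A`
#' (no inbreeding). MZ co-twins get identical genetic vectors.
#' Common-environment vectors (correlation `rC`) are drawn once per
#' household (all children of one mother share a household) and
#' unique-environment vectors (correlation `rE`) independently per person.
#' Liabilities combine the three standardized components by the square-root
#' loadings, so the marginal liability variance is 1.
#'
#' @param pedigree Output of [simulate_pedigrees()] (or a list with
#'   `persons`, `parents`, `zygosity`).
#' @param params A [biv_ace_params] object.
#' @param seed Integer seed for this stage.
#' @return Numeric matrix (persons x 2) of liabilities, rows aligned with
#'   `pedigree$persons$person_id` and named by it.
#' @export
simulate_liabilities <- function(pedigree, params,
                                 seed = 1L + .stage_offsets[["liabilities"]]) {
  stopifnot(inherits(params, "biv_ace_params"))
  persons <- pedigree$persons
  parents <- pedigree$parents
  set.seed(seed)
  n <- nrow(persons)
  mrow <- match(parents$mother_id[match(persons$person_id,
                                        parents$person_id)],
                persons$person_id)
  frow <- match(parents$father_id[match(persons$person_id,
                                        parents$person_id)],
                persons$person_id)
  corr_chol <- function(r) chol(matrix(c(1, r, r, 1), 2))
  rnorm2 <- function(m, r) matrix(rnorm(2 * m), m, 2) %*% corr_chol(r)

  # generation depth: founders 0, child = max(parent depth) + 1
  depth <- rep(0L, n)
  has_par <- !is.na(mrow) | !is.na(frow)
  repeat {
    pd <- pmax(ifelse(is.na(mrow), -1L, depth[mrow]),
               ifelse(is.na(frow), -1L, depth[frow])) + 1L
    pd[!has_par] <- 0L
    if (all(pd == depth)) break
    depth <- pd
  }
  A <- matrix(NA_real_, n, 2)
  seg_chol <- chol(0.5 * matrix(c(1, params$rA, params$rA, 1), 2))
  for (d in sort(unique(depth))) {
    rows <- which(depth == d)
    if (d == 0L) {
      A[rows, ] <- rnorm2(length(rows), params$rA)
    } else {
      noise <- matrix(rnorm(2 * length(rows)), ncol = 2) %*% seg_chol
      A[rows, ] <- 0.5 * (A[mrow[rows], ] + A[frow[rows], ]) + noise
    }
  }
  # MZ co-twins: identical genetic vectors (copy from the lower person_id)
  zyg <- pedigree$zygosity
  if (nrow(zyg)) {
    mz <- zyg[zyg$zygosity == "MZ", ]
    if (nrow(mz)) {
      mz <- mz[order(mz$twin_pair_id, mz$person_id), ]
      first <- !duplicated(mz$twin_pair_id)
      src <- match(mz$person_id[first][match(mz$twin_pair_id,
                                             mz$twin_pair_id[first])],
                   persons$person_id)
      dst <- match(mz$person_id, persons$person_id)
      A[dst, ] <- A[src, ]
    }
  }
  # households: children of one mother share a C draw; founders own theirs
  mother_of <- parents$mother_id[match(persons$person_id, parents$person_id)]
  household <- ifelse(is.na(mother_of), persons$person_id, mother_of)
  hh <- unique(household)
  Ch <- rnorm2(length(hh), params$rC)
  C <- Ch[match(household, hh), , drop = FALSE]
  E <- rnorm2(n, params$rE)
  t1 <- params$trait1; t2 <- params$trait2
  L <- cbind(sqrt(t1$a2) * A[, 1] + sqrt(t1$c2) * C[, 1] +
               sqrt(t1$e2) * E[, 1],
             sqrt(t2$a2) * A[, 2] + sqrt(t2$c2) * C[, 2] +
               sqrt(t2$e2) * E[, 2])
  rownames(L) <- as.character(persons$person_id)
  L
}

#' Liability threshold for a target prevalence
#'
#' Returns the threshold `tau` such that a standard-normal liability
#' exceeds `tau` with probability `p`; a person is diagnosed when their
#' liability exceeds their threshold.
#'
#' @param p Prevalence in (0, 1); vectorized.
#' @return Threshold(s) on the liability scale.
#' @examples
#' threshold_for_prevalence(0.5)    # 0
#' threshold_for_prevalence(0.009)  # ~2.366
#' @export
threshold_for_prevalence <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("prevalence must lie strictly in (0, 1)")
  qnorm(p, lower.tail = FALSE)
}

#' Convert liabilities into registry diagnosis and person tables
#'
#' Applies the liability-threshold link with probit-scale sex and
#' birth-year threshold shifts, samples death and first-emigration dates
#' from constant yearly hazards, and emits one or more diagnosis event rows
#' per diagnosed person with an era-consistent ICD code drawn from the
#' configured code sets, dated uniformly within the person's follow-up
#' (registry start 1987-01-01 to 2020-12-31). Persons whose follow-up
#' window is empty produce no event rows.
#'
#' @param liabilities Matrix from [simulate_liabilities()].
#' @param pedigree Output of [simulate_pedigrees()].
#' @param config The [simulation_config()].
#' @return List with completed `persons` table (death/emigration dates
#'   filled) and `diagnoses` table.
#' @export
liabilities_to_registry <- function(liabilities, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + .stage_offsets[["registry"]])
  persons <- data.table::copy(pedigree$persons)
  n <- nrow(persons)
  reg_start <- as.Date("1987-01-01")
  reg_end <- as.Date("2020-12-31")
  byr <- as.integer(format(persons$birth_date, "%Y"))
  mid <- mean(config$birth_year_range)

  draw_years <- function(rate)
    if (rate > 0) rexp(n, rate) else rep(Inf, n)
  death_t <- draw_years(config$death_rate)
  emig_t <- draw_years(config$emigration_rate)
  death_date <- persons$birth_date + round(365.25 * death_t)
  emig_date <- persons$birth_date + round(365.25 * emig_t)
  death_date[death_date > reg_end] <- NA
  emig_date[emig_date > reg_end] <- NA
  emig_date[!is.na(death_date) & !is.na(emig_date) &
              emig_date >= death_date] <- NA
  data.table::set(persons, j = "death_date", value = death_date)
  data.table::set(persons, j = "emigration_date", value = emig_date)
  data.table::set(persons, j = "immigration_date", value = as.Date(NA))

  fu_start <- pmax(persons$birth_date, reg_start)
  fu_end <- pmin(data.table::fifelse(is.na(death_date), reg_end, death_date),
                 data.table::fifelse(is.na(emig_date), reg_end, emig_date),
                 reg_end)
  events <- list()
  for (t in 1:2) {
    shift <- config$sex_shift[t] * (persons$sex == "female") +
      config$birth_year_coef[t] * (byr - mid)
    # calibrate the base threshold so the marginal prevalence over the
    # realized covariate mix hits the target even with shifts active
    tau0 <- if (all(shift == 0)) threshold_for_prevalence(config$prevalence[t])
    else uniroot(function(t0)
      mean(pnorm(t0 + shift, lower.tail = FALSE)) - config$prevalence[t],
      interval = c(-8, 8), tol = 1e-10)$root
    tau <- tau0 + shift
    dx <- liabilities[, t] > tau & fu_start <= fu_end
    idx <- which(dx)
    if (!length(idx)) next
    n_ev <- 1L + rpois(length(idx), 0.3)
    rows <- rep(idx, n_ev)
    d0 <- as.integer(fu_start[rows]); d1 <- as.integer(fu_end[rows])
    ev_date <- as.Date(d0 + floor(runif(length(rows)) * (d1 - d0 + 1)),
                       origin = "1970-01-01")
    era9 <- as.integer(format(ev_date, "%Y")) <= 1996L
    codes <- config$trait_codes[[t]]
    code <- character(length(rows))
    code[era9] <- sample(rep_len(codes$icd9, 2), sum(era9), replace = TRUE)
    code[!era9] <- sample(rep_len(codes$icd10, 2), sum(!era9),
                          replace = TRUE)
    events[[t]] <- data.table::data.table(
      person_id = persons$person_id[rows],
      icd_revision = data.table::fifelse(era9, 9L, 10L),
      code = code, date = ev_date,
      source = sample(c("inpatient", "outpatient"), length(rows),
                      replace = TRUE, prob = c(0.4, 0.6)),
      phenotype = codes$name)
  }
  diagnoses <- if (length(events)) data.table::rbindlist(events) else
    data.table::data.table(person_id = integer(), icd_revision = integer(),
                           code = character(), date = as.Date(character()),
                           source = character(), phenotype = character())
  data.table::setorder(diagnoses, person_id, date)
  diagnoses[, phenotype := NULL]
  list(persons = persons, diagnoses = diagnoses)
}

#' Run the full synthetic-registry generator
#'
#' Convenience wrapper: pedigree structure, liabilities, thresholding and
#' registry tables in one call, fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of `data.table`s: `persons`, `parents`, `zygosity`,
#'   `diagnoses`, plus the liability matrix as attribute `"liabilities"`.
#' @export
simulate_registry <- function(config) {
  ped <- simulate_pedigrees(config)
  liab <- simulate_liabilities(ped, config$params,
                               seed = config$seed +
                                 .stage_offsets[["liabilities"]])
  reg <- liabilities_to_registry(liab, ped, config)
  out <- list(persons = reg$persons, parents = ped$parents,
              zygosity = ped$zygosity, diagnoses = reg$diagnoses)
  attr(out, "liabilities") <- liab
  out
}

#' Simulate sibling-pair liabilities or binary traits directly
#'
#' Fast path for Monte-Carlo studies of the pair estimators: generates
#' `n_pairs` families of a single structural type through the pedigree and
#' gene-dropping machinery and returns the two cohort children's bivariate
#' liabilities (and, if `prevalence` is given, their binary diagnoses).
#'
#' @param kinship One of `"full_sib"`, `"maternal_half_sib"`,
#'   `"paternal_half_sib"`, `"mz_twin"`, `"dz_twin"`, `"cousin"`.
#' @param n_pairs Number of pairs.
#' @param params A [biv_ace_params] object.
#' @param seed Integer seed.
#' @param prevalence Optional length-2 prevalences; when given, binary
#'   indicator matrices are returned alongside the liabilities.
#' @return List with matrices `liab_a`, `liab_b` (n_pairs x 2) and, when
#'   thresholding, `y_a`, `y_b` (0/1).
#' @export
simulate_sibling_pairs <- function(kinship, n_pairs, params, seed = 1L,
                                   prevalence = NULL) {
  if (kinship %in% c("MZ_twin", "DZ_twin")) kinship <- tolower(kinship)
  mix <- setNames(rep(0, 6), c("full_sib", "maternal_half_sib",
                               "paternal_half_sib", "mz_twin", "dz_twin",
                               "cousin"))
  if (!kinship %in% names(mix)) stop("unknown kinship type: ", kinship)
  mix[kinship] <- 1
  cfg <- simulation_config(n_families = n_pairs, family_mix = mix,
                           params = params, seed = seed)
  ped <- simulate_pedigrees(cfg)
  liab <- simulate_liabilities(ped, params,
                               seed = cfg$seed +
                                 .stage_offsets[["liabilities"]])
  kids <- ped$persons[ped$persons$role == "child", ]
  kids <- kids[order(kids$family_id, kids$person_id), ]
  ra <- match(kids$person_id[c(TRUE, FALSE)], ped$persons$person_id)
  rb <- match(kids$person_id[c(FALSE, TRUE)], ped$persons$person_id)
  out <- list(liab_a = liab[ra, , drop = FALSE],
              liab_b = liab[rb, , drop = FALSE])
  if (!is.null(prevalence)) {
    tau <- threshold_for_prevalence(prevalence)
    out$y_a <- sweep(out$liab_a, 2, tau, ">") + 0L
    out$y_b <- sweep(out$liab_b, 2, tau, ">") + 0L
  }
  out
}

#' Write registry tables as tab-delimited text
#'
#' Writes `persons.tsv`, `parents.tsv`, `zygosity.tsv` and `diagnoses.tsv`
#' (UTF-8, ISO-8601 dates, empty string for missing values) so they
#' round-trip losslessly through [read_registry()]. Internal bookkeeping
#' columns of the simulator are not written.
#'
#' @param tables List with `persons`, `parents`, `zygosity`, `diagnoses`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_registry <- function(tables, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  pers <- data.table::as.data.table(tables$persons)
  for (col in c("death_date", "immigration_date", "emigration_date",
                "malformation_flag"))
    if (!col %in% names(pers)) pers[, (col) := NA]
  pers <- pers[, .(person_id, sex, birth_date, death_date, immigration_date,
                   emigration_date,
                   malformation_flag = as.integer(malformation_flag))]
  wr <- function(x, f)
    data.table::fwrite(x, file.path(directory, f), sep = "\t", na = "",
                       quote = FALSE, dateTimeAs = "ISO")
  wr(pers, "persons.tsv")
  wr(data.table::as.data.table(tables$parents)[
    , .(person_id, mother_id, father_id)], "parents.tsv")
  wr(data.table::as.data.table(tables$zygosity), "zygosity.tsv")
  wr(data.table::as.data.table(tables$diagnoses)[
    , .(person_id, icd_revision, code, date, source)], "diagnoses.tsv")
  invisible(directory)
}
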