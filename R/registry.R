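# Cohort, phenotype and relative-pair machinery over register-style tables.

.parse_dates <- function(x, file, col) {
  d <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  filled <- !is.na(x) & nzchar(x)
  d[filled] <- as.Date(x[filled], format = "%Y-%m-%d")
  bad <- which(filled & is.na(d))
  if (length(bad))
    stop(sprintf("%s: malformed date '%s' in column '%s', row %d",
                 file, x[bad[1]], col, bad[1]))
  # reject dates that parse but renormalize (e.g. 1987-02-30)
  rt <- format(d[filled], "%Y-%m-%d")
  bad <- which(filled)[rt != x[filled]]
  if (length(bad))
    stop(sprintf("%s: invalid calendar date '%s' in column '%s', row %d",
                 file, x[bad[1]], col, bad[1]))
  d
}

.require_cols <- function(dt, cols, file) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(file, ": missing column(s) ", paste(miss, collapse = ", "))
}

#' Read and validate a registry directory
#'
#' Reads the tab-delimited registry schema (`persons.tsv`, `parents.tsv`,
#' `zygosity.tsv`, `diagnoses.tsv`), parses ISO-8601 dates strictly, and
#' verifies referential integrity: parent links and diagnosis rows must
#' point at existing persons, dates must be valid, and death/emigration
#' cannot precede birth. Parent links may not form cycles (no person can be
#' its own ancestor).
#'
#' @param directory Directory containing the four TSV files.
#' @return List of class `registry` with `data.table`s `persons`,
#'   `parents`, `zygosity`, `diagnoses`.
#' @export
read_registry <- function(directory) {
  rd <- function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("missing registry file: ", path)
    data.table::fread(path, sep = "\t", colClasses = "character",
                      na.strings = NULL)
  }
  pers <- rd("persons.tsv")
  .require_cols(pers, c("person_id", "sex", "birth_date", "death_date",
                        "immigration_date", "emigration_date",
                        "malformation_flag"), "persons.tsv")
  persons <- data.table::data.table(
    person_id = as.integer(pers$person_id),
    sex = pers$sex,
    birth_date = .parse_dates(pers$birth_date, "persons.tsv", "birth_date"),
    death_date = .parse_dates(pers$death_date, "persons.tsv", "death_date"),
    immigration_date = .parse_dates(pers$immigration_date, "persons.tsv",
                                    "immigration_date"),
    emigration_date = .parse_dates(pers$emigration_date, "persons.tsv",
                                   "emigration_date"),
    malformation_flag = pers$malformation_flag %in% c("1", "TRUE", "true"))
  if (anyNA(persons$person_id)) stop("persons.tsv: non-integer person_id")
  if (anyDuplicated(persons$person_id))
    stop("persons.tsv: duplicated person_id")
  if (!all(persons$sex %in% c("male", "female")))
    stop("persons.tsv: sex must be 'male' or 'female'")
  if (anyNA(persons$birth_date)) stop("persons.tsv: missing birth_date")
  for (col in c("death_date", "emigration_date")) {
    bad <- which(!is.na(persons[[col]]) &
                   persons[[col]] < persons$birth_date)
    if (length(bad))
      stop(sprintf("persons.tsv: %s before birth_date, row %d", col, bad[1]))
  }

  par <- rd("parents.tsv")
  .require_cols(par, c("person_id", "mother_id", "father_id"), "parents.tsv")
  to_id <- function(x) ifelse(nzchar(x), suppressWarnings(as.integer(x)), NA)
  parents <- data.table::data.table(person_id = as.integer(par$person_id),
                                    mother_id = to_id(par$mother_id),
                                    father_id = to_id(par$father_id))
  known <- persons$person_id
  for (col in c("person_id", "mother_id", "father_id")) {
    dangling <- which(!is.na(parents[[col]]) & !parents[[col]] %in% known)
    if (length(dangling))
      stop(sprintf("parents.tsv: dangling id %d in column '%s', row %d",
                   parents[[col]][dangling[1]], col, dangling[1]))
  }
  if (nrow(parents)) {
    el <- rbind(
      cbind(parents$mother_id, parents$person_id),
      cbind(parents$father_id, parents$person_id))
    el <- el[!is.na(el[, 1]), , drop = FALSE]
    if (nrow(el)) {
      g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                       directed = TRUE)
      if (!igraph::is_dag(g))
        stop("parents.tsv: contradictory links, a person is its own ancestor")
    }
  }

  zy <- rd("zygosity.tsv")
  .require_cols(zy, c("person_id", "twin_pair_id", "zygosity"),
                "zygosity.tsv")
  zygosity <- data.table::data.table(person_id = as.integer(zy$person_id),
                                     twin_pair_id = as.integer(zy$twin_pair_id),
                                     zygosity = zy$zygosity)
  if (nrow(zygosity) && !all(zygosity$person_id %in% known))
    stop("zygosity.tsv: unknown person_id")

  dx <- rd("diagnoses.tsv")
  .require_cols(dx, c("person_id", "icd_revision", "code", "date", "source"),
                "diagnoses.tsv")
  diagnoses <- data.table::data.table(
    person_id = as.integer(dx$person_id),
    icd_revision = as.integer(dx$icd_revision),
    code = dx$code,
    date = .parse_dates(dx$date, "diagnoses.tsv", "date"),
    source = dx$source)
  bad <- which(!diagnoses$person_id %in% known)
  if (length(bad))
    stop(sprintf("diagnoses.tsv: unknown person_id %d, row %d",
                 diagnoses$person_id[bad[1]], bad[1]))
  if (nrow(diagnoses) &&
      !all(diagnoses$source %in% c("inpatient", "outpatient",
                                   "cause_of_death")))
    stop("diagnoses.tsv: unknown source value")
  structure(list(persons = persons, parents = parents, zygosity = zygosity,
                 diagnoses = diagnoses), class = "registry")
}

# calendar arithmetic: nth birthday (Feb 29 birthdays roll to Mar 1)
.add_years <- function(d, n) {
  lt <- as.POSIXlt(d)
  lt$year <- lt$year + n
  as.Date(format(as.POSIXct(lt, tz = "UTC"), "%Y-%m-%d"))
}

#' Apply birth-cohort exclusions
#'
#' Keeps persons born inside the cohort window with a known biological
#' mother and no congenital-malformation flag, and excludes anyone who died
#' or first emigrated before their 18th birthday (so all cohort members had
#' time to receive an exposure diagnosis in adulthood).
#'
#' @param registry A `registry` list from [read_registry()] (or the
#'   simulator's in-memory tables).
#' @param birth_window Two dates; default 1973-01-01 to 2001-12-31.
#' @param min_age Minimum attained age in years (default 18).
#' @return `data.table` of cohort persons, with attribute `"exclusions"`
#'   holding counts per exclusion reason.
#' @export
apply_cohort_exclusions <- function(registry,
                                    birth_window = as.Date(c("1973-01-01",
                                                             "2001-12-31")),
                                    min_age = 18) {
  persons <- data.table::as.data.table(registry$persons)
  parents <- data.table::as.data.table(registry$parents)
  known_mother <- persons$person_id %in%
    parents$person_id[!is.na(parents$mother_id)]
  in_window <- persons$birth_date >= birth_window[1] &
    persons$birth_date <= birth_window[2]
  malformed <- isTRUE_vec(persons$malformation_flag)
  coming_of_age <- .add_years(persons$birth_date, min_age)
  died_young <- !is.na(persons$death_date) &
    persons$death_date < coming_of_age
  left_young <- !is.na(persons$emigration_date) &
    persons$emigration_date < coming_of_age
  keep <- in_window & known_mother & !malformed & !died_young & !left_young
  out <- persons[keep]
  attr(out, "exclusions") <- c(
    outside_birth_window = sum(!in_window),
    unknown_mother = sum(in_window & !known_mother),
    malformation = sum(in_window & known_mother & malformed),
    died_before_18 = sum(in_window & known_mother & !malformed & died_young),
    emigrated_before_18 = sum(in_window & known_mother & !malformed &
                                !died_young & left_young))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Define a phenotype by ICD code sets
#'
#' @param name Phenotype name.
#' @param domain One of `"psychiatric"`, `"somatic"`, `"behavioral"`.
#' @param icd9,icd10 Character vectors of code prefixes per ICD revision
#'   (a diagnosis row matches when its code starts with a listed prefix in
#'   the matching revision). At least one code overall is required.
#' @param female_only Restrict the outcome to female individuals.
#' @param within_generation_only Analyze only within-generation relative
#'   pairs (used for psychiatric phenotypes, whose register coverage in the
#'   parental generation is limited).
#' @param cause_of_death_source Ascertain only from cause-of-death rows
#'   (death by suicide), instead of in/outpatient care.
#' @return Object of class `phenotype_def`.
#' @export
phenotype_definition <- function(name, domain = "psychiatric",
                                 icd9 = character(), icd10 = character(),
                                 female_only = FALSE,
                                 within_generation_only =
                                   domain == "psychiatric",
                                 cause_of_death_source = FALSE) {
  domain <- match.arg(domain, c("psychiatric", "somatic", "behavioral"))
  if (length(icd9) + length(icd10) == 0)
    stop("phenotype '", name, "' needs at least one ICD code")
  structure(list(name = name, domain = domain, icd9 = icd9, icd10 = icd10,
                 female_only = isTRUE(female_only),
                 within_generation_only = isTRUE(within_generation_only),
                 cause_of_death_source = isTRUE(cause_of_death_source)),
            class = "phenotype_def")
}

#' Read phenotype definitions from YAML
#'
#' The file holds a list of entries with fields `name`, `domain`, `icd9`,
#' `icd10` and optional flags `female_only`, `within_generation_only`,
#' `cause_of_death_source`.
#'
#' @param path YAML file path.
#' @return Named list of [phenotype_definition()] objects.
#' @export
read_phenotype_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(x)
    phenotype_definition(
      name = x$name, domain = x$domain,
      icd9 = as.character(x$icd9 %||% character()),
      icd10 = as.character(x$icd10 %||% character()),
      female_only = isTRUE(x$female_only),
      within_generation_only =
        if (is.null(x$within_generation_only)) x$domain == "psychiatric"
        else isTRUE(x$within_generation_only),
      cause_of_death_source = isTRUE(x$cause_of_death_source)))
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ascertain a lifetime phenotype
#'
#' A person's lifetime indicator is 1 when at least one diagnosis row
#' matches the definition's code set in the matching ICD revision, from
#' in/outpatient care (or, for cause-of-death phenotypes such as suicide,
#' exclusively from cause-of-death rows). For female-only phenotypes the
#' indicator is `NA` for males.
#'
#' @param persons Person table (cohort or full registry persons).
#' @param definition A [phenotype_definition()].
#' @param diagnoses Diagnosis table.
#' @return `data.table` with `person_id`, `indicator` (0/1, `NA` when not
#'   ascertainable) and `first_date` of the earliest matching diagnosis.
#' @export
ascertain_phenotype <- function(persons, definition, diagnoses) {
  stopifnot(inherits(definition, "phenotype_def"))
  persons <- data.table::as.data.table(persons)
  dx <- data.table::as.data.table(diagnoses)
  match_codes <- function(codes, prefixes) {
    if (!length(prefixes)) return(rep(FALSE, length(codes)))
    Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
  }
  src_ok <- if (definition$cause_of_death_source)
    dx$source == "cause_of_death"
  else dx$source %in% c("inpatient", "outpatient")
  hit <- src_ok &
    ((dx$icd_revision == 9L & match_codes(dx$code, definition$icd9)) |
       (dx$icd_revision == 10L & match_codes(dx$code, definition$icd10)))
  firsts <- if (any(hit))
    dx[hit, .(first_date = min(date)), by = person_id]
  else data.table::data.table(person_id = integer(),
                              first_date = as.Date(character()))
  out <- data.table::data.table(person_id = persons$person_id)
  out[, first_date := firsts$first_date[match(person_id,
                                              firsts$person_id)]]
  out[, indicator := as.integer(!is.na(first_date))]
  if (definition$female_only)
    out[persons$sex != "female", `:=`(indicator = NA_integer_,
                                      first_date = as.Date(NA))]
  out[]
}

#' Compute follow-up windows for one phenotype
#'
#' Follow-up runs from the latest of birth, first immigration and the
#' registry start (1987-01-01) until the earliest of first emigration,
#' first matching diagnosis, death and the registry end (2020-12-31).
#' Intervals are closed; a diagnosis on the start date counts as an event.
#' Persons whose window is empty are flagged `degenerate` and carry
#' `event = NA`.
#'
#' @param persons Person table.
#' @param first_dates Output of [ascertain_phenotype()] (or a vector of
#'   first-diagnosis dates aligned with `persons`).
#' @param registry_window Two dates bounding register coverage.
#' @return `data.table` with `person_id`, `start`, `end`, `event`,
#'   `degenerate`.
#' @export
compute_follow_up <- function(persons, first_dates,
                              registry_window = as.Date(c("1987-01-01",
                                                          "2020-12-31"))) {
  persons <- data.table::as.data.table(persons)
  fd <- if (is.data.frame(first_dates))
    first_dates$first_date[match(persons$person_id, first_dates$person_id)]
  else rep_len(as.Date(first_dates), nrow(persons))
  pmin_na <- function(...) do.call(pmin, c(list(...), na.rm = TRUE))
  pmax_na <- function(...) do.call(pmax, c(list(...), na.rm = TRUE))
  start <- pmax_na(persons$birth_date, persons$immigration_date,
                   registry_window[1])
  end <- pmin_na(persons$emigration_date, fd, persons$death_date,
                 registry_window[2])
  degenerate <- start > end
  event <- !is.na(fd) & fd <= end & !degenerate
  out <- data.table::data.table(person_id = persons$person_id,
                                start = start, end = end,
                                event = as.integer(event),
                                degenerate = degenerate)
  out[degenerate == TRUE, event := NA_integer_]
  attr(out, "n_degenerate") <- sum(degenerate)
  out[]
}

#' Extended-family cluster ids
#'
#' Connected components of the person-parent graph: two persons fall in the
#' same cluster when linked through any chain of parent-child relations.
#' Used as the clustering unit for sandwich variances, so every double
#' entered or overlapping relative pair lies within one cluster.
#'
#' @param persons Person table.
#' @param parents Parent-link table.
#' @return Integer vector of cluster ids aligned with `persons$person_id`.
#' @export
family_clusters <- function(persons, parents) {
  persons <- data.table::as.data.table(persons)
  parents <- data.table::as.data.table(parents)
  verts <- as.character(persons$person_id)
  el <- rbind(cbind(parents$person_id, parents$mother_id),
              cbind(parents$person_id, parents$father_id))
  el <- el[!is.na(el[, 1]) & !is.na(el[, 2]), , drop = FALSE]
  edges <- data.frame(from = as.character(el[, 1]),
                      to = as.character(el[, 2]))
  all_verts <- unique(c(verts, edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = all_verts))
  comp <- igraph::components(g)$membership
  unname(comp[verts])
}

#' Enumerate relative pairs from register tables
#'
#' Classifies kinship from parent links (shared mother and father = full
#' sibling; shared mother only = maternal half-sibling; shared father only
#' = paternal half-sibling; parents who are full siblings = first cousins)
#' and from the zygosity table (MZ/DZ twins; twin pairs with unknown
#' zygosity are excluded from the twin sets but remain full siblings).
#' Within-generation pairs (twins, full/half siblings, cousins) are emitted
#' in both orientations ("double entry"); between-generation pairs
#' (parent-child, aunt/uncle) once, with the older relative on the exposure
#' side (`id_a`) and restricted to relatives born on or after
#' `relative_birth_floor` to respect register coverage.
#'
#' @param registry A `registry` list.
#' @param cohort Cohort person table ([apply_cohort_exclusions()]); both
#'   members of within-generation pairs, and the younger member of
#'   between-generation pairs, must belong to it.
#' @param kinships Kinship types to emit.
#' @param relative_birth_floor Earliest allowed birth date for the older
#'   relative of between-generation pairs (default 1933-01-01).
#' @return `data.table` with `id_a`, `id_b`, `kinship`, `alpha`, `gamma`,
#'   `generation` (`"within"`/`"between"`).
#' @export
enumerate_relative_pairs <- function(registry, cohort,
                                     kinships = c("MZ_twin", "DZ_twin",
                                                  "full_sib",
                                                  "maternal_half_sib",
                                                  "paternal_half_sib",
                                                  "parent_child",
                                                  "aunt_uncle", "cousin"),
                                     relative_birth_floor =
                                       as.Date("1933-01-01")) {
  parents <- data.table::as.data.table(registry$parents)
  persons <- data.table::as.data.table(registry$persons)
  zygosity <- data.table::as.data.table(registry$zygosity)
  cohort_ids <- cohort$person_id

  sib_pairs_all <- local({
    p <- parents[, .(person_id, mother_id, father_id)]
    bym <- merge(p, p, by = "mother_id", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))[person_id_a < person_id_b]
    byf <- merge(p, p, by = "father_id", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))[person_id_a < person_id_b]
    bym <- bym[!is.na(mother_id)]
    byf <- byf[!is.na(father_id)]
    full_keys <- intersect(bym[!is.na(father_id_a) &
                                 father_id_a == father_id_b,
                               paste(person_id_a, person_id_b)],
                           byf[, paste(person_id_a, person_id_b)])
    bym[, key := paste(person_id_a, person_id_b)]
    byf[, key := paste(person_id_a, person_id_b)]
    full <- bym[key %in% full_keys,
                .(id_a = person_id_a, id_b = person_id_b,
                  kinship = "full_sib")]
    mhalf <- bym[!key %in% full_keys,
                 .(id_a = person_id_a, id_b = person_id_b,
                   kinship = "maternal_half_sib")]
    phalf <- byf[!key %in% full_keys,
                 .(id_a = person_id_a, id_b = person_id_b,
                   kinship = "paternal_half_sib")]
    data.table::rbindlist(list(full, mhalf, phalf))
  })

  # twin reclassification among full siblings
  if (nrow(zygosity)) {
    zy <- zygosity[order(twin_pair_id, person_id)]
    tw <- zy[, .(id_a = person_id[1], id_b = person_id[2],
                 zygosity = zygosity[1]), by = twin_pair_id]
    tw <- tw[!is.na(id_b)]
    sib_pairs_all[tw, on = c("id_a", "id_b"),
                  kinship := data.table::fifelse(
                    i.zygosity == "MZ", "MZ_twin",
                    data.table::fifelse(i.zygosity == "DZ", "DZ_twin",
                                        kinship))]
  }

  within <- sib_pairs_all[id_a %in% cohort_ids & id_b %in% cohort_ids]

  # cousins: children of full-sibling parents
  if ("cousin" %in% kinships) {
    psibs <- sib_pairs_all[kinship %in% c("full_sib", "MZ_twin", "DZ_twin"),
                           .(id_a, id_b)]
    if (nrow(psibs)) {
      kids <- parents[, .(person_id, mother_id, father_id)]
      kid_of <- data.table::rbindlist(list(
        kids[!is.na(mother_id), .(parent = mother_id, child = person_id)],
        kids[!is.na(father_id), .(parent = father_id, child = person_id)]))
      kid_of <- unique(kid_of)
      cz <- merge(merge(psibs, kid_of, by.x = "id_a", by.y = "parent",
                        allow.cartesian = TRUE),
                  kid_of, by.x = "id_b", by.y = "parent",
                  allow.cartesian = TRUE, suffixes = c("_a", "_b"))
      if (nrow(cz)) {
        cz <- unique(data.table::data.table(
          id_a = pmin(cz$child_a, cz$child_b),
          id_b = pmax(cz$child_a, cz$child_b)))
        cz <- cz[id_a != id_b & id_a %in% cohort_ids & id_b %in% cohort_ids]
        # genuine cousins only: drop pairs that are already siblings
        cz[, kinship := "cousin"]
        sibkeys <- within[, paste(id_a, id_b)]
        cz <- cz[!paste(id_a, id_b) %in% sibkeys]
        within <- data.table::rbindlist(list(within, cz), use.names = TRUE)
      }
    }
  }
  within <- within[kinship %in% kinships]
  # double entry: both orientations
  within2 <- data.table::rbindlist(list(
    within,
    within[, .(id_a = id_b, id_b = id_a, kinship)]))
  within2[, generation := "within"]

  between <- data.table::data.table(id_a = integer(), id_b = integer(),
                                    kinship = character())
  if ("parent_child" %in% kinships) {
    pc <- data.table::rbindlist(list(
      parents[!is.na(mother_id), .(id_a = mother_id, id_b = person_id)],
      parents[!is.na(father_id), .(id_a = father_id, id_b = person_id)]))
    pc <- pc[id_b %in% cohort_ids]
    pc[, kinship := "parent_child"]
    between <- data.table::rbindlist(list(between, pc))
  }
  if ("aunt_uncle" %in% kinships) {
    psibs <- sib_pairs_all[kinship %in% c("full_sib", "MZ_twin", "DZ_twin"),
                           .(id_a, id_b)]
    psibs <- data.table::rbindlist(list(psibs,
                                        psibs[, .(id_a = id_b,
                                                  id_b = id_a)]))
    kids <- data.table::rbindlist(list(
      parents[!is.na(mother_id), .(parent = mother_id, child = person_id)],
      parents[!is.na(father_id), .(parent = father_id, child = person_id)]))
    au <- merge(psibs, unique(kids), by.x = "id_b", by.y = "parent",
                allow.cartesian = TRUE)[, .(id_a, id_b = child)]
    au <- unique(au[id_b %in% cohort_ids])
    au[, kinship := "aunt_uncle"]
    between <- data.table::rbindlist(list(between, au))
  }
  if (nrow(between)) {
    bd <- persons$birth_date[match(between$id_a, persons$person_id)]
    between <- between[!is.na(bd) & bd >= relative_birth_floor]
    between[, generation := "between"]
  } else between[, generation := character()]

  out <- data.table::rbindlist(list(within2, between), use.names = TRUE)
  kc <- kinship_coefficients()
  out[, alpha := kc$alpha[match(kinship, kc$kinship)]]
  out[, gamma := kc$gamma[match(kinship, kc$kinship)]]
  out[]
}

#' Select one sibling pair per kinship type per family cluster
#'
#' Family clusters are connected components of the sibling graph (full and
#' half-sibling edges). Within each cluster and kinship type the retained
#' pair is the one (1) closest in age; ties are broken by (2) the earliest
#' birth date of the older member, then (3) a seeded uniform draw. MZ twin
#' pairs are never candidates for the full-sibling set; DZ twins are
#' ordinary full siblings genetically and are included as such when
#' `include_dz_twins` is `TRUE`.
#'
#' @param pairs Pair table from [enumerate_relative_pairs()] (orientations
#'   are deduplicated internally).
#' @param persons Person table supplying birth dates.
#' @param seed Integer seed for the final random tie-break.
#' @param include_dz_twins Treat DZ twin pairs as full-sibling candidates.
#' @return `data.table` of selected pairs (`id_a`, `id_b`, `kinship`,
#'   `alpha`, `gamma`, `cluster`).
#' @export
select_unique_sibling_pairs <- function(pairs, persons, seed = 1L,
                                        include_dz_twins = TRUE) {
  persons <- data.table::as.data.table(persons)
  dt <- data.table::as.data.table(pairs)
  dt <- dt[, .(id_a = pmin(id_a, id_b), id_b = pmax(id_a, id_b), kinship)]
  dt <- unique(dt)
  if (include_dz_twins)
    dt[kinship == "DZ_twin", kinship := "full_sib"]
  dt <- dt[kinship %in% c("full_sib", "maternal_half_sib",
                          "paternal_half_sib")]
  if (!nrow(dt)) return(dt[, .(id_a, id_b, kinship)])
  # clusters: components over sibling edges
  g <- igraph::graph_from_edgelist(
    cbind(as.character(dt$id_a), as.character(dt$id_b)), directed = FALSE)
  memb <- igraph::components(g)$membership
  dt[, cluster := unname(memb[as.character(id_a)])]
  bd <- persons$birth_date
  pid <- persons$person_id
  dt[, bd_a := bd[match(id_a, pid)]]
  dt[, bd_b := bd[match(id_b, pid)]]
  dt[, gap := abs(as.integer(bd_a) - as.integer(bd_b))]
  dt[, older_bd := pmin(bd_a, bd_b)]
  set.seed(seed)
  dt[, jitter := runif(.N)]
  data.table::setorder(dt, cluster, kinship, gap, older_bd, jitter)
  sel <- dt[, .SD[1], by = .(cluster, kinship)]
  kc <- kinship_coefficients()
  sel[, alpha := kc$alpha[match(kinship, kc$kinship)]]
  sel[, gamma := kc$gamma[match(kinship, kc$kinship)]]
  sel[, .(id_a, id_b, kinship, alpha, gamma, cluster)]
}
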