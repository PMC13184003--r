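# End-to-end orchestration: simulate -> build cohort -> co-aggregation ORs
# -> sibling-pair ACE models, with provenance and publication-style tables.

#' Pipeline run configuration
#'
#' @param simulation A [simulation_config()] (used unless `registry_dir`
#'   points at existing registry files).
#' @param registry_dir Optional directory with pre-existing registry TSVs.
#' @param phenotypes Named list of [phenotype_definition()]s; the FIRST
#'   entry is the exposure phenotype. Defaults to the two traits the
#'   simulator emits.
#' @param analyses Character subset of `c("within_individual",
#'   "coaggregation", "ace")`.
#' @param out_dir Output directory.
#' @param seed Global seed, propagated to the simulator and every
#'   stochastic stage.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(n_families = 20000,
                                                           seed = seed),
                            registry_dir = NULL,
                            phenotypes = default_phenotypes(),
                            analyses = c("within_individual",
                                         "coaggregation", "ace"),
                            out_dir = tempfile("famliab_run"),
                            seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.null(registry_dir) && !dir.exists(registry_dir))
    stop("registry_dir does not exist: ", registry_dir)
  if (length(phenotypes) < 2)
    stop("need at least an exposure and one outcome phenotype")
  stopifnot(all(vapply(phenotypes, inherits, TRUE, "phenotype_def")))
  structure(list(simulation = simulation, registry_dir = registry_dir,
                 phenotypes = phenotypes, analyses = analyses,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Default phenotype definitions matching the simulator's code sets
#' @return Named list of two [phenotype_definition()]s (exposure first).
#' @export
default_phenotypes <- function() {
  list(
    bpd = phenotype_definition("bpd", "psychiatric",
                               icd9 = c("301D", "301J"), icd10 = "F60.3"),
    depression = phenotype_definition("depression", "psychiatric",
                                      icd9 = "311",
                                      icd10 = c("F32", "F33")))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (unless a registry
#' directory is supplied), read and validate the registry, apply cohort
#' exclusions, ascertain lifetime phenotypes, descriptives,
#' within-individual and per-kinship co-aggregation odds ratios, sibling
#' pair selection, latent correlation structure, univariate and bivariate
#' ACE fits with screening. All outputs are written under
#' `config$out_dir` together with a provenance record (config hash, seed,
#' package version); a rerun with the same config reproduces every
#' stochastic output byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return Result bundle (list) with elements `cohort`, `descriptives`,
#'   `coaggregation`, `structure`, `univariate`, `bivariate`, `screening`,
#'   `paths`; invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reg_dir <- config$registry_dir
  if (is.null(reg_dir)) {
    sim <- config$simulation
    sim$seed <- config$seed
    reg_dir <- file.path(out_dir, "registry")
    write_registry(simulate_registry(sim), reg_dir)
  }
  registry <- read_registry(reg_dir)
  cohort <- apply_cohort_exclusions(registry)
  defs <- config$phenotypes
  exposure_def <- defs[[1]]

  asc <- lapply(defs, ascertain_phenotype, persons = cohort,
                diagnoses = registry$diagnoses)
  cohort_dt <- data.table::as.data.table(cohort)
  cohort_dt[, birth_year := as.integer(format(birth_date, "%Y"))]
  cohort_dt[, cluster := family_clusters(cohort_dt, registry$parents)]
  cohort_dt[, exposure := asc[[1]]$indicator]

  descr <- descriptive_table(
    cohort_dt,
    phenotypes = lapply(asc[-1], `[[`, "indicator"))
  data.table::fwrite(descr, file.path(out_dir, "descriptives.tsv"),
                     sep = "\t")

  outcome_names <- names(defs)[-1]
  coagg <- list()
  if ("within_individual" %in% config$analyses) {
    for (nm in outcome_names) {
      fit <- within_individual_or(
        data.table::data.table(exposure = cohort_dt$exposure,
                               outcome = asc[[nm]]$indicator,
                               sex = cohort_dt$sex,
                               birth_year = cohort_dt$birth_year,
                               cluster = cohort_dt$cluster),
        female_only = defs[[nm]]$female_only)
      coagg[[length(coagg) + 1L]] <- .or_row(nm, "within_individual", fit)
    }
  }

  pairs <- enumerate_relative_pairs(registry, cohort_dt)
  data.table::fwrite(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t")
  if ("coaggregation" %in% config$analyses) {
    for (nm in outcome_names) {
      def <- defs[[nm]]
      use <- if (def$within_generation_only) pairs[generation == "within"]
      else pairs
      for (kn in unique(use$kinship)) {
        pk <- use[kinship == kn]
        pd <- data.table::data.table(
          exposure_a = cohort_expand(asc[[1]]$indicator, cohort_dt,
                                     pk$id_a, registry),
          outcome_b = cohort_expand(asc[[nm]]$indicator, cohort_dt,
                                    pk$id_b, registry),
          sex_a = person_field(registry, pk$id_a, "sex"),
          sex_b = person_field(registry, pk$id_b, "sex"),
          birth_year_a = person_year(registry, pk$id_a),
          birth_year_b = person_year(registry, pk$id_b),
          cluster = family_clusters(
            data.table::data.table(person_id = pk$id_a),
            registry$parents))
        fit <- tryCatch(
          familial_coaggregation_or(pd, female_only = def$female_only),
          error = function(e) .suppressed_fit(conditionMessage(e)))
        coagg[[length(coagg) + 1L]] <- .or_row(nm, kn, fit)
      }
    }
  }
  coagg <- if (length(coagg)) data.table::rbindlist(coagg) else
    data.table::data.table()
  if (nrow(coagg))
    data.table::fwrite(coagg, file.path(out_dir, "coaggregation.tsv"),
                       sep = "\t")

  structure_tab <- NULL; uni <- NULL; biv <- NULL; screening <- NULL
  if ("ace" %in% config$analyses) {
    sel <- select_unique_sibling_pairs(pairs, registry$persons,
                                       seed = config$seed)
    # covariate-adjusted thresholds on the full cohort
    tau <- list()
    for (tr in 1:2) {
      nm <- names(defs)[tr]
      y <- asc[[nm]]$indicator
      sb <- natural_spline_basis(cohort_dt$birth_year, df = 5)
      X <- cbind(female = as.integer(cohort_dt$sex == "female"), sb$basis)
      tm <- estimate_thresholds(y, X)
      tau[[tr]] <- tm$thresholds
    }
    row_a <- match(sel$id_a, cohort_dt$person_id)
    row_b <- match(sel$id_b, cohort_dt$person_id)
    ok <- !is.na(row_a) & !is.na(row_b)
    sel <- sel[ok]; row_a <- row_a[ok]; row_b <- row_b[ok]
    pair_data <- data.table::data.table(
      kinship = sel$kinship,
      y1_a = asc[[1]]$indicator[row_a], y2_a = asc[[2]]$indicator[row_a],
      y1_b = asc[[1]]$indicator[row_b], y2_b = asc[[2]]$indicator[row_b],
      tau1_a = tau[[1]][row_a], tau2_a = tau[[2]][row_a],
      tau1_b = tau[[1]][row_b], tau2_b = tau[[2]][row_b])
    structure_tab <- pair_polychoric_structure(pair_data)
    data.table::fwrite(structure_tab, file.path(out_dir, "structure.tsv"),
                       sep = "\t")
    uni <- lapply(1:2, function(tr) {
      mom <- paste0("same_trait", tr)
      st <- structure_tab[moment == mom & is.finite(r)]
      if (nrow(st) < 2) return(NULL)
      fit_univariate_ace(st$r, st$alpha, st$gamma, var = st$var)
    })
    names(uni) <- names(defs)[1:2]
    # screening: within-person correlation and pooled pair counts (trait 2)
    wtab <- tetrachoric_pairs(
      c(pair_data$y1_a, pair_data$y1_b), c(pair_data$y2_a, pair_data$y2_b),
      c(pair_data$tau1_a, pair_data$tau1_b),
      c(pair_data$tau2_a, pair_data$tau2_b))
    cnt <- attr(structure_tab, "pair_counts")
    cnt2 <- cnt[trait == 2L]
    screening <- screen_phenotypes(wtab$rho, sum(cnt2$concordant),
                                   sum(cnt2$discordant))
    if (screening$include) {
      uc2 <- vapply(uni, function(u) if (is.null(u)) NA_real_ else u$c2, 0)
      biv <- fit_bivariate_ace(structure_tab, univariate_c2 = uc2)
      jsonlite::write_json(
        list(theta = as.list(fit_theta(biv)), fixed_c = biv$fixed_c,
             converged = biv$converged, objective = biv$objective,
             derived = biv$derived, screening = screening),
        file.path(out_dir, "ace.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    }
  }

  prov_cfg <- file.path(out_dir, "config.json")
  jsonlite::write_json(.config_fingerprint(config), prov_cfg,
                       auto_unbox = TRUE, digits = NA)
  prov <- list(config_hash = unname(tools::md5sum(prov_cfg)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("famliab")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  bundle <- list(cohort = cohort_dt, descriptives = descr,
                 coaggregation = coagg, structure = structure_tab,
                 univariate = uni, bivariate = biv, screening = screening,
                 paths = list(out_dir = out_dir, registry = reg_dir))
  class(bundle) <- "famliab_bundle"
  invisible(bundle)
}

fit_theta <- function(fit) fit$theta

.config_fingerprint <- function(config) {
  sim <- config$simulation
  list(seed = config$seed,
       analyses = config$analyses,
       registry_dir = config$registry_dir,
       phenotypes = lapply(config$phenotypes, unclass),
       simulation = list(
         n_families = sim$n_families,
         family_mix = as.list(sim$family_mix),
         prevalence = sim$prevalence,
         sex_shift = sim$sex_shift,
         birth_year_coef = sim$birth_year_coef,
         birth_year_range = sim$birth_year_range,
         death_rate = sim$death_rate,
         emigration_rate = sim$emigration_rate,
         malformation_rate = sim$malformation_rate,
         params = list(
           trait1 = unclass(sim$params$trait1),
           trait2 = unclass(sim$params$trait2),
           rA = sim$params$rA, rC = sim$params$rC, rE = sim$params$rE)))
}

.or_row <- function(phenotype, kinship, fit) {
  if (isTRUE(fit$suppressed))
    data.table::data.table(phenotype = phenotype, kinship = kinship,
                           or = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, n = fit$n,
                           clusters = fit$n_clusters, suppressed = TRUE)
  else {
    row <- fit$or_table[fit$or_table$term == "exposure", ]
    data.table::data.table(phenotype = phenotype, kinship = kinship,
                           or = row$or, ci_low = row$ci_low,
                           ci_high = row$ci_high, n = fit$n,
                           clusters = fit$n_clusters, suppressed = FALSE)
  }
}

cohort_expand <- function(indicator, cohort_dt, ids, registry) {
  indicator[match(ids, cohort_dt$person_id)]
}

person_field <- function(registry, ids, field) {
  registry$persons[[field]][match(ids, registry$persons$person_id)]
}

person_year <- function(registry, ids) {
  as.integer(format(person_field(registry, ids, "birth_date"), "%Y"))
}

#' Render a result bundle as plain-text report tables
#'
#' Produces a descriptives table, an OR-by-kinship table per phenotype
#' (suppressed estimates rendered `NA`), the ACE decomposition
#' (bivA/bivC/bivE with CIs, ordered by absolute genetic contribution) and
#' a genetic-correlation line.
#'
#' @param bundle Result of [run_pipeline()].
#' @param file Optional path; when given the report is also written there.
#' @return Character vector of report lines, invisibly when `file` given.
#' @export
render_tables <- function(bundle, file = NULL) {
  fmt_or <- function(or, lo, hi, suppressed)
    ifelse(suppressed | !is.finite(or), "NA",
           sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
  lines <- c("== Cohort descriptives ==")
  d <- bundle$descriptives
  lines <- c(lines, sprintf("%-12s %-14s %10s %10s (%5s%%) %8s (%5s%%)",
                            "block", "label", "total", "unexposed", "pct",
                            "exposed", "pct"))
  lines <- c(lines, sprintf("%-12s %-14s %10d %10d (%5.1f%%) %8d (%5.1f%%)",
                            d$block, d$label, d$n_total, d$n_unexposed,
                            d$pct_unexposed, d$n_exposed, d$pct_exposed))
  if (!is.null(bundle$coaggregation) && nrow(bundle$coaggregation)) {
    lines <- c(lines, "", "== Odds ratios (adjusted, cluster-robust 95% CI) ==")
    co <- bundle$coaggregation
    lines <- c(lines, sprintf("%-14s %-20s %-22s n=%d", co$phenotype,
                              co$kinship,
                              fmt_or(co$or, co$ci_low, co$ci_high,
                                     co$suppressed), co$n))
  }
  if (!is.null(bundle$bivariate)) {
    der <- bundle$bivariate$derived
    pick <- function(q) der[der$quantity == q, ]
    dec <- do.call(rbind, lapply(c("bivA", "bivC", "bivE"), pick))
    dec <- dec[order(-abs(dec$estimate)), ]
    lines <- c(lines, "", "== ACE decomposition of the phenotypic correlation ==",
               sprintf("r_ph = %.3f", pick("r_ph")$estimate),
               sprintf("%-5s %7.1f%% (95%%CI %6.1f%% to %6.1f%%)",
                       dec$quantity, 100 * dec$estimate, 100 * dec$ci_low,
                       100 * dec$ci_high),
               sprintf("genetic correlation rA = %.2f (95%%CI %.2f to %.2f)",
                       pick("rA")$estimate, pick("rA")$ci_low,
                       pick("rA")$ci_high))
  } else if (!is.null(bundle$screening) && !bundle$screening$include) {
    lines <- c(lines, "", paste("Bivariate model not fitted:",
                                paste(bundle$screening$reasons,
                                      collapse = ", ")))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
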