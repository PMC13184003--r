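# Within-individual and familial co-aggregation odds ratios: logistic
# models fit by IRLS (independence working correlation, so point estimates
# coincide with ordinary logistic ML) with cluster-robust sandwich
# covariance and Wald 95% confidence intervals.

#' Natural cubic spline basis
#'
#' Natural cubic spline with boundary knots at the data extremes and
#' interior knots at equally spaced quantiles; the represented function is
#' linear beyond the boundary knots. Used to adjust odds-ratio models for
#' birth year.
#'
#' @param x Numeric vector.
#' @param df Degrees of freedom (basis columns); default 5.
#' @return Object of class `spline_basis` with elements `basis` (matrix),
#'   `knots`, `boundary_knots`; use [predict_spline_basis()] to evaluate at
#'   new points.
#' @export
natural_spline_basis <- function(x, df = 5) {
  ux <- unique(x[is.finite(x)])
  if (length(ux) < df + 1)
    stop("need at least df + 1 distinct values for a ", df, "-df spline")
  b <- splines::ns(x, df = df)
  structure(list(basis = unclass(b)[, , drop = FALSE],
                 knots = attr(b, "knots"),
                 boundary_knots = attr(b, "Boundary.knots"),
                 ns = b),
            class = "spline_basis")
}

#' Evaluate a fitted spline basis at new points
#' @param object A `spline_basis`.
#' @param x New points.
#' @return Basis matrix with one column per df.
#' @export
predict_spline_basis <- function(object, x) {
  stopifnot(inherits(object, "spline_basis"))
  unclass(predict(object$ns, x))[, , drop = FALSE]
}

#' Logistic model with cluster-robust sandwich variance
#'
#' Fits a binary logistic regression by iteratively reweighted least
#' squares (equivalently, an estimating-equation fit with independence
#' working correlation, whose point estimates equal ordinary logistic ML)
#' and computes the sandwich covariance with scores summed within clusters.
#' Wald 95% confidence intervals on the odds-ratio scale use
#' `exp(beta +/- 1.96 * robust SE)`.
#'
#' @param outcome 0/1 vector.
#' @param design Numeric design matrix including the intercept column.
#' @param cluster Cluster identifiers (family components).
#' @param weights Optional frequency weights (counts of identical rows).
#' @param beta_cap Separation guard: an absolute coefficient beyond this
#'   value aborts with a separation error (default 15 on the log-odds
#'   scale).
#' @return Object of class `gee_fit`: `coefficients`, `vcov` (cluster
#'   robust), `or_table` (OR with Wald 95%CI per term), `n`, `n_clusters`,
#'   `converged`.
#' @export
fit_logistic_gee <- function(outcome, design, cluster,
                             weights = NULL, beta_cap = 15) {
  design <- as.matrix(design)
  stopifnot(length(outcome) == nrow(design),
            length(cluster) == nrow(design))
  if (is.null(weights)) weights <- rep(1, length(outcome))
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank deficient")
  if (is.null(colnames(design)) || any(!nzchar(colnames(design))))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  df <- data.frame(.y = outcome, .w = weights, design, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(design)),
                            response = ".y", intercept = FALSE)
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df, weights = .w,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- stats::setNames(stats::coef(fit), colnames(design))
  if (any(abs(beta) > beta_cap))
    stop("separation detected: |coefficient| exceeds ", beta_cap)
  # sandwich with scores summed within clusters (no small-sample factor):
  # bread from the IRLS information, meat from cluster score sums
  mu <- fit$fitted.values
  info <- crossprod(design * sqrt(weights * mu * (1 - mu)))
  bread <- solve(info)
  scores <- design * (weights * (outcome - mu))
  score_sums <- rowsum(scores, group = as.character(cluster))
  vc <- bread %*% crossprod(score_sums) %*% bread
  dimnames(vc) <- list(colnames(design), colnames(design))
  se <- sqrt(diag(vc))
  z <- qnorm(0.975)
  or_table <- data.frame(term = colnames(design), beta = beta,
                         robust_se = se, or = exp(beta),
                         ci_low = exp(beta - z * se),
                         ci_high = exp(beta + z * se),
                         row.names = NULL)
  structure(list(coefficients = beta, vcov = vc, or_table = or_table,
                 n = sum(weights), n_clusters = length(unique(cluster)),
                 converged = isTRUE(fit$converged), suppressed = FALSE),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  if (isTRUE(x$suppressed)) {
    cat("Suppressed estimate:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Logistic fit, %d observations in %d clusters%s\n", x$n,
              x$n_clusters, if (x$converged) "" else " (NOT converged)"))
  tab <- x$or_table
  tab[, -1] <- lapply(tab[, -1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

.suppressed_fit <- function(reason, n = 0L) {
  structure(list(coefficients = NULL, vcov = NULL, or_table = NULL,
                 n = n, n_clusters = 0L, converged = NA,
                 suppressed = TRUE, reason = reason),
            class = "gee_fit")
}

#' Within-individual odds ratio of an outcome given the exposure diagnosis
#'
#' Logistic model of the outcome indicator on the exposure indicator,
#' adjusted for sex and a 5-df natural cubic spline of birth year, with
#' family-cluster-robust Wald confidence intervals. Female-only outcomes
#' restrict the data to females and drop the sex covariate. The estimate is
#' suppressed (with a reason) when fewer than `min_informative` individuals
#' carry both diagnoses.
#'
#' @param data `data.frame` with columns `exposure` (0/1), `outcome`
#'   (0/1 or `NA`), `sex`, `birth_year`, `cluster`.
#' @param adjust Include sex and birth-year spline covariates.
#' @param female_only Restrict to females.
#' @param spline_df Birth-year spline degrees of freedom.
#' @param min_informative Suppression threshold (default 5).
#' @return A `gee_fit`; the exposure row of `or_table` carries the OR.
#' @export
within_individual_or <- function(data, adjust = TRUE, female_only = FALSE,
                                 spline_df = 5, min_informative = 5) {
  dt <- data.table::as.data.table(data)
  if (female_only) dt <- dt[sex == "female"]
  dt <- dt[!is.na(outcome) & !is.na(exposure)]
  if (sum(dt$exposure == 1 & dt$outcome == 1) < min_informative)
    return(.suppressed_fit(sprintf(
      "fewer than %d individuals with both diagnoses", min_informative),
      n = nrow(dt)))
  X <- cbind(intercept = 1, exposure = dt$exposure)
  if (adjust) {
    if (!female_only) X <- cbind(X, female = as.integer(dt$sex == "female"))
    sb <- natural_spline_basis(dt$birth_year, df = spline_df)
    colnames(sb$basis) <- paste0("byr_ns", seq_len(ncol(sb$basis)))
    X <- cbind(X, sb$basis)
  }
  fit_logistic_gee(dt$outcome, X, dt$cluster)
}

#' Familial co-aggregation odds ratio for one kinship type
#'
#' Outcome: relative B's phenotype; exposure: relative A's exposure
#' diagnosis, over (double-entered, for within-generation kinship) relative
#' pairs. Covariates: both members' sexes and 5-df birth-year splines
#' (only the exposure relative's sex for female-only phenotypes, whose
#' outcome side is restricted to females). Clusters are extended-family
#' components covering both members. Sparse cells (fewer than
#' `min_informative` pairs with both diagnoses) suppress the estimate,
#' matching the "too few observations to estimate" entries of
#' register-study figures.
#'
#' @param pair_data `data.frame` with columns `exposure_a`, `outcome_b`,
#'   `sex_a`, `sex_b`, `birth_year_a`, `birth_year_b`, `cluster`.
#' @param adjust,female_only,spline_df,min_informative See
#'   [within_individual_or()].
#' @return A `gee_fit`.
#' @export
familial_coaggregation_or <- function(pair_data, adjust = TRUE,
                                      female_only = FALSE, spline_df = 5,
                                      min_informative = 5) {
  dt <- data.table::as.data.table(pair_data)
  if (female_only) dt <- dt[sex_b == "female"]
  dt <- dt[!is.na(outcome_b) & !is.na(exposure_a)]
  if (nrow(dt) == 0 ||
      sum(dt$exposure_a == 1 & dt$outcome_b == 1) < min_informative)
    return(.suppressed_fit(sprintf(
      "fewer than %d informative pairs", min_informative), n = nrow(dt)))
  X <- cbind(intercept = 1, exposure = dt$exposure_a)
  if (adjust) {
    X <- cbind(X, female_a = as.integer(dt$sex_a == "female"))
    if (!female_only) X <- cbind(X, female_b = as.integer(dt$sex_b == "female"))
    for (side in c("a", "b")) {
      by <- dt[[paste0("birth_year_", side)]]
      if (length(unique(by)) >= spline_df + 1) {
        sb <- natural_spline_basis(by, df = spline_df)
        colnames(sb$basis) <- paste0("byr_", side, "_ns",
                                     seq_len(ncol(sb$basis)))
        X <- cbind(X, sb$basis)
      }
    }
  }
  fit_logistic_gee(dt$outcome_b, X, dt$cluster)
}

#' Descriptive table of the birth cohort by exposure status
#'
#' Counts and percentages in the style of register-study cohort tables:
#' total N, sex and birth-year strata with row percentages by exposure
#' status, and per-phenotype counts with column percentages within the
#' exposed and unexposed groups.
#'
#' @param cohort `data.frame` with `person_id`, `sex`, `birth_year` and a
#'   0/1 `exposure` column.
#' @param phenotypes Named list of 0/1 indicator vectors aligned with
#'   `cohort` rows (NA allowed, e.g. female-only phenotypes in males).
#' @param year_breaks Cut points for birth-year strata.
#' @return `data.table` with columns `block`, `label`, `n_total`,
#'   `n_unexposed`, `pct_unexposed`, `n_exposed`, `pct_exposed`.
#' @export
descriptive_table <- function(cohort, phenotypes = list(),
                              year_breaks = c(1973, 1978, 1983, 1988, 1993,
                                              1998, 2002)) {
  dt <- data.table::as.data.table(cohort)
  exp1 <- dt$exposure == 1
  pct <- function(num, den) ifelse(den > 0, round(100 * num / den, 1), 0)
  row_line <- function(block, label, sel) {
    n <- sum(sel); ne <- sum(sel & exp1)
    data.table::data.table(block = block, label = label, n_total = n,
                           n_unexposed = n - ne,
                           pct_unexposed = pct(n - ne, n),
                           n_exposed = ne, pct_exposed = pct(ne, n))
  }
  out <- list(row_line("total", "N", rep(TRUE, nrow(dt))))
  for (s in c("male", "female"))
    out[[length(out) + 1L]] <- row_line("sex", s, dt$sex == s)
  if (length(year_breaks) > 1) {
    yb <- cut(dt$birth_year, breaks = year_breaks, right = FALSE,
              labels = paste(head(year_breaks, -1),
                             pmin(year_breaks[-1] - 1, max(year_breaks)),
                             sep = "-"))
    for (lev in levels(yb))
      out[[length(out) + 1L]] <- row_line("birth_year", lev,
                                          !is.na(yb) & yb == lev)
  }
  n_unexp <- sum(!exp1); n_exp <- sum(exp1)
  for (nm in names(phenotypes)) {
    y <- phenotypes[[nm]]
    n1e <- sum(y == 1 & exp1, na.rm = TRUE)
    n1u <- sum(y == 1 & !exp1, na.rm = TRUE)
    out[[length(out) + 1L]] <- data.table::data.table(
      block = "phenotype", label = nm, n_total = n1e + n1u,
      n_unexposed = n1u, pct_unexposed = pct(n1u, n_unexp),
      n_exposed = n1e, pct_exposed = pct(n1e, n_exp))
  }
  data.table::rbindlist(out)
}
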