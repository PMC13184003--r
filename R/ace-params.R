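#' Liability variance components for one trait
#'
#' Bundles the standardized variance shares of a single-trait liability ACE
#' decomposition: additive genetic (A), common/shared environmental (C) and
#' unique environmental (E) components. Shares must be non-negative and sum
#' to one, so the latent liability has unit variance.
#'
#' @param a2 Additive genetic variance share, in \[0, 1\].
#' @param c2 Common environmental variance share, in \[0, 1\].
#' @param e2 Unique environmental variance share, in \[0, 1\]. Defaults to
#'   `1 - a2 - c2`.
#' @return An object of class `ace_params` with fields `a2`, `c2`, `e2`.
#' @examples
#' ace_params(0.5, 0.05)
#' @export
ace_params <- function(a2, c2, e2 = 1 - a2 - c2) {
  stopifnot(is.numeric(a2), is.numeric(c2), is.numeric(e2),
            length(a2) == 1L, length(c2) == 1L, length(e2) == 1L)
  if (min(a2, c2, e2) < -1e-12)
    stop("ACE variance shares must be non-negative")
  if (abs(a2 + c2 + e2 - 1) > 1e-12)
    stop("ACE variance shares must sum to 1 (got ", a2 + c2 + e2, ")")
  structure(list(a2 = a2, c2 = c2, e2 = e2), class = "ace_params")
}

#' @export
print.ace_params <- function(x, ...) {
  cat(sprintf("ACE liability shares: a2 = %.4g, c2 = %.4g, e2 = %.4g\n",
              x$a2, x$c2, x$e2))
  invisible(x)
}

#' Bivariate correlated-factors ACE parameters
#'
#' Two single-trait ACE decompositions plus the correlations between their
#' latent factors: `rA` between additive-genetic factors (the genetic
#' correlation), `rC` between common-environment factors, `rE` between
#' unique-environment factors. The implied within-person cross-trait
#' (phenotypic) correlation is
#' `r_ph = a1*a2*rA + c1*c2*rC + e1*e2*rE` with `a_t = sqrt(a2_t)` etc.
#'
#' @param trait1,trait2 [ace_params] objects for the two traits.
#' @param rA,rC,rE Factor correlations in \[-1, 1\].
#' @return An object of class `biv_ace_params`.
#' @examples
#' biv_ace_params(ace_params(0.5, 0.1), ace_params(0.5, 0.1),
#'                rA = 0.8, rC = 0.5, rE = 0.25)
#' @export
biv_ace_params <- function(trait1, trait2, rA, rC, rE) {
  stopifnot(inherits(trait1, "ace_params"), inherits(trait2, "ace_params"))
  for (r in c(rA, rC, rE))
    if (!is.finite(r) || abs(r) > 1)
      stop("factor correlations must lie in [-1, 1]")
  p <- structure(list(trait1 = trait1, trait2 = trait2,
                      rA = rA, rC = rC, rE = rE),
                 class = "biv_ace_params")
  rph <- phenotypic_correlation(p)
  if (abs(rph) > 1 + 1e-12)
    stop("implied within-person cross-trait correlation ", signif(rph, 4),
         " falls outside [-1, 1]")
  p
}

#' @export
print.biv_ace_params <- function(x, ...) {
  cat("Bivariate ACE parameters (correlated factors)\n")
  cat(sprintf("  trait1: a2 = %.3g, c2 = %.3g, e2 = %.3g\n",
              x$trait1$a2, x$trait1$c2, x$trait1$e2))
  cat(sprintf("  trait2: a2 = %.3g, c2 = %.3g, e2 = %.3g\n",
              x$trait2$a2, x$trait2$c2, x$trait2$e2))
  cat(sprintf("  rA = %.3g, rC = %.3g, rE = %.3g, implied r_ph = %.4g\n",
              x$rA, x$rC, x$rE, phenotypic_correlation(x)))
  invisible(x)
}

#' Implied within-person cross-trait correlation
#'
#' @param params A [biv_ace_params] object.
#' @return The phenotypic correlation `a1*a2*rA + c1*c2*rC + e1*e2*rE`.
#' @export
phenotypic_correlation <- function(params) {
  stopifnot(inherits(params, "biv_ace_params"))
  t1 <- params$trait1; t2 <- params$trait2
  sqrt(t1$a2 * t2$a2) * params$rA +
    sqrt(t1$c2 * t2$c2) * params$rC +
    sqrt(t1$e2 * t2$e2) * params$rE
}

#' Kinship sharing coefficients
#'
#' For each supported kinship type, `alpha` is the expected shared fraction
#' of additive-genetic variance and `gamma` the shared fraction of
#' common-environment variance. Full siblings share on average half their
#' additive-genetic variance; maternal and paternal half-siblings a quarter;
#' first cousins an eighth. The common environment is modelled as fully
#' shared by siblings raised by the same mother (MZ/DZ twins, full siblings,
#' maternal half-siblings) and not shared by paternal half-siblings.
#'
#' @param kinship Character vector of kinship types; one of `"MZ_twin"`,
#'   `"DZ_twin"`, `"full_sib"`, `"maternal_half_sib"`, `"paternal_half_sib"`,
#'   `"parent_child"`, `"aunt_uncle"`, `"cousin"`.
#' @return A `data.frame` with columns `kinship`, `alpha`, `gamma`.
#' @examples
#' kinship_coefficients(c("full_sib", "paternal_half_sib"))
#' @export
kinship_coefficients <- function(kinship = names(.kinship_table)) {
  kinship <- match.arg(kinship, names(.kinship_table), several.ok = TRUE)
  out <- do.call(rbind, lapply(.kinship_table[kinship], function(x)
    data.frame(alpha = x[1], gamma = x[2])))
  data.frame(kinship = kinship, out, row.names = NULL,
             stringsAsFactors = FALSE)
}

.kinship_table <- list(
  MZ_twin           = c(1,     1),
  DZ_twin           = c(0.5,   1),
  full_sib          = c(0.5,   1),
  maternal_half_sib = c(0.25,  1),
  paternal_half_sib = c(0.25,  0),
  parent_child      = c(0.5,   0),
  aunt_uncle        = c(0.25,  0),
  cousin            = c(0.125, 0)
)

#' Expected cross-relative same-trait liability correlation
#'
#' Under the liability ACE model the correlation between the same trait's
#' liabilities in a relative pair with sharing coefficients `(alpha, gamma)`
#' is `alpha * a2 + gamma * c2`.
#'
#' @param a2,c2 Variance shares for the trait.
#' @param kinship Kinship type (see [kinship_coefficients()]) or a list/row
#'   with `alpha` and `gamma` entries.
#' @return Expected pair correlation.
#' @examples
#' expected_pair_correlation(0.4, 0.2, "full_sib")          # 0.40
#' expected_pair_correlation(0.4, 0.2, "paternal_half_sib") # 0.10
#' @export
expected_pair_correlation <- function(a2, c2, kinship) {
  k <- .resolve_kinship(kinship)
  k$alpha * a2 + k$gamma * c2
}

#' Expected cross-trait liability correlations
#'
#' For a bivariate correlated-factors ACE model, returns the implied
#' cross-trait correlation. Within one person (`kinship = "self"`) all three
#' pathways contribute: `a1*a2*rA + c1*c2*rC + e1*e2*rE`. Across a relative
#' pair only the familial pathways do: `alpha*a1*a2*rA + gamma*c1*c2*rC`.
#'
#' @param params A [biv_ace_params] object.
#' @param kinship `"self"` for the within-person correlation, otherwise a
#'   kinship type or a list with `alpha`/`gamma`.
#' @return Implied correlation.
#' @examples
#' p <- biv_ace_params(ace_params(0.5, 0.1), ace_params(0.5, 0.1),
#'                     rA = 0.8, rC = 0.5, rE = 0.25)
#' expected_cross_trait_correlation(p, "self")      # 0.55
#' expected_cross_trait_correlation(p, "full_sib")  # 0.25
#' @export
expected_cross_trait_correlation <- function(params, kinship = "self") {
  stopifnot(inherits(params, "biv_ace_params"))
  if (identical(kinship, "self")) return(phenotypic_correlation(params))
  k <- .resolve_kinship(kinship)
  t1 <- params$trait1; t2 <- params$trait2
  k$alpha * sqrt(t1$a2 * t2$a2) * params$rA +
    k$gamma * sqrt(t1$c2 * t2$c2) * params$rC
}

.resolve_kinship <- function(kinship) {
  if (is.character(kinship)) {
    k <- kinship_coefficients(kinship)
    list(alpha = k$alpha, gamma = k$gamma)
  } else if (!is.null(kinship$alpha) && !is.null(kinship$gamma)) {
    kinship
  } else stop("kinship must be a type name or carry alpha/gamma")
}

#' Noiseless correlation structure implied by bivariate ACE parameters
#'
#' Computes, for each kinship group, the four latent correlations the
#' bivariate model constrains: the within-person cross-trait correlation,
#' the two cross-person same-trait correlations, and the cross-person
#' cross-trait correlation. Used as the exact-inversion oracle for the WLS
#' fitter and as the target structure the simulator must reproduce.
#'
#' @param params A [biv_ace_params] object.
#' @param kinships Character vector of kinship types.
#' @param var Asymptotic variance attached to every entry (weights for
#'   fitting; the default gives equal unit weights).
#' @return A `data.frame` of class `pair_structure` with columns `kinship`,
#'   `alpha`, `gamma`, `moment` (one of `within_cross`, `same_trait1`,
#'   `same_trait2`, `cross_cross`), `r`, `var`.
#' @export
implied_pair_structure <- function(params,
                                   kinships = c("full_sib",
                                                "maternal_half_sib",
                                                "paternal_half_sib"),
                                   var = 1) {
  stopifnot(inherits(params, "biv_ace_params"))
  rows <- lapply(kinships, function(kn) {
    k <- .resolve_kinship(kn)
    data.frame(
      kinship = kn, alpha = k$alpha, gamma = k$gamma,
      moment = c("within_cross", "same_trait1", "same_trait2", "cross_cross"),
      r = c(phenotypic_correlation(params),
            expected_pair_correlation(params$trait1$a2, params$trait1$c2, kn),
            expected_pair_correlation(params$trait2$a2, params$trait2$c2, kn),
            expected_cross_trait_correlation(params, kn)),
      var = var, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pair_structure", "data.frame")
  out
}
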