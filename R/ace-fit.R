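# Univariate and bivariate liability ACE models fitted by weighted least
# squares over the kinship-group correlation structure (correlated factors
# parameterization), with delta-method Wald confidence intervals.

.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# WLS sandwich (J' W J)^-1 J' W S W J (J' W J)^-1; S may be a full moment
# covariance matrix or a vector of variances (diagonal S)
.wls_vcov <- function(J, w, S) {
  JtWJ <- crossprod(J, J * w)
  bread <- .pinv(JtWJ)
  meat <- if (is.matrix(S)) crossprod(J * w, S %*% (J * w))
  else crossprod(J * w, (J * w) * S)
  bread %*% meat %*% bread
}

#' Univariate ACE fit from kinship-group correlations
#'
#' Solves the weighted least-squares problem
#' `min sum_g w_g (r_g - alpha_g a2 - gamma_g c2)^2` over the same-trait
#' sibling correlations of at least two kinship groups with distinct
#' sharing coefficients. The fit is unconstrained, so `a2` or `c2` may be
#' negative; `e2 = 1 - a2 - c2` by construction. Weights default to inverse
#' asymptotic variances.
#'
#' @param r Observed same-trait correlations per kinship group.
#' @param alpha,gamma Sharing coefficients per group (or pass `kinship`).
#' @param var Asymptotic variances of `r` (default 1: equal weights).
#' @param kinship Optional kinship names resolving `alpha`/`gamma`.
#' @return Object of class `ace_uni_fit`: estimates, SEs, 95% CIs,
#'   objective.
#' @examples
#' fit_univariate_ace(c(0.30, 0.175, 0.125),
#'                    kinship = c("full_sib", "maternal_half_sib",
#'                                "paternal_half_sib"))
#' @export
fit_univariate_ace <- function(r, alpha = NULL, gamma = NULL, var = 1,
                               kinship = NULL) {
  if (!is.null(kinship)) {
    kc <- kinship_coefficients()
    idx <- match(kinship, kc$kinship)
    alpha <- kc$alpha[idx]; gamma <- kc$gamma[idx]
  }
  stopifnot(length(alpha) == length(r), length(gamma) == length(r))
  var <- rep_len(var, length(r))
  keep <- is.finite(r) & is.finite(var) & var > 0
  r <- r[keep]; alpha <- alpha[keep]; gamma <- gamma[keep]
  var <- var[keep]
  X <- cbind(a2 = alpha, c2 = gamma)
  if (qr(X)$rank < 2)
    stop("kinship groups share identical (alpha, gamma): a2 and c2 are not identifiable")
  w <- 1 / var
  XtWX <- crossprod(X, X * w)
  beta <- drop(solve(XtWX, crossprod(X, r * w)))
  resid <- r - drop(X %*% beta)
  vc <- .wls_vcov(X, w, var)
  se <- sqrt(pmax(diag(vc), 0))
  # e2 = 1 - a2 - c2: delta method with gradient (-1, -1)
  se_e2 <- sqrt(max(sum(vc), 0))
  z <- qnorm(0.975)
  est <- c(beta, e2 = 1 - sum(beta))
  ses <- c(se, e2 = se_e2)
  structure(list(a2 = est[["a2"]], c2 = est[["c2"]], e2 = est[["e2"]],
                 se = ses,
                 ci = cbind(low = est - z * ses, high = est + z * ses),
                 objective = sum(w * resid^2),
                 groups = data.frame(alpha = alpha, gamma = gamma, r = r,
                                     var = var, residual = resid),
                 vcov = vc),
            class = "ace_uni_fit")
}

#' @export
print.ace_uni_fit <- function(x, ...) {
  cat("Univariate ACE (WLS over kinship-group correlations)\n")
  est <- c(a2 = x$a2, c2 = x$c2, e2 = x$e2)
  for (i in 1:3)
    cat(sprintf("  %s = %7.4f (SE %.4f, 95%%CI %.4f to %.4f)\n",
                names(est)[i], est[i], x$se[i], x$ci[i, 1], x$ci[i, 2]))
  cat(sprintf("  objective = %.3g over %d groups\n", x$objective,
              nrow(x$groups)))
  invisible(x)
}

# moment vector implied by theta for the rows of a pair_structure table
.biv_implied <- function(theta, struct, fix_c) {
  if (fix_c) {
    a1 <- theta[1]; c1 <- 0; a2 <- theta[2]; c2 <- 0
    rA <- theta[3]; rC <- 0; rE <- theta[4]
  } else {
    a1 <- theta[1]; c1 <- theta[2]; a2 <- theta[3]; c2 <- theta[4]
    rA <- theta[5]; rC <- theta[6]; rE <- theta[7]
  }
  s1 <- a1^2 + c1^2; s2 <- a2^2 + c2^2
  e1 <- sqrt(max(1 - s1, 0)); e2 <- sqrt(max(1 - s2, 0))
  imp <- numeric(nrow(struct))
  m <- struct$moment
  imp[m == "within_cross"] <- a1 * a2 * rA + c1 * c2 * rC + e1 * e2 * rE
  i <- m == "same_trait1"
  imp[i] <- struct$alpha[i] * a1^2 + struct$gamma[i] * c1^2
  i <- m == "same_trait2"
  imp[i] <- struct$alpha[i] * a2^2 + struct$gamma[i] * c2^2
  i <- m == "cross_cross"
  imp[i] <- struct$alpha[i] * a1 * a2 * rA + struct$gamma[i] * c1 * c2 * rC
  pen <- 0
  if (s1 > 1) pen <- pen + 1e4 * (s1 - 1)^2
  if (s2 > 1) pen <- pen + 1e4 * (s2 - 1)^2
  attr(imp, "penalty") <- pen
  imp
}

.biv_starts <- function(fix_c) {
  g <- expand.grid(a = c(0.35, 0.7), rA = c(-0.5, 0.5),
                   x3 = c(0.15, 0.45))
  starts <- lapply(seq_len(nrow(g)), function(i) {
    if (fix_c)
      c(g$a[i], g$a[i], g$rA[i], sign(g$rA[i]) * g$x3[i] / 2)
    else
      c(g$a[i], g$x3[i], g$a[i], g$x3[i], g$rA[i], g$rA[i] / 2,
        g$rA[i] / 4)
  })
  starts
}

#' Bivariate ACE fit (correlated factors, weighted least squares)
#'
#' Minimizes the inverse-variance weighted squared discrepancy between the
#' observed kinship-group correlation structure and the model-implied
#' correlations over `theta = (a1, c1, a2, c2, rA, rC, rE)` with loadings
#' constrained non-negative, factor correlations in \[-1, 1\] and
#' `e_t = sqrt(1 - a_t^2 - c_t^2)` (unit liability variance). A bounded
#' quasi-Newton search is run from 8 deterministic starts and the best
#' objective kept. With `fix_c = TRUE` the common-environment loadings are
#' fixed at 0 and `rC` is dropped (the refit used when the free model fails
#' to optimize and the univariate fits put C at zero); that retry happens
#' automatically when `univariate_c2` values are supplied and both are
#' non-positive.
#'
#' @param structure A `pair_structure` table ([pair_polychoric_structure()]
#'   or [implied_pair_structure()]): columns `kinship`, `alpha`, `gamma`,
#'   `moment`, `r`, `var`.
#' @param fix_c Fix the C pathway to zero.
#' @param univariate_c2 Optional length-2 vector of unconstrained
#'   univariate `c2` estimates; enables the automatic `fix_c` retry.
#' @param conf_level Confidence level for Wald intervals.
#' @return Object of class `ace_biv_fit`: loadings and factor correlations
#'   with SEs and untruncated Wald CIs, derived `r_ph`, `bivA`, `bivC`,
#'   `bivE`, convergence diagnostics and the multi-start record.
#' @export
fit_bivariate_ace <- function(structure, fix_c = FALSE,
                              univariate_c2 = NULL, conf_level = 0.95) {
  moment_cov <- attr(structure, "moment_cov")
  struct <- data.table::as.data.table(structure)
  if (!"row_id" %in% names(struct))
    struct[, row_id := paste(kinship, moment, seq_len(.N), sep = ".")]
  struct <- struct[is.finite(r) & is.finite(var) & var > 0]
  if (!nrow(struct)) stop("no usable correlation entries in structure")
  Sigma <- if (!is.null(moment_cov) &&
               all(struct$row_id %in% rownames(moment_cov)))
    moment_cov[struct$row_id, struct$row_id, drop = FALSE]
  else diag(struct$var, nrow(struct))
  w <- 1 / struct$var
  obj <- function(theta, fc) {
    imp <- .biv_implied(theta, struct, fc)
    sum(w * (struct$r - imp)^2) + attr(imp, "penalty")
  }
  run <- function(fc) {
    lower <- if (fc) c(0, 0, -1, -1) else c(0, 0, 0, 0, -1, -1, -1)
    upper <- if (fc) c(1, 1, 1, 1) else rep(1, 7)
    fits <- lapply(.biv_starts(fc), function(s) {
      tryCatch(stats::optim(s, obj, fc = fc, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500)),
               error = function(e) list(value = Inf, convergence = 99L))
    })
    vals <- vapply(fits, `[[`, 0, "value")
    best <- fits[[which.min(vals)]]
    best$all_values <- vals
    # damped Gauss-Newton polish: quadratic convergence near the optimum;
    # the projected step norm at exit is the stationarity diagnostic
    th <- best$par
    f_obj <- obj(th, fc)
    moved <- Inf
    for (it in 1:50) {
      Jp <- .num_jacobian(function(p)
        as.numeric(.biv_implied(p, struct, fc)), th)
      resid <- struct$r - as.numeric(.biv_implied(th, struct, fc))
      step <- drop(.pinv(crossprod(Jp, Jp * w)) %*% crossprod(Jp, w * resid))
      lam <- 1
      repeat {
        cand <- pmin(pmax(th + lam * step, lower), upper)
        f_new <- obj(cand, fc)
        if (f_new <= f_obj || lam < 1e-6) break
        lam <- lam / 2
      }
      if (f_new > f_obj) { moved <- 0; break }
      moved <- max(abs(cand - th))
      th <- cand; f_obj <- f_new
      if (moved < 1e-13) break
    }
    if (f_obj <= best$value) { best$par <- th; best$value <- f_obj }
    best$stationary <- moved < 1e-6
    best
  }
  used_fix_c <- fix_c
  best <- run(fix_c)
  free_failed <- !is.finite(best$value) ||
    !(best$convergence == 0 || isTRUE(best$stationary))
  if (!fix_c && free_failed &&
      !is.null(univariate_c2) && all(univariate_c2 <= 0)) {
    used_fix_c <- TRUE
    best <- run(TRUE)
  }
  converged <- is.finite(best$value) &&
    (best$convergence == 0 || isTRUE(best$stationary))
  th <- best$par
  if (used_fix_c) {
    theta <- c(a1 = th[1], c1 = 0, a2 = th[2], c2 = 0,
               rA = th[3], rC = NA_real_, rE = th[4])
    free <- c("a1", "a2", "rA", "rE")
  } else {
    theta <- c(a1 = th[1], c1 = th[2], a2 = th[3], c2 = th[4],
               rA = th[5], rC = th[6], rE = th[7])
    free <- c("a1", "c1", "a2", "c2", "rA", "rC", "rE")
  }
  # parameter covariance: WLS sandwich at the optimum
  J <- .num_jacobian(function(p) as.numeric(.biv_implied(p, struct,
                                                         used_fix_c)),
                     best$par)
  vc_free <- .wls_vcov(J, w, Sigma)
  dimnames(vc_free) <- list(free, free)
  fit <- structure(list(theta = theta, fixed_c = used_fix_c,
                        vcov = vc_free, free = free,
                        objective = best$value, converged = converged,
                        multistart_objectives = best$all_values,
                        structure = struct, conf_level = conf_level),
                   class = "ace_biv_fit")
  fit$derived <- .biv_derived(fit)
  fit
}

.num_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# derived quantities (r_ph, bivA/bivC/bivE, variance shares) + delta CIs
.biv_derived <- function(fit) {
  th <- fit$theta
  fc <- fit$fixed_c
  dfun <- function(p) {
    if (fc) {
      a1 <- p[1]; c1 <- 0; a2 <- p[2]; c2 <- 0
      rA <- p[3]; rC <- 0; rE <- p[4]
    } else {
      a1 <- p[1]; c1 <- p[2]; a2 <- p[3]; c2 <- p[4]
      rA <- p[5]; rC <- p[6]; rE <- p[7]
    }
    a1 <- unname(a1); c1 <- unname(c1); a2 <- unname(a2); c2 <- unname(c2)
    rA <- unname(rA); rC <- unname(rC); rE <- unname(rE)
    e1 <- sqrt(max(1 - a1^2 - c1^2, 0)); e2 <- sqrt(max(1 - a2^2 - c2^2, 0))
    pA <- a1 * a2 * rA; pC <- c1 * c2 * rC; pE <- e1 * e2 * rE
    rph <- pA + pC + pE
    c(r_ph = rph,
      bivA = if (rph != 0) pA / rph else NA_real_,
      bivC = if (rph != 0) pC / rph else NA_real_,
      bivE = if (rph != 0) pE / rph else NA_real_,
      a2_1 = a1^2, c2_1 = c1^2, e2_1 = e1^2,
      a2_2 = a2^2, c2_2 = c2^2, e2_2 = e2^2,
      rA = rA, rC = rC, rE = rE)
  }
  p0 <- th[fit$free]
  vals <- dfun(p0)
  G <- .num_jacobian(dfun, p0)
  ses <- sqrt(pmax(diag(G %*% fit$vcov %*% t(G)), 0))
  z <- qnorm(1 - (1 - fit$conf_level) / 2)
  out <- data.frame(quantity = names(vals), estimate = unname(vals),
                    se = unname(ses),
                    ci_low = unname(vals - z * ses),
                    ci_high = unname(vals + z * ses))
  if (fc) out[out$quantity %in% c("bivC", "rC"), c("se", "ci_low",
                                                   "ci_high")] <- NA
  out
}

#' @export
print.ace_biv_fit <- function(x, ...) {
  cat(sprintf(
    "Bivariate ACE fit (correlated factors, WLS)%s%s\n",
    if (x$fixed_c) ", C fixed to 0" else "",
    if (x$converged) "" else " [NOT converged]"))
  cat(sprintf("  objective = %.4g\n", x$objective))
  d <- x$derived
  d[, -1] <- lapply(d[, -1], signif, 4)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Decompose the phenotypic correlation into ACE contributions
#'
#' `bivA = a1*a2*rA / r_ph`, `bivC = c1*c2*rC / r_ph`,
#' `bivE = e1*e2*rE / r_ph`; the proportions sum to 1 and individual terms
#' may be negative (a pathway working against the net correlation).
#'
#' @param fit An `ace_biv_fit`.
#' @return Named vector `(bivA, bivC, bivE)`.
#' @export
decompose_phenotypic_correlation <- function(fit) {
  stopifnot(inherits(fit, "ace_biv_fit"))
  d <- fit$derived
  rph <- d$estimate[d$quantity == "r_ph"]
  if (!is.finite(rph) || rph == 0)
    stop("phenotypic correlation is zero: bivariate proportions undefined")
  out <- d$estimate[match(c("bivA", "bivC", "bivE"), d$quantity)]
  names(out) <- c("bivA", "bivC", "bivE")
  if (fit$fixed_c) out["bivC"] <- 0
  out
}

#' Screening rule for bivariate modeling
#'
#' A phenotype enters bivariate ACE modeling only with some evidence of
#' within-individual association with the exposure (tetrachoric correlation
#' at least `min_rho`) and enough informative sibling pairs (at least
#' `min_pairs` concordant and `min_pairs` discordant pairs, boundaries
#' inclusive).
#'
#' @param within_rho Within-individual tetrachoric correlation.
#' @param n_concordant,n_discordant Pooled sibling-pair counts for the
#'   phenotype.
#' @param min_rho,min_pairs Rule thresholds (defaults 0.1 and 5).
#' @return List with `include` (logical) and `reasons` (character vector of
#'   reason codes, empty when included).
#' @export
screen_phenotypes <- function(within_rho, n_concordant, n_discordant,
                              min_rho = 0.1, min_pairs = 5) {
  reasons <- character()
  if (!is.finite(within_rho) || within_rho < min_rho)
    reasons <- c(reasons, "within_individual_correlation_below_threshold")
  if (!is.finite(n_concordant) || n_concordant < min_pairs)
    reasons <- c(reasons, "too_few_concordant_pairs")
  if (!is.finite(n_discordant) || n_discordant < min_pairs)
    reasons <- c(reasons, "too_few_discordant_pairs")
  list(include = length(reasons) == 0L, reasons = reasons)
}
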