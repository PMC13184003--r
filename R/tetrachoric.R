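# Thresholds and tetrachoric correlations for binary liability traits.
#
# Two-step estimation: diagnosis thresholds come from a marginal probit
# model (person-specific when covariates are supplied), then the latent
# correlation is profiled out of the bivariate-normal cell likelihood with
# thresholds held fixed. Keeping the binary likelihood exact makes the
# covariate adjustment enter through thresholds rather than residuals.

#' Probit threshold model for a binary trait
#'
#' Estimates the liability-scale diagnosis threshold, optionally as a
#' linear function of covariates (sex, birth-year spline). Under the
#' liability model `P(y = 1 | x) = Phi(eta(x))`, the person-specific
#' threshold is `tau(x) = -eta(x)`; with no covariates
#' `tau = qnorm(1 - prevalence)`.
#'
#' @param outcome 0/1 vector.
#' @param covariates Optional numeric matrix (no intercept column needed).
#' @return Object of class `threshold_model` with `coefficients`,
#'   `thresholds` (fitted per-person thresholds) and `vcov`.
#' @export
estimate_thresholds <- function(outcome, covariates = NULL) {
  outcome <- as.integer(outcome)
  keep <- !is.na(outcome)
  if (all(outcome[keep] == 1L) || all(outcome[keep] == 0L))
    stop("degenerate outcome: all observations are ",
         outcome[which(keep)[1]])
  if (is.null(covariates)) {
    X <- matrix(1, sum(keep), 1, dimnames = list(NULL, "intercept"))
  } else {
    covariates <- as.matrix(covariates)
    X <- cbind(intercept = 1, covariates[keep, , drop = FALSE])
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, outcome[keep],
                   family = stats::binomial(link = "probit")))
  eta <- drop(X %*% fit$coefficients)
  tau <- rep(NA_real_, length(outcome))
  tau[keep] <- -eta
  structure(list(coefficients = fit$coefficients,
                 thresholds = tau,
                 converged = isTRUE(fit$converged),
                 n = sum(keep)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("Probit threshold model, n =", x$n, "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

.tetra_loglik_table <- function(rho, counts, tau1, tau2) {
  p <- bvn_cell_probabilities(tau1, tau2, rho)
  sum(counts * log(pmax(p, 1e-300)))
}

.tetra_se <- function(loglik, rho, h = 1e-4) {
  r <- min(max(rho, -1 + 2 * h), 1 - 2 * h)
  d2 <- (loglik(r + h) - 2 * loglik(r) + loglik(r - h)) / h^2
  if (!is.finite(d2) || d2 >= 0) return(NA_real_)
  1 / sqrt(-d2)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' underlying a 2x2 table of binary outcomes, with thresholds either fixed
#' (e.g. from a covariate-adjusted probit model) or profiled from the table
#' margins. The asymptotic standard error comes from the observed
#' information in the profiled likelihood.
#'
#' @param counts Length-4 vector `(n11, n10, n01, n00)` (1 = affected) or a
#'   2x2 matrix with the affected row/column first.
#' @param tau Optional fixed thresholds `c(tau1, tau2)`; when `NULL` they
#'   are profiled from the margins.
#' @return Object of class `tetrachoric` with `rho`, `tau1`, `tau2`, `se`,
#'   `var`, `n`, `boundary` and the cell `counts`.
#' @export
tetrachoric_from_table <- function(counts, tau = NULL) {
  if (is.matrix(counts)) counts <- c(counts[1, 1], counts[1, 2],
                                     counts[2, 1], counts[2, 2])
  stopifnot(length(counts) == 4, all(counts >= 0))
  names(counts) <- c("n11", "n10", "n01", "n00")
  n <- sum(counts)
  if (n < 1) stop("empty table")
  m1 <- counts[1] + counts[2]  # trait 1 affected
  m2 <- counts[1] + counts[3]  # trait 2 affected
  if (m1 == 0 || m1 == n || m2 == 0 || m2 == n)
    stop("degenerate margin: a trait is constant")
  if (is.null(tau)) tau <- c(qnorm(1 - m1 / n), qnorm(1 - m2 / n))
  ll <- function(rho) .tetra_loglik_table(rho, counts, tau[1], tau[2])
  eps <- 1e-7
  opt <- stats::optimize(ll, c(-1 + eps, 1 - eps), maximum = TRUE,
                         tol = 1e-9)
  rho <- opt$maximum
  boundary <- abs(rho) >= 1 - 1e-6
  # optimize() cannot land exactly on the boundary; snap when the edge wins
  if (!boundary) {
    if (counts[2] == 0 && counts[3] == 0) { rho <- 1; boundary <- TRUE }
    if (counts[1] == 0 && counts[4] == 0) { rho <- -1; boundary <- TRUE }
  }
  se <- if (boundary) NA_real_ else .tetra_se(ll, rho)
  structure(list(rho = unname(rho), tau1 = unname(tau[1]),
                 tau2 = unname(tau[2]), se = se, var = se^2, n = n,
                 boundary = boundary, counts = counts,
                 loglik = unname(opt$objective)),
            class = "tetrachoric")
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf(
    "Tetrachoric correlation: rho = %.4f (SE %.4f), tau = (%.3f, %.3f), n = %d%s\n",
    x$rho, x$se, x$tau1, x$tau2, x$n,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Tetrachoric correlation with observation-specific thresholds
#'
#' Profile ML over the latent correlation when each observation pair
#' carries its own thresholds (covariate-adjusted probit linear
#' predictors). With constant thresholds this reduces to
#' [tetrachoric_from_table()], which is used automatically for speed.
#'
#' @param y1,y2 0/1 vectors.
#' @param tau1,tau2 Threshold vectors (recycled).
#' @return A `tetrachoric` object.
#' @export
tetrachoric_pairs <- function(y1, y2, tau1, tau2) {
  keep <- !is.na(y1) & !is.na(y2)
  y1 <- y1[keep]; y2 <- y2[keep]
  n <- length(y1)
  if (n < 1) stop("no complete pairs")
  tau1 <- rep_len(tau1, length(keep))[keep]
  tau2 <- rep_len(tau2, length(keep))[keep]
  counts <- c(n11 = sum(y1 & y2), n10 = sum(y1 & !y2),
              n01 = sum(!y1 & y2), n00 = sum(!y1 & !y2))
  if (length(unique(tau1)) == 1L && length(unique(tau2)) == 1L)
    return(tetrachoric_from_table(counts, tau = c(tau1[1], tau2[1])))
  if (all(y1 == y1[1]) || all(y2 == y2[1]))
    stop("degenerate margin: a trait is constant")
  idx <- cbind(seq_len(n),
               ifelse(y1 == 1 & y2 == 1, 1L,
                      ifelse(y1 == 1, 2L, ifelse(y2 == 1, 3L, 4L))))
  ll <- function(rho) {
    p <- bvn_cell_probabilities(tau1, tau2, rho)
    sum(log(pmax(p[idx], 1e-300)))
  }
  eps <- 1e-7
  opt <- stats::optimize(ll, c(-1 + eps, 1 - eps), maximum = TRUE,
                         tol = 1e-8)
  rho <- opt$maximum
  boundary <- abs(rho) >= 1 - 1e-6
  se <- if (boundary) NA_real_ else .tetra_se(ll, rho)
  structure(list(rho = unname(rho), tau1 = mean(tau1), tau2 = mean(tau2),
                 se = se, var = se^2, n = n, boundary = boundary,
                 counts = counts, loglik = unname(opt$objective)),
            class = "tetrachoric")
}

# per-observation influence values of the tetrachoric ML estimate
# (score over total observed information); used to assemble the covariance
# between moment estimates that share pairs
.tetra_influence <- function(y1, y2, tau1, tau2, rho, h = 1e-5) {
  n <- length(y1)
  tau1 <- rep_len(tau1, n); tau2 <- rep_len(tau2, n)
  idx <- cbind(seq_len(n),
               ifelse(y1 == 1 & y2 == 1, 1L,
                      ifelse(y1 == 1, 2L, ifelse(y2 == 1, 3L, 4L))))
  lp <- function(r) {
    p <- bvn_cell_probabilities(tau1, tau2, r)
    log(pmax(p[idx], 1e-300))
  }
  r <- min(max(rho, -1 + 2 * h), 1 - 2 * h)
  lp_p <- lp(r + h); lp_m <- lp(r - h); lp_0 <- lp(r)
  score <- (lp_p - lp_m) / (2 * h)
  info <- -sum((lp_p - 2 * lp_0 + lp_m) / h^2)
  if (!is.finite(info) || info <= 0) return(rep(NA_real_, n))
  score / info
}

#' Latent correlation structure of selected sibling pairs
#'
#' For each kinship group, estimates the four latent correlations the
#' bivariate ACE model constrains: the within-person cross-trait
#' correlation (members of the group's pairs, both positions pooled), the
#' two cross-person same-trait correlations, and the cross-person
#' cross-trait correlation (the two symmetric orientations estimated
#' separately and averaged). Thresholds are held fixed at the
#' covariate-adjusted probit values supplied per person.
#'
#' @param pair_data `data.frame` with one row per selected pair: `kinship`,
#'   binary indicators `y1_a`, `y2_a`, `y1_b`, `y2_b`, and thresholds
#'   `tau1_a`, `tau2_a`, `tau1_b`, `tau2_b`.
#' @param min_cell Insufficient-data signal: a required estimate whose
#'   concordant or discordant pair count falls below this is returned with
#'   `NA` correlation (consumed by the screening rule).
#' @return `data.table` of class `pair_structure` with columns `kinship`,
#'   `alpha`, `gamma`, `moment`, `r`, `var`, `se`, `n`, `boundary`, plus
#'   attribute `"pair_counts"` (concordant/discordant counts per trait and
#'   kinship).
#' @export
pair_polychoric_structure <- function(pair_data, min_cell = 5) {
  dt <- data.table::as.data.table(pair_data)
  kc <- kinship_coefficients()
  res <- list(); cnts <- list()
  est <- function(y1, y2, t1, t2) {
    out <- try(tetrachoric_pairs(y1, y2, t1, t2), silent = TRUE)
    if (inherits(out, "try-error"))
      list(rho = NA_real_, se = NA_real_, var = NA_real_,
           n = length(y1), boundary = NA)
    else out
  }
  covs <- list()
  for (kn in unique(dt$kinship)) {
    g <- dt[kinship == kn]
    m <- nrow(g)
    co <- kc[match(kn, kc$kinship), ]
    # within-person cross-trait, both pair positions pooled
    w <- est(c(g$y1_a, g$y1_b), c(g$y2_a, g$y2_b),
             c(g$tau1_a, g$tau1_b), c(g$tau2_a, g$tau2_b))
    s1 <- est(g$y1_a, g$y1_b, g$tau1_a, g$tau1_b)
    s2 <- est(g$y2_a, g$y2_b, g$tau2_a, g$tau2_b)
    x1 <- est(g$y1_a, g$y2_b, g$tau1_a, g$tau2_b)
    x2 <- est(g$y1_b, g$y2_a, g$tau1_b, g$tau2_a)
    xr <- mean(c(x1$rho, x2$rho))
    # moment covariance within the group: the four estimates share the
    # same pairs, so assemble per-pair influence values and cross them
    IF <- matrix(NA_real_, m, 4)
    if (is.finite(w$rho) && !isTRUE(w$boundary)) {
      iw <- .tetra_influence(c(g$y1_a, g$y1_b), c(g$y2_a, g$y2_b),
                             c(g$tau1_a, g$tau1_b), c(g$tau2_a, g$tau2_b),
                             w$rho)
      IF[, 1] <- iw[seq_len(m)] + iw[m + seq_len(m)]
    }
    if (is.finite(s1$rho) && !isTRUE(s1$boundary))
      IF[, 2] <- .tetra_influence(g$y1_a, g$y1_b, g$tau1_a, g$tau1_b,
                                  s1$rho)
    if (is.finite(s2$rho) && !isTRUE(s2$boundary))
      IF[, 3] <- .tetra_influence(g$y2_a, g$y2_b, g$tau2_a, g$tau2_b,
                                  s2$rho)
    if (is.finite(xr) && !isTRUE(x1$boundary) && !isTRUE(x2$boundary)) {
      i1 <- .tetra_influence(g$y1_a, g$y2_b, g$tau1_a, g$tau2_b, x1$rho)
      i2 <- .tetra_influence(g$y1_b, g$y2_a, g$tau1_b, g$tau2_a, x2$rho)
      IF[, 4] <- (i1 + i2) / 2
    }
    Sig <- matrix(NA_real_, 4, 4)
    ok <- which(colSums(is.na(IF)) == 0)
    if (length(ok))
      Sig[ok, ok] <- crossprod(IF[, ok, drop = FALSE])
    # fall back to the observed-information variance where influence
    # values are unavailable (boundary/degenerate estimates)
    fallback <- c(w$var, s1$var, s2$var, mean(c(x1$var, x2$var)))
    for (j in 1:4) if (is.na(Sig[j, j])) Sig[j, j] <- fallback[j]
    Sig[is.na(Sig)] <- 0
    vars <- diag(Sig)
    rid <- paste(kn, c("within_cross", "same_trait1", "same_trait2",
                       "cross_cross"), sep = ".")
    dimnames(Sig) <- list(rid, rid)
    covs[[length(covs) + 1L]] <- Sig
    res[[length(res) + 1L]] <- data.table::data.table(
      kinship = kn, alpha = co$alpha, gamma = co$gamma,
      moment = c("within_cross", "same_trait1", "same_trait2",
                 "cross_cross"),
      row_id = rid,
      r = c(w$rho, s1$rho, s2$rho, xr),
      var = vars, se = sqrt(vars),
      n = c(w$n, s1$n, s2$n, m),
      boundary = c(w$boundary, s1$boundary, s2$boundary,
                   isTRUE(x1$boundary) | isTRUE(x2$boundary)))
    cnts[[length(cnts) + 1L]] <- data.table::data.table(
      kinship = kn,
      trait = c(1L, 2L),
      concordant = c(sum(g$y1_a == 1 & g$y1_b == 1, na.rm = TRUE),
                     sum(g$y2_a == 1 & g$y2_b == 1, na.rm = TRUE)),
      discordant = c(sum(g$y1_a != g$y1_b, na.rm = TRUE),
                     sum(g$y2_a != g$y2_b, na.rm = TRUE)))
  }
  out <- data.table::rbindlist(res)
  # block-diagonal moment covariance across kinship groups
  nall <- sum(vapply(covs, nrow, 0L))
  Sigma <- matrix(0, nall, nall)
  ids <- unlist(lapply(covs, rownames))
  dimnames(Sigma) <- list(ids, ids)
  off <- 0L
  for (S in covs) {
    idx <- off + seq_len(nrow(S))
    Sigma[idx, idx] <- S
    off <- off + nrow(S)
  }
  data.table::setattr(out, "moment_cov", Sigma)
  # insufficient-data signal for sparse required cells
  counts <- data.table::rbindlist(cnts)
  sparse <- counts[concordant < min_cell | discordant < min_cell]
  if (nrow(sparse)) {
    for (i in seq_len(nrow(sparse))) {
      mom <- paste0("same_trait", sparse$trait[i])
      out[kinship == sparse$kinship[i] & moment == mom, r := NA_real_]
    }
  }
  data.table::setattr(out, "pair_counts", counts)
  data.table::setattr(out, "class",
                      c("pair_structure", class(out)))
  out[]
}
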