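#' Percentages from an aggregated cohort counts table
#'
#' Recomputes the percentages of a published-style cohort descriptives
#' table from its raw counts: the exposure prevalence, row percentages for
#' sex and birth-year strata, and column percentages (within the exposed
#' and unexposed groups) for co-occurring phenotypes. Rounding is to one
#' decimal, as such tables print.
#'
#' @param counts `data.frame` with columns `block` (`total`, `sex`,
#'   `birth_year`, `phenotype`), `label`, `n_total`, `n_without`, `n_with`,
#'   or the path of a TSV file holding it. A packaged example:
#'   `system.file("extdata", "birth_cohort_counts.tsv", package = "famliab")`.
#' @return `data.table` with added `pct_without` and `pct_with` columns and
#'   attribute `"prevalence_pct"` (exposed share of the total row, percent,
#'   one decimal).
#' @export
cohort_percentages <- function(counts) {
  if (is.character(counts))
    counts <- data.table::fread(counts, sep = "\t")
  dt <- data.table::as.data.table(counts)
  need <- c("block", "label", "n_total", "n_without", "n_with")
  if (!all(need %in% names(dt)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  tot <- dt[block == "total"]
  if (nrow(tot) != 1) stop("counts table needs exactly one 'total' row")
  r1 <- function(x) round(x, 1)
  dt[, pct_without := r1(100 * n_without / n_total)]
  dt[, pct_with := r1(100 * n_with / n_total)]
  # composition of the exposed group (e.g. percent female among exposed)
  dt[, pct_of_exposed := r1(100 * n_with / tot$n_with)]
  # co-occurring phenotypes: percentages within exposure group
  dt[block == "phenotype",
     `:=`(pct_without = r1(100 * n_without / tot$n_without),
          pct_with = r1(100 * n_with / tot$n_with))]
  data.table::setattr(dt, "prevalence_pct",
                      r1(100 * tot$n_with / tot$n_total))
  dt[]
}
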