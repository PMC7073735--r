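# Hypothesis tests on segment properties: Pearson correlations (with
# two-sided p from the t transform) between propiece and mature-peptide
# lengths and net charges, per species and pooled.

#' Pearson correlation with two-sided p
#'
#' Sample Pearson r; the p-value is two-sided from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (the classical
#' test, as implemented by `stats::cor.test`). Reports serialize p to 3
#' decimals, so `0.000` means `p < 0.0005`.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with nonzero
#'   variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variable: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Segment-property correlation report
#'
#' For segmented, descriptor-annotated precursors, computes the Pearson
#' correlation between propiece and mature-peptide lengths and between
#' their net charges, per species and pooled over all records. The pooled
#' value is computed over the union of records, not as a mean of
#' per-species r.
#'
#' @param precursors List of `amp_precursor` objects.
#' @param charge_convention `"integer"` (side-chain counting, default) or
#'   `"ph7"` (modeled charge at pH 7).
#' @return A data frame with columns `variable_pair`
#'   (`"length-length"`/`"charge-charge"`), `scope` (species or
#'   `"pooled"`), `n`, `r`, `p`. Species with fewer than 3 records are
#'   skipped with a warning.
#' @export
correlation_report <- function(precursors,
                               charge_convention = c("integer", "ph7")) {
  charge_convention <- match.arg(charge_convention)
  seg_value <- function(p, region, what) {
    aa <- precursor_segment(p, region)
    if (what == "length") return(nchar(aa))
    if (charge_convention == "integer") net_charge_integer(aa)
    else charge_at_pH(aa, 7)
  }
  df <- data.frame(
    species = vapply(precursors, `[[`, character(1), "species"),
    len_pro = vapply(precursors, seg_value, numeric(1), "propiece", "length"),
    len_mat = vapply(precursors, seg_value, numeric(1), "mature", "length"),
    chg_pro = vapply(precursors, seg_value, numeric(1), "propiece", "charge"),
    chg_mat = vapply(precursors, seg_value, numeric(1), "mature", "charge"),
    stringsAsFactors = FALSE)
  scopes <- c(sort(unique(df$species)), "pooled")
  rows <- list()
  for (scope in scopes) {
    sub <- if (scope == "pooled") df else df[df$species == scope, ]
    if (nrow(sub) < 3L) {
      warning("scope '", scope, "' skipped: fewer than 3 records")
      next
    }
    for (pair in c("length-length", "charge-charge")) {
      xy <- if (pair == "length-length") list(sub$len_pro, sub$len_mat)
            else list(sub$chg_pro, sub$chg_mat)
      res <- tryCatch(pearson(xy[[1]], xy[[2]]), error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variable_pair = pair, scope = scope, n = res$n,
        r = res$r, p = res$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
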