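# Physicochemical descriptors for peptide segments.
#
# Conventions follow the ExPASy ProtParam/Compute-pI tools: average residue
# masses, Bjellqvist pKa values, Kyte-Doolittle hydropathy, and the
# Guruprasad dipeptide weight table for the instability index.

check_standard <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  bad <- setdiff(chars, .standard_aa)
  if (length(bad)) {
    stop("nonstandard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  chars
}

#' Average-isotopic molecular weight of a peptide
#'
#' Sum of average residue masses plus one water.
#'
#' @param aa Protein string of standard residues.
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(aa) {
  chars <- check_standard(aa)
  sum(.aa_masses[chars]) + .water_mass
}

#' Modeled net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups (D, E, C, Y, H, K, R side
#' chains plus the termini) using the Bjellqvist pKa set: each positive
#' group contributes `+1/(1 + 10^(pH - pKa))`, each negative group
#' `-1/(1 + 10^(pKa - pH))`. N- and C-terminal pKa values depend on the
#' terminal residue where Bjellqvist specifies so.
#'
#' @param aa Protein string of standard residues.
#' @param pH pH in `[0, 14]`.
#' @return The modeled net charge (continuous, strictly decreasing in pH).
#' @export
charge_at_pH <- function(aa, pH) {
  stopifnot(pH >= 0, pH <= 14)
  chars <- check_standard(aa)
  pos_contrib <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_contrib <- function(pka) -1 / (1 + 10^(pka - pH))
  q <- 0
  for (res in names(.pka$positive)) {
    q <- q + sum(chars == res) * pos_contrib(.pka$positive[[res]])
  }
  for (res in names(.pka$negative)) {
    q <- q + sum(chars == res) * neg_contrib(.pka$negative[[res]])
  }
  first <- chars[1]; last <- chars[length(chars)]
  nterm_pka <- if (first %in% names(.pka$nterm_by_residue)) {
    .pka$nterm_by_residue[[first]]
  } else .pka$nterm_default
  cterm_pka <- if (last %in% names(.pka$cterm_by_residue)) {
    .pka$cterm_by_residue[[last]]
  } else .pka$cterm_default
  q + pos_contrib(nterm_pka) + neg_contrib(cterm_pka)
}

#' Theoretical isoelectric point
#'
#' The pH at which [charge_at_pH()] is zero, found by bisection on `[0, 14]`
#' to an interval narrower than 0.002.
#'
#' @param aa Protein string of standard residues (non-empty; the termini are
#'   always ionizable).
#' @return The pI in pH units.
#' @export
isoelectric_point <- function(aa) {
  check_standard(aa)
  if (!nchar(aa)) stop("no ionizable groups in an empty peptide")
  lo <- 0; hi <- 14
  while (hi - lo >= 0.002) {
    mid <- (lo + hi) / 2
    if (charge_at_pH(aa, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Integer net charge by side-chain counting
#'
#' `count(K) + count(R) - count(D) - count(E)`; histidine and the termini
#' are excluded. This is the convention used for the charge-balance
#' correlations; [charge_at_pH()] at pH 7 is the continuous alternative.
#'
#' @param aa Protein string of standard residues.
#' @return Integer net charge.
#' @export
net_charge_integer <- function(aa) {
  chars <- check_standard(aa)
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy value; negative values indicate
#' hydrophilic peptides.
#'
#' @param aa Protein string of standard residues.
#' @return GRAVY, bounded by the table extremes `[-4.5, 4.5]`.
#' @export
gravy <- function(aa) {
  chars <- check_standard(aa)
  mean(.kd_hydropathy[chars])
}

#' Guruprasad instability index
#'
#' `II = (10/L) * sum over consecutive dipeptides of DIWV(aa_i, aa_{i+1})`.
#' Peptides with `II < 40` are conventionally called stable.
#'
#' @param aa Protein string of at least 2 standard residues.
#' @return The instability index.
#' @export
instability_index <- function(aa) {
  chars <- check_standard(aa)
  L <- length(chars)
  if (L < 2L) stop("instability index needs at least 2 residues")
  idx <- cbind(chars[-L], chars[-1])
  (10 / L) * sum(.diwv[idx])
}

#' Full descriptor bundle for one peptide segment
#'
#' @param aa Protein string of standard residues.
#' @return An object of class `peptide_properties`: length, molecular
#'   weight (Da), pI, integer net charge, charge at pH 7, GRAVY,
#'   instability index and the stability call (`II < 40`).
#' @export
peptide_properties <- function(aa) {
  structure(list(
    length = nchar(aa),
    mw = molecular_weight(aa),
    pI = isoelectric_point(aa),
    net_charge = net_charge_integer(aa),
    charge_ph7 = charge_at_pH(aa, 7),
    gravy = gravy(aa),
    instability_index = if (nchar(aa) >= 2) instability_index(aa) else NA_real_,
    stable = if (nchar(aa) >= 2) instability_index(aa) < 40 else NA
  ), class = "peptide_properties")
}

#' @export
print.peptide_properties <- function(x, ...) {
  cat(sprintf(
    "<peptide_properties> %d aa, MW %.2f Da, pI %.2f, net charge %+d, GRAVY %.2f, II %.2f (%s)\n",
    x$length, x$mw, x$pI, x$net_charge, x$gravy,
    ifelse(is.na(x$instability_index), NaN, x$instability_index),
    if (isTRUE(x$stable)) "stable" else "unstable"))
  invisible(x)
}

#' Descriptor table for a set of segmented precursors
#'
#' One row per record per region, for the propiece and mature segments.
#'
#' @param precursors List of `amp_precursor` objects.
#' @param charge_convention `"integer"` for side-chain counting or `"ph7"`
#'   for the modeled charge at pH 7.
#' @return A data frame with id, species, family, region and the
#'   descriptors.
#' @export
descriptor_report <- function(precursors, charge_convention = c("integer", "ph7")) {
  charge_convention <- match.arg(charge_convention)
  rows <- list()
  for (p in precursors) {
    for (region in c("propiece", "mature")) {
      aa <- precursor_segment(p, region)
      if (!nchar(aa)) next
      pr <- peptide_properties(aa)
      charge <- if (charge_convention == "integer") pr$net_charge else pr$charge_ph7
      rows[[length(rows) + 1L]] <- data.frame(
        id = p$id, species = p$species, family = p$family, region = region,
        length = pr$length, mw = round(pr$mw, 2), pI = round(pr$pI, 2),
        net_charge = charge, gravy = round(pr$gravy, 3),
        instability_index = round(pr$instability_index, 2),
        stable = pr$stable, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
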