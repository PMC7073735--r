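# Translation, precursor segmentation and residue-level summaries.
#
# A precursor is segmented as
#   [signal (possibly primer-truncated)] [acidic propiece ... motif] [mature]
# where the processing motif (KR/ER/RR by default) belongs to the propiece
# and the mature peptide starts at the residue after it.

#' Segmentation configuration
#'
#' @param min_mature,max_mature Allowed mature-peptide length range
#'   (residues). Defaults 8 and 63 bracket the canonical 10-60 residue AMP
#'   size range with a small margin.
#' @param motifs Dibasic processing motifs scanned for the cut point.
#' @param default_signal_end Signal-peptide length (residues) assumed when no
#'   annotation is present; 0 treats the whole pre-cut region as "propiece
#'   including residual signal", appropriate for primer-truncated clones.
#' @param min_total Minimum precursor length accepted for segmentation.
#' @param strict If `TRUE`, segmentation failures are errors; otherwise they
#'   are returned as `NULL` with a logged message.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_mature = 8L, max_mature = 63L,
                                motifs = c("KR", "RR", "ER"),
                                default_signal_end = 0L,
                                min_total = 25L, strict = FALSE) {
  stopifnot(min_mature >= 1L, max_mature >= min_mature,
            all(nchar(motifs) == 2L))
  structure(list(min_mature = as.integer(min_mature),
                 max_mature = as.integer(max_mature),
                 motifs = toupper(motifs),
                 default_signal_end = as.integer(default_signal_end),
                 min_total = as.integer(min_total),
                 strict = isTRUE(strict)),
            class = "segmentation_config")
}

#' Translate a DNA string in a given reading frame
#'
#' Standard genetic code; translation stops at (and excludes) the first stop
#' codon; codons containing `N` translate to `X`; an incomplete trailing
#' codon is dropped.
#'
#' @param nt DNA string.
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return The translated protein string.
#' @export
translate_dna <- function(nt, frame = 0L) {
  stopifnot(frame %in% 0:2)
  nt <- normalize_nt(nt)
  if (nchar(nt) - frame < 3L) stop("no complete codon in frame ", frame)
  aa <- seqinr::translate(seqinr::s2c(nt), frame = frame, sens = "F")
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

#' Choose the reading frame of a primer-truncated clone
#'
#' Cloned precursor cDNAs begin inside the signal peptide at a primer site,
#' so no ATG anchor is available. The frame whose translation has the
#' longest stop-free prefix is chosen; ties go to the smallest frame index.
#'
#' @param nt DNA string of length >= 9.
#' @return A list with elements `frame` (0/1/2) and `aa` (the stop-trimmed
#'   translation in that frame).
#' @export
pick_frame <- function(nt) {
  nt <- normalize_nt(nt)
  if (nchar(nt) < 9L) stop("sequence too short to pick a frame")
  prots <- vapply(0:2, function(f) translate_dna(nt, f), character(1))
  lens <- nchar(prots)
  if (all(lens < 10L)) {
    stop("no plausible ORF: all frames hit a stop within 10 codons")
  }
  best <- which.max(lens)  # ties: which.max takes the first (smallest frame)
  list(frame = best - 1L, aa = prots[best])
}

#' Segment a precursor into signal, propiece and mature peptide
#'
#' Annotated boundaries (features `sig_peptide`/`propeptide`/`mat_peptide`
#' on the source record, in amino-acid coordinates) take precedence; absent
#' those, the cut point is placed after the rightmost processing motif whose
#' implied mature length falls within the configured range. Motif residues
#' belong to the propiece.
#'
#' @param aa Protein string (stop-trimmed translation).
#' @param features Optional data frame of amino-acid-coordinate features
#'   with columns `key`, `start`, `end` (1-based inclusive on `aa`).
#' @param cfg A [segmentation_config()].
#' @return A list with `signal_end` (number of signal residues; 0 if none),
#'   `cut_point` (index of the last propiece residue; mature starts at
#'   `cut_point + 1`) and `provenance` (`"annotation"` or `"motif-scan"`),
#'   or `NULL` in non-strict mode when no cut point qualifies.
#' @export
segment_precursor <- function(aa, features = NULL, cfg = segmentation_config()) {
  stopifnot(is.character(aa), length(aa) == 1L)
  n <- nchar(aa)
  if (n < cfg$min_total) {
    return(segmentation_failure(cfg, "sequence shorter than min_total"))
  }
  if (!is.null(features) && nrow(features)) {
    mat <- features[features$key == "mat_peptide", , drop = FALSE]
    sig <- features[features$key == "sig_peptide", , drop = FALSE]
    if (nrow(mat)) {
      cut_point <- mat$start[1] - 1L
      signal_end <- if (nrow(sig)) sig$end[1] else cfg$default_signal_end
      if (signal_end > cut_point) {
        return(segmentation_failure(cfg, "annotated signal extends past cut point"))
      }
      return(list(signal_end = as.integer(signal_end),
                  cut_point = as.integer(cut_point),
                  provenance = "annotation"))
    }
  }
  chars <- strsplit(aa, "")[[1]]
  pairs <- paste0(chars[-n], chars[-1])
  hits <- which(pairs %in% cfg$motifs)      # hit i = motif at residues i, i+1
  if (length(hits)) {
    mature_len <- n - (hits + 1L)
    ok <- mature_len >= cfg$min_mature & mature_len <= cfg$max_mature
    hits <- hits[ok]
  }
  if (!length(hits)) {
    return(segmentation_failure(cfg, "no cut point"))
  }
  cut_point <- max(hits) + 1L               # rightmost motif; motif in propiece
  list(signal_end = cfg$default_signal_end,
       cut_point = as.integer(cut_point),
       provenance = "motif-scan")
}

segmentation_failure <- function(cfg, why) {
  if (cfg$strict) stop(why)
  message("segmentation failed: ", why)
  NULL
}

#' Build a segmented precursor from a sequence record
#'
#' Picks the reading frame, translates, and segments. Nucleotide-coordinate
#' `CDS`/peptide features on the record are converted to amino-acid
#' coordinates relative to the chosen frame before segmentation.
#'
#' @param record An [amp_record()].
#' @param cfg A [segmentation_config()].
#' @return An object of class `amp_precursor` (the record plus `frame`,
#'   `aa`, `signal_end`, `cut_point`, `provenance`), or `NULL` in
#'   non-strict mode when the record cannot be segmented.
#' @export
build_precursor <- function(record, cfg = segmentation_config()) {
  fr <- tryCatch(pick_frame(record$nt), error = function(e) e)
  if (inherits(fr, "error")) {
    return(segmentation_failure(cfg, paste0(record$id, ": ", conditionMessage(fr))))
  }
  aa_features <- nt_features_to_aa(record$features, fr$frame, nchar(fr$aa))
  seg <- segment_precursor(fr$aa, aa_features, cfg)
  if (is.null(seg)) {
    message("record '", record$id, "' excluded from segmentation")
    return(NULL)
  }
  structure(c(record[c("id", "species", "family", "nt")],
              list(frame = fr$frame, aa = fr$aa,
                   signal_end = seg$signal_end, cut_point = seg$cut_point,
                   provenance = seg$provenance)),
            class = "amp_precursor")
}

# Convert nucleotide-coordinate peptide features to amino-acid coordinates
# in the given frame; features not congruent with the frame are dropped.
nt_features_to_aa <- function(features, frame, aa_len) {
  if (is.null(features) || !nrow(features)) return(features)
  keep <- features$key %in% c("sig_peptide", "propeptide", "mat_peptide")
  features <- features[keep, , drop = FALSE]
  if (!nrow(features)) return(features)
  aa_start <- (features$start - 1L - frame) %/% 3L + 1L
  aa_end <- (features$end - frame) %/% 3L
  ok <- (features$start - 1L - frame) %% 3L == 0L & aa_start >= 1L & aa_end <= aa_len
  features <- features[ok, , drop = FALSE]
  features$start <- aa_start[ok]
  features$end <- aa_end[ok]
  features
}

#' Extract a peptide segment from a segmented precursor
#'
#' @param precursor An `amp_precursor`.
#' @param region One of `"signal"`, `"propiece"`, `"mature"`, `"whole"`.
#'   `"propiece"` spans `(signal_end, cut_point]`, i.e. includes the
#'   processing motif and, for primer-truncated clones segmented with
#'   `default_signal_end = 0`, any residual signal residues.
#' @return The segment's protein string.
#' @export
precursor_segment <- function(precursor,
                              region = c("mature", "propiece", "signal", "whole")) {
  region <- match.arg(region)
  n <- nchar(precursor$aa)
  switch(region,
    signal   = substr(precursor$aa, 1L, precursor$signal_end),
    propiece = substr(precursor$aa, precursor$signal_end + 1L, precursor$cut_point),
    mature   = substr(precursor$aa, precursor$cut_point + 1L, n),
    whole    = precursor$aa)
}

#' @export
print.amp_precursor <- function(x, ...) {
  cat(sprintf("<amp_precursor %s> frame %d, %d aa; signal 1..%d | propiece ..%d | mature ..%d (%s)\n",
              x$id, x$frame, nchar(x$aa), x$signal_end, x$cut_point,
              nchar(x$aa), x$provenance))
  invisible(x)
}

#' Classify a residue by hydropathy class
#'
#' The three classes used for coloring logo-style summaries of mature
#' peptides: hydrophilic = R,K,D,E,N,Q; neutral = S,G,H,T,A,P;
#' hydrophobic = Y,V,L,I,F,W,M,C. The sets partition the 20 standard
#' residues.
#'
#' @param aa1 A single standard residue.
#' @return `"hydrophilic"`, `"neutral"` or `"hydrophobic"`.
#' @export
classify_residue <- function(aa1) {
  stopifnot(is.character(aa1), length(aa1) == 1L, nchar(aa1) == 1L)
  if (aa1 %in% c("R", "K", "D", "E", "N", "Q")) return("hydrophilic")
  if (aa1 %in% c("S", "G", "H", "T", "A", "P")) return("neutral")
  if (aa1 %in% c("Y", "V", "L", "I", "F", "W", "M", "C")) return("hydrophobic")
  stop("nonstandard residue: ", aa1)
}

#' Position-wise residue frequency matrix
#'
#' The numeric core of a sequence logo: per-position relative frequencies
#' over non-gap residues, with the gap fraction tracked separately.
#'
#' @param peptides Character vector of equal-length (aligned) protein
#'   strings; `-` marks gaps.
#' @return A list of class `frequency_matrix` with `freq` (positions x 20
#'   matrix; rows of all-gap columns are `NA`) and `gap_fraction`
#'   (per-position).
#' @export
frequency_matrix <- function(peptides) {
  stopifnot(length(peptides) >= 1L)
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L) stop("peptides must have equal lengths")
  L <- lens[1]
  m <- do.call(rbind, strsplit(peptides, ""))
  freq <- matrix(0, nrow = L, ncol = 20,
                 dimnames = list(NULL, .standard_aa))
  gap_fraction <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    gap_fraction[j] <- mean(col == "-")
    res <- col[col != "-"]
    if (!length(res)) {
      freq[j, ] <- NA_real_
      next
    }
    bad <- setdiff(res, .standard_aa)
    if (length(bad)) stop("nonstandard residue(s): ", paste(bad, collapse = ","))
    tab <- table(factor(res, levels = .standard_aa))
    freq[j, ] <- as.numeric(tab) / length(res)
  }
  structure(list(freq = freq, gap_fraction = gap_fraction),
            class = "frequency_matrix")
}
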