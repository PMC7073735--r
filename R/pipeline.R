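# Pipeline orchestration: segment -> describe -> diversity -> selection ->
# tree -> correlate, from records to a bundle of TSV reports.
#
# Report conventions follow the field's summary-table style: "-" marks a
# ts/tv ratio that is absent because no transversions were observed, "/"
# marks any statistic that could not be computed because the family had
# only one cDNA sequence.

#' Validate pipeline inputs
#'
#' Lists records that fail translation or segmentation, with reasons, plus
#' summary counts per species and family.
#'
#' @param records List of [amp_record()] objects.
#' @param cfg A [segmentation_config()].
#' @return A list with `diagnostics` (data frame id/status/reason; zero
#'   rows when everything passes) and `counts` (records per
#'   species x family).
#' @export
validate_inputs <- function(records, cfg = segmentation_config()) {
  diags <- list()
  for (r in records) {
    fr <- tryCatch(pick_frame(r$nt), error = function(e) e)
    if (inherits(fr, "error")) {
      diags[[length(diags) + 1L]] <- data.frame(
        id = r$id, status = "translation_failed",
        reason = conditionMessage(fr), stringsAsFactors = FALSE)
      next
    }
    seg <- suppressMessages(
      segment_precursor(fr$aa, nt_features_to_aa(r$features, fr$frame, nchar(fr$aa)),
                        segmentation_config(cfg$min_mature, cfg$max_mature,
                                            cfg$motifs, cfg$default_signal_end,
                                            cfg$min_total, strict = FALSE)))
    if (is.null(seg)) {
      diags[[length(diags) + 1L]] <- data.frame(
        id = r$id, status = "segmentation_failed", reason = "no cut point",
        stringsAsFactors = FALSE)
    }
  }
  counts <- as.data.frame(table(
    species = vapply(records, `[[`, character(1), "species"),
    family = vapply(records, `[[`, character(1), "family")))
  counts <- counts[counts$Freq > 0, ]
  list(diagnostics = if (length(diags)) do.call(rbind, diags) else
         data.frame(id = character(), status = character(),
                    reason = character(), stringsAsFactors = FALSE),
       counts = counts)
}

# Build per-family aligned_family objects from segmented precursors.
# Members must share one sequence length (substitution-only families);
# families with indels need a pre-aligned input and are skipped here with
# a message. Region masks come from the first member's boundaries.
families_from_precursors <- function(precursors) {
  fam_names <- unique(vapply(precursors, `[[`, character(1), "family"))
  out <- list()
  for (fam in fam_names) {
    members <- Filter(function(p) p$family == fam, precursors)
    lens <- vapply(members, function(p) nchar(p$nt), integer(1))
    if (length(unique(lens)) != 1L) {
      message("family '", fam, "' skipped: members differ in length (alignment needed)")
      next
    }
    p1 <- members[[1]]
    fr <- p1$frame
    cut_nt <- 3L * p1$cut_point
    aa_nt <- 3L * nchar(p1$aa)
    seqs <- vapply(members, `[[`, character(1), "nt")
    names(seqs) <- vapply(members, `[[`, character(1), "id")
    out[[fam]] <- aligned_family(
      seqs, family = fam, species = p1$species,
      region_masks = list(propiece = fr + seq_len(cut_nt),
                          mature = fr + (cut_nt + 1L):aa_nt,
                          whole = fr + seq_len(aa_nt)))
  }
  out
}

fmt_ratio <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))

#' Run the full analysis pipeline
#'
#' Segments every record, computes descriptors, per-family nucleotide
#' diversity, region-wise ts/tv and NG86 selection summaries, the
#' correlation report, per-family mature-peptide frequency matrices, and
#' (when all sequences share one length) a neighbor-joining tree with
#' bootstrap supports. All outputs are TSV/Newick files under `out_dir`,
#' plus a manifest recording the seed and configuration.
#'
#' @param records List of [amp_record()] objects (e.g. from
#'   [read_fasta()]), with family labels present or supplied via
#'   `metadata`.
#' @param out_dir Output directory (created if needed).
#' @param metadata Optional metadata table or TSV path for
#'   [join_metadata()].
#' @param seg_cfg A [segmentation_config()]; its `strict` flag decides
#'   whether segmentation failures abort the run or are excluded and
#'   logged.
#' @param charge_convention Passed to [descriptor_report()] and
#'   [correlation_report()].
#' @param deletion Passed to [nucleotide_diversity()].
#' @param tree Whether to attempt the joint NJ tree.
#' @param bootstrap_reps,seed Bootstrap replicates and RNG seed for branch
#'   supports.
#' @return Invisibly, a list with the output paths and the in-memory
#'   tables.
#' @export
run_pipeline <- function(records, out_dir, metadata = NULL,
                         seg_cfg = segmentation_config(),
                         charge_convention = c("integer", "ph7"),
                         deletion = c("complete", "pairwise"),
                         tree = TRUE, bootstrap_reps = 100L, seed = 1L) {
  charge_convention <- match.arg(charge_convention)
  deletion <- match.arg(deletion)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(metadata)) records <- join_metadata(records, metadata)

  precursors <- list()
  excluded <- list()
  for (r in records) {
    p <- withCallingHandlers(
      build_precursor(r, seg_cfg),
      message = function(m) invokeRestart("muffleMessage"))
    if (is.null(p)) {
      excluded[[length(excluded) + 1L]] <- r$id
    } else {
      precursors[[length(precursors) + 1L]] <- p
    }
  }
  if (length(excluded)) {
    message(length(excluded), " record(s) excluded from segmentation: ",
            paste(unlist(excluded), collapse = ", "))
  }

  paths <- list()
  desc <- descriptor_report(precursors, charge_convention)
  paths$descriptors <- write_report(desc, file.path(out_dir, "descriptors.tsv"))

  fams <- withCallingHandlers(
    families_from_precursors(precursors),
    message = function(m) invokeRestart("muffleMessage"))
  singleton <- vapply(fams, function(f) f$n < 2L, logical(1))

  div_rows <- lapply(fams, function(f) {
    if (f$n < 2L) {
      return(data.frame(family = f$family, species = f$species, n = f$n,
                        pi = "/", sd = "/", sites = "/",
                        stringsAsFactors = FALSE))
    }
    d <- nucleotide_diversity(f, "whole", deletion)
    data.frame(family = f$family, species = f$species, n = d$n,
               pi = sprintf("%.3f", d$pi), sd = sprintf("%.3f", d$sd),
               sites = as.character(d$sites), stringsAsFactors = FALSE)
  })
  diversity <- do.call(rbind, c(div_rows, make.row.names = FALSE))
  paths$diversity <- write_report(diversity, file.path(out_dir, "diversity.tsv"))

  sel_rows <- lapply(fams, function(f) {
    if (f$n < 2L) {
      return(data.frame(family = f$family, region = c("propiece", "mature", "whole"),
                        n = f$n, dS = "/", dN = "/", omega = "/",
                        classification = "/", ts_tv = "/",
                        stringsAsFactors = FALSE))
    }
    s <- family_selection(f)
    data.frame(family = s$family, region = s$region, n = s$n,
               dS = ifelse(is.na(s$dS), "-", sprintf("%.4f", s$dS)),
               dN = ifelse(is.na(s$dN), "-", sprintf("%.4f", s$dN)),
               omega = ifelse(is.na(s$omega), "-", sprintf("%.3f", s$omega)),
               classification = ifelse(is.na(s$classification), "-",
                                       s$classification),
               ts_tv = fmt_ratio(s$ts_tv), stringsAsFactors = FALSE)
  })
  selection <- do.call(rbind, c(sel_rows, make.row.names = FALSE))
  paths$selection <- write_report(selection, file.path(out_dir, "selection.tsv"))

  correlations <- suppressWarnings(correlation_report(precursors, charge_convention))
  if (!is.null(correlations)) {
    correlations$r <- sprintf("%.3f", correlations$r)
    correlations$p <- sprintf("%.3f", correlations$p)
  }
  paths$correlations <- write_report(correlations,
                                     file.path(out_dir, "correlations.tsv"))

  freq_rows <- list()
  for (f in fams) {
    matures <- vapply(Filter(function(p) p$family == f$family, precursors),
                      precursor_segment, character(1), "mature")
    if (length(unique(nchar(matures))) != 1L) next
    fm <- frequency_matrix(matures)
    for (pos in seq_len(nrow(fm$freq))) {
      nonzero <- which(fm$freq[pos, ] > 0)
      for (j in nonzero) {
        freq_rows[[length(freq_rows) + 1L]] <- data.frame(
          family = f$family, position = pos,
          residue = colnames(fm$freq)[j],
          class = classify_residue(colnames(fm$freq)[j]),
          freq = round(fm$freq[pos, j], 4),
          gap_fraction = fm$gap_fraction[pos], stringsAsFactors = FALSE)
      }
    }
  }
  freqs <- if (length(freq_rows)) do.call(rbind, freq_rows) else
    data.frame(family = character(), position = integer(),
               residue = character(), class = character(),
               freq = numeric(), gap_fraction = numeric())
  paths$frequencies <- write_report(freqs, file.path(out_dir, "frequency_matrices.tsv"))

  tree_obj <- NULL
  if (tree) {
    all_seqs <- unlist(lapply(fams, function(f) f$seqs))
    if (length(unique(nchar(all_seqs))) == 1L && length(all_seqs) >= 3L) {
      tree_obj <- bootstrap_supports(all_seqs, reps = bootstrap_reps,
                                     mode = "tbe", seed = seed,
                                     threshold = 0.60)
      paths$tree <- write_newick(tree_obj, file.path(out_dir, "tree.nwk"))
      paths$supports <- write_report(attr(tree_obj, "support_table"),
                                     file.path(out_dir, "branch_supports.tsv"))
    } else {
      message("joint tree skipped: sequences are not aligned to one length")
    }
  }

  manifest <- data.frame(
    key = c("seed", "bootstrap_reps", "charge_convention", "deletion",
            "motifs", "min_mature", "max_mature", "default_signal_end",
            "n_records", "n_segmented", "n_excluded", "excluded_ids",
            "descriptors_md5"),
    value = c(seed, bootstrap_reps, charge_convention, deletion,
              paste(seg_cfg$motifs, collapse = ","), seg_cfg$min_mature,
              seg_cfg$max_mature, seg_cfg$default_signal_end,
              length(records), length(precursors), length(excluded),
              paste(unlist(excluded), collapse = ","),
              unname(tools::md5sum(paths$descriptors))),
    stringsAsFactors = FALSE)
  paths$manifest <- write_report(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(paths = paths, precursors = precursors, families = fams,
                 descriptors = desc, diversity = diversity,
                 selection = selection, correlations = correlations,
                 frequencies = freqs, tree = tree_obj,
                 excluded = unlist(excluded)))
}
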