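# Seeded generator of AMP precursor families with known ground truth.
#
# Architecture of every simulated cDNA:
#   [frame-offset bases] [signal (truncated)] [propiece ... motif] [mature]
#   [stop codon] [3' tail]
# The generator guarantees: no internal stops in the true frame, exactly one
# qualifying processing motif (at the true cut point), and that every wrong
# reading frame hits a stop before the true frame's translation ends, so the
# reading frame and cut point are recoverable by construction. Family
# members evolve by substitution only (star genealogy, no indels), with a
# transition:transversion proposal bias kappa and acceptance thinning of
# nonsynonymous changes by omega.

#' Simulation configuration
#'
#' Defaults emulate the cloned frog AMP precursor data the pipeline was
#' built for: ~34 families across three pseudo-species, primer-truncated
#' signal peptides, acidic propieces ending in a KR motif, cationic
#' leucine/glycine-rich mature peptides (~10-60 residues), a negative
#' length coupling of about -0.8 between propiece and mature peptide,
#' negative charge coupling, mild transition bias and purifying selection.
#'
#' @param seed Integer RNG seed.
#' @param n_families Number of families (used by [simulate_forest()]).
#' @param members_per_family Integer vector of candidate member counts; one
#'   value is drawn per family.
#' @param signal_len Full signal-peptide length in residues.
#' @param signal_keep Residues of signal retained after primer truncation.
#' @param mean_mature,mean_propiece Mean segment lengths (residues,
#'   propiece includes the 2-residue motif).
#' @param length_jitter SD (residues) of the shared length deviation.
#' @param rho_length Target correlation between propiece and mature
#'   lengths, in `[-1, 0]`.
#' @param charge_coupling `"negative"` couples propiece acidity to mature
#'   cationicity; `"none"` draws them independently.
#' @param kappa Transition:transversion proposal odds (>= 0).
#' @param omega Nonsynonymous acceptance probability in `(0, 1.5]`; values
#'   above 1 thin synonymous proposals by `1/omega` instead.
#' @param subs_per_seq Expected substitutions per lineage (Poisson mean).
#' @param divergence_subs Substitutions separating family ancestors in
#'   [simulate_forest()].
#' @param motif Processing motif placed at the cut point.
#' @param protect_motif If `TRUE` (default), substitutions that touch the
#'   motif or stop codon, or that create a new qualifying motif, are
#'   rejected, keeping the segmentation truth stable.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_families = 20L,
                              members_per_family = 3:9,
                              signal_len = 22L, signal_keep = 10L,
                              mean_mature = 28L, mean_propiece = 25L,
                              length_jitter = 7L, rho_length = -0.8,
                              charge_coupling = c("negative", "none"),
                              kappa = 4, omega = 0.3, subs_per_seq = 5,
                              divergence_subs = 60L,
                              motif = "KR", protect_motif = TRUE) {
  charge_coupling <- match.arg(charge_coupling)
  stopifnot(rho_length <= 0, rho_length >= -1, kappa >= 0,
            omega > 0, omega <= 1.5, nchar(motif) == 2L,
            signal_keep <= signal_len, mean_mature >= 10, mean_propiece >= 8)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 signal_len = as.integer(signal_len),
                 signal_keep = as.integer(signal_keep),
                 mean_mature = as.integer(mean_mature),
                 mean_propiece = as.integer(mean_propiece),
                 length_jitter = as.numeric(length_jitter),
                 rho_length = rho_length, charge_coupling = charge_coupling,
                 kappa = kappa, omega = omega, subs_per_seq = subs_per_seq,
                 divergence_subs = as.integer(divergence_subs),
                 motif = toupper(motif), protect_motif = isTRUE(protect_motif)),
            class = "simulation_config")
}

.signal_alphabet <- c("L", "I", "V", "F", "A", "W", "M", "C", "S", "T", "G", "P")
.propiece_filler <- c("A", "S", "G", "T", "P", "Q", "N", "V", "L", "I", "F")
.mature_filler <- c("L", "L", "L", "G", "G", "A", "I", "F", "V", "S", "T",
                    "N", "Q", "P", "H", "M", "W", "C")
.cut_motifs <- c("KR", "RR", "ER")

reverse_codon_table <- function() {
  tab <- codon_table()
  split(names(tab), tab)
}

aa_to_codons <- function(aa_chars) {
  rev_tab <- reverse_codon_table()
  vapply(aa_chars, function(a) {
    opts <- rev_tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
}

# Positions (1-based, on the aa string) where a qualifying motif occurs.
motif_positions <- function(aa_chars) {
  n <- length(aa_chars)
  if (n < 2L) return(integer())
  pairs <- paste0(aa_chars[-n], aa_chars[-1])
  which(pairs %in% .cut_motifs)
}

#' Generate one ancestral precursor with known truth
#'
#' Draws segment lengths from a rounded bivariate-normal coupling with
#' correlation `rho_length` (a shared deviation of SD `length_jitter`), so
#' that with `rho_length = -1` the propiece+mature sum is constant across
#' draws. Charges are induced by the number of K/R residues placed in the
#' mature peptide and D/E residues in the propiece, coupled when
#' `charge_coupling = "negative"`. Codons are drawn uniformly over
#' synonymous codons.
#'
#' @param cfg A [simulation_config()]. Uses the current RNG state (callers
#'   seed once).
#' @return A list with `nt` (the cDNA), `frame`, `aa` (true translation),
#'   `signal_end`, `cut_point` (1-based aa index of the last propiece
#'   residue), segment lengths and charges.
#' @export
make_ancestor <- function(cfg = simulation_config()) {
  for (attempt in seq_len(1000L)) {
    dev <- round(cfg$length_jitter * stats::rnorm(1))
    mature_len <- cfg$mean_mature + dev
    pro_dev <- cfg$rho_length * dev +
      cfg$length_jitter * sqrt(1 - cfg$rho_length^2) * stats::rnorm(1)
    propiece_len <- cfg$mean_propiece + round(pro_dev)
    mature_len <- as.integer(min(max(mature_len, 10L), 58L))
    propiece_len <- as.integer(min(max(propiece_len, 8L), 45L))

    q_m <- sample(3:7, 1L)
    q_p <- if (cfg$charge_coupling == "negative") {
      max(2L, q_m + sample(-1:1, 1L))
    } else sample(3:7, 1L)
    q_p <- min(q_p, propiece_len - 2L)

    signal <- sample(.signal_alphabet, cfg$signal_keep, replace = TRUE)

    body_len <- propiece_len - 2L
    pro_body <- sample(.propiece_filler, body_len, replace = TRUE)
    acidic_at <- sample.int(body_len, q_p)
    pro_body[acidic_at] <- sample(c("D", "E"), q_p, replace = TRUE)

    mat <- sample(.mature_filler, mature_len, replace = TRUE)
    q_m_eff <- min(q_m, mature_len)
    basic_at <- sample.int(mature_len, q_m_eff)
    mat[basic_at] <- sample(c("K", "R"), q_m_eff, replace = TRUE)

    aa_chars <- c(signal, pro_body, strsplit(cfg$motif, "")[[1]], mat)
    cut_point <- as.integer(cfg$signal_keep + propiece_len)
    if (!identical(motif_positions(aa_chars), cut_point - 1L)) next

    codons <- aa_to_codons(aa_chars)
    frame <- sample(0:2, 1L)
    prepend <- if (frame > 0) sample(c("A", "C", "G", "T"), frame, replace = TRUE) else character()
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    tail <- sample(c("A", "C", "G", "T"), 12L, replace = TRUE)
    nt <- paste(c(prepend, codons, stop_codon, tail), collapse = "")

    aa <- paste(aa_chars, collapse = "")
    if (!frame_identifiable(nt, frame, nchar(aa))) next
    return(list(nt = nt, frame = frame, aa = aa,
                signal_end = cfg$signal_keep, cut_point = cut_point,
                propiece_len = propiece_len, mature_len = mature_len,
                mature_charge = q_m_eff, propiece_charge = -q_p))
  }
  stop("could not satisfy generator constraints after 1000 draws")
}

# TRUE iff the stated frame is the unique longest stop-free frame.
frame_identifiable <- function(nt, frame, aa_len) {
  for (f in 0:2) {
    if (f == frame) next
    alt <- tryCatch(translate_dna(nt, f), error = function(e) "")
    if (nchar(alt) >= aa_len) return(FALSE)
  }
  nchar(translate_dna(nt, frame)) == aa_len
}

# Apply n substitution events to a cDNA under the cfg's kappa/omega rules.
# Events whose proposal is rejected are consumed (acceptance thinning).
mutate_lineage <- function(nt, anc, cfg, n_events) {
  chars <- strsplit(nt, "")[[1]]
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  body_start <- anc$frame + 1L
  aa_len <- nchar(anc$aa)
  stop_start <- anc$frame + 3L * aa_len + 1L
  protected <- integer()
  if (cfg$protect_motif) {
    motif_aa <- (anc$cut_point - 1L):anc$cut_point
    protected <- c(anc$frame + (3L * (motif_aa[1] - 1L) + 1L):(3L * motif_aa[2]),
                   stop_start:(stop_start + 2L))
  }
  syn_ok <- if (cfg$omega > 1) 1 / cfg$omega else 1
  nonsyn_ok <- min(1, cfg$omega)
  for (ev in seq_len(n_events)) {
    site <- sample.int(length(chars), 1L)
    if (site %in% protected) next
    cur <- chars[site]
    w <- ifelse(bases == transition_of[[cur]], cfg$kappa, 1)
    w[bases == cur] <- 0
    new <- sample(bases, 1L, prob = w)
    in_cds <- site >= body_start && site < stop_start
    if (!in_cds) { chars[site] <- new; next }
    codon_i <- (site - body_start) %/% 3L
    cstart <- body_start + 3L * codon_i
    codon_old <- paste(chars[cstart:(cstart + 2L)], collapse = "")
    codon_new_chars <- chars[cstart:(cstart + 2L)]
    codon_new_chars[site - cstart + 1L] <- new
    codon_new <- paste(codon_new_chars, collapse = "")
    if (is_stop_codon(codon_new)) next
    tab <- codon_table()
    synonymous <- tab[[codon_old]] == tab[[codon_new]]
    accept_p <- if (synonymous) syn_ok else nonsyn_ok
    if (stats::runif(1) > accept_p) next
    if (cfg$protect_motif && !synonymous) {
      trial <- chars; trial[site] <- new
      aa_trial <- strsplit(translate_dna(paste(trial, collapse = ""), anc$frame), "")[[1]]
      if (!identical(motif_positions(aa_trial), anc$cut_point - 1L)) next
    }
    chars[site] <- new
  }
  paste(chars, collapse = "")
}

#' Evolve one family from an ancestor
#'
#' Members are produced independently (star genealogy): each lineage
#' receives `Poisson(subs_per_seq)` substitution events with transition
#' odds `kappa:1` against each transversion; nonsynonymous proposals are
#' accepted with probability `min(1, omega)` (synonymous thinned by
#' `1/omega` when `omega > 1`); stop-creating changes are rejected.
#'
#' @param ancestor Output of [make_ancestor()].
#' @param cfg A [simulation_config()].
#' @param n_members Number of members; default drawn from
#'   `cfg$members_per_family`.
#' @param family,species Labels for the resulting family.
#' @return A list with `family` (an [aligned_family()] with propiece,
#'   mature and whole codon masks in cDNA coordinates) and `truth` (a data
#'   frame of per-member ground truth).
#' @export
evolve_family <- function(ancestor, cfg = simulation_config(),
                          n_members = NULL, family = "fam", species = "sp") {
  if (is.null(n_members)) {
    n_members <- sample(cfg$members_per_family, 1L)
  }
  stopifnot(n_members >= 1L)
  seqs <- character(n_members)
  for (i in seq_len(n_members)) {
    repeat {
      n_events <- stats::rpois(1, cfg$subs_per_seq)
      nt <- mutate_lineage(ancestor$nt, ancestor, cfg, n_events)
      if (frame_identifiable(nt, ancestor$frame, nchar(ancestor$aa))) break
    }
    seqs[i] <- nt
  }
  names(seqs) <- sprintf("%s_%02d", family, seq_len(n_members))
  fr <- ancestor$frame
  cut_nt <- 3L * ancestor$cut_point
  aa_nt <- 3L * nchar(ancestor$aa)
  masks <- list(propiece = fr + seq_len(cut_nt),
                mature = fr + (cut_nt + 1L):aa_nt,
                whole = fr + seq_len(aa_nt))
  fam <- aligned_family(seqs, family = family, species = species,
                        region_masks = masks)
  truth <- data.frame(
    id = names(seqs), family = family, species = species,
    frame = fr, signal_end = ancestor$signal_end,
    cut_point = ancestor$cut_point,
    propiece_len = ancestor$propiece_len, mature_len = ancestor$mature_len,
    propiece_charge = ancestor$propiece_charge,
    mature_charge = ancestor$mature_charge,
    omega_true = cfg$omega, kappa_true = cfg$kappa,
    stringsAsFactors = FALSE)
  list(family = fam, truth = truth)
}

#' Simulate a forest of equal-length families for tree analyses
#'
#' One base ancestor is generated; each family's ancestor is derived from
#' it by `divergence_subs` substitutions, then members evolve as in
#' [evolve_family()]. All sequences share coordinates, so the combined set
#' is alignment-free input for a joint tree.
#'
#' @param cfg A [simulation_config()]; `length_jitter` is forced to 0 so
#'   all families share one length.
#' @param species Label applied to all families.
#' @return A list with `seqs` (all members, named), `families` (list of
#'   per-family [evolve_family()] results) and `truth` (combined truth
#'   table).
#' @export
simulate_forest <- function(cfg = simulation_config(), species = "sp") {
  set.seed(cfg$seed)
  base_cfg <- cfg
  base_cfg$length_jitter <- 0
  base <- make_ancestor(base_cfg)
  fams <- vector("list", cfg$n_families)
  for (k in seq_len(cfg$n_families)) {
    fam_anc <- base
    fam_anc$nt <- mutate_lineage(base$nt, base, cfg, cfg$divergence_subs)
    fams[[k]] <- evolve_family(fam_anc, cfg,
                               family = sprintf("fam%02d", k),
                               species = species)
  }
  seqs <- unlist(lapply(fams, function(f) f$family$seqs))
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  list(seqs = seqs, families = fams, truth = truth)
}

#' Write a gold-standard synthetic dataset
#'
#' Emits three pseudo-species blocks with 14, 7 and 13 families (mirroring
#' the three study species' clade counts), as a FASTA file with
#' `id|species|family` headers, a metadata TSV and a truth TSV. Output is
#' deterministic for a fixed `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param family_counts Families per pseudo-species.
#' @return Invisibly, a list with the file paths, the list of per-family
#'   simulation results and the combined truth table.
#' @export
gold_dataset <- function(cfg = simulation_config(), dir,
                         family_counts = c(SpA = 14L, SpB = 7L, SpC = 13L)) {
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fams <- list()
  for (sp in names(family_counts)) {
    for (k in seq_len(family_counts[[sp]])) {
      anc <- make_ancestor(cfg)
      fam_name <- sprintf("%s-fam%02d", sp, k)
      res <- evolve_family(anc, cfg, family = fam_name, species = sp)
      fams[[fam_name]] <- res
    }
  }
  records <- list()
  for (res in fams) {
    fam <- res$family
    for (i in seq_along(fam$seqs)) {
      records[[length(records) + 1L]] <-
        amp_record(id = names(fam$seqs)[i], nt = fam$seqs[[i]],
                   species = fam$species, family = fam$family)
    }
  }
  fasta <- file.path(dir, "gold.fasta")
  write_fasta(records, fasta)
  meta <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    species = vapply(records, `[[`, character(1), "species"),
    family = vapply(records, `[[`, character(1), "family"),
    stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "gold_metadata.tsv")
  write_report(meta, meta_path)
  truth <- do.call(rbind, c(lapply(fams, `[[`, "truth"), make.row.names = FALSE))
  truth_path <- file.path(dir, "gold_truth.tsv")
  write_report(truth, truth_path)
  invisible(list(fasta = fasta, metadata = meta_path, truth_file = truth_path,
                 families = fams, truth = truth))
}
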