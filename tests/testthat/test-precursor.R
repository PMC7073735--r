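test_that("translation follows the standard code, stops at stops, and handles N and frames", {
  expect_equal(translate_dna("ATGGGC", 0), "MG")
  expect_equal(translate_dna("ATGTAAGGG", 0), "M")
  expect_equal(translate_dna("NATGGC", 1), "M")   # frame offset, tail dropped
  expect_equal(translate_dna("ATGNNNGGC", 0), "MXG")
  expect_error(translate_dna("AC", 0), "codon")
  # agreement with an independent codon table on random clean sequences
  set.seed(41)
  for (i in 1:20) {
    s <- random_codon_string(15)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_equal(translate_dna(s, 0),
                 paste(oracle_genetic_code[codons], collapse = ""))
  }
})

test_that("frame picking prefers the longest stop-free prefix with smallest-index ties", {
  # 30 clean codons in frame 0; frames 1/2 hit stops quickly
  clean <- paste(rep("ATGGCT", 15), collapse = "")
  s <- paste0(clean, "TAA")
  pf <- pick_frame(s)
  expect_equal(pf$frame, 0)
  expect_equal(pf$aa, translate_dna(s, 0))
  # all frames stop within 10 codons -> error
  expect_error(pick_frame("TGATTGAATAGTAAATAAATAGTTAG"), "no plausible ORF")
})

test_that("frame ties break to the smaller frame index", {
  # construct: frame 0 and frame 1 both translate the full tail cleanly
  s <- "AATGGCTGCTGCTGCTGCTGCTGCTGCTGCTG"
  lens <- vapply(0:2, function(f) nchar(translate_dna(s, f)), integer(1))
  top <- which(lens == max(lens))
  pf <- pick_frame(s)
  expect_equal(pf$frame, top[1] - 1L)
})

test_that("motif-scan segmentation uses the rightmost qualifying motif, motif in propiece", {
  cfg <- segmentation_config(min_total = 10)
  seg <- segment_precursor("DDEEAAKRGLFDIIKKIAES", cfg = cfg)
  expect_equal(seg$cut_point, 8)
  expect_equal(seg$provenance, "motif-scan")
  # two KR motifs, both legal -> rightmost wins
  aa2 <- "DDEKRDDEEEEKRGLFDIIKKIAES"      # KR at aa 4-5 and 12-13
  seg2 <- segment_precursor(aa2, cfg = cfg)
  expect_equal(seg2$cut_point, 13)
  # motif whose mature segment would be too short is not qualifying
  aa3 <- "DDEKRDDEEEEGLFDIIKKIAESKRAA"
  seg3 <- segment_precursor(aa3, cfg = cfg)
  expect_equal(seg3$cut_point, 5)
})

test_that("annotated boundaries take precedence over the motif scan", {
  cfg <- segmentation_config(min_total = 10)
  feats <- data.frame(key = c("sig_peptide", "mat_peptide"),
                      start = c(1L, 10L), end = c(3L, 20L), note = "",
                      stringsAsFactors = FALSE)
  seg <- segment_precursor("DDEEAAKRGLFDIIKKIAES", feats, cfg)
  expect_equal(seg$provenance, "annotation")
  expect_equal(seg$cut_point, 9)
  expect_equal(seg$signal_end, 3)
})

test_that("records with no qualifying cut point are excluded, not dropped silently", {
  cfg <- segmentation_config(min_total = 10, strict = FALSE)
  expect_message(out <- segment_precursor("GGGGGGGGGGGGGGGG", cfg = cfg),
                 "no cut point")
  expect_null(out)
  strict <- segmentation_config(min_total = 10, strict = TRUE)
  expect_error(segment_precursor("GGGGGGGGGGGGGGGG", cfg = strict), "no cut point")
})

test_that("residue classes partition the 20 standard residues as in the logo coloring", {
  hydrophilic <- c("R", "K", "D", "E", "N", "Q")
  neutral <- c("S", "G", "H", "T", "A", "P")
  hydrophobic <- c("Y", "V", "L", "I", "F", "W", "M", "C")
  all20 <- c(hydrophilic, neutral, hydrophobic)
  expect_setequal(all20, c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  for (r in hydrophilic) expect_equal(classify_residue(r), "hydrophilic")
  for (r in neutral) expect_equal(classify_residue(r), "neutral")
  for (r in hydrophobic) expect_equal(classify_residue(r), "hydrophobic")
  expect_error(classify_residue("B"), "nonstandard")
})

test_that("frequency matrices are column-normalized with gaps tracked separately", {
  fm <- frequency_matrix(c("GL", "GL", "GI"))
  expect_equal(unname(fm$freq[1, "G"]), 1)
  expect_equal(unname(fm$freq[2, "L"]), 2 / 3)
  expect_equal(unname(fm$freq[2, "I"]), 1 / 3)
  expect_equal(fm$gap_fraction, c(0, 0))
  # all-gap column: NA frequencies, gap fraction 1
  fm2 <- frequency_matrix(c("A-", "C-"))
  expect_true(all(is.na(fm2$freq[2, ])))
  expect_equal(fm2$gap_fraction[2], 1)
  expect_error(frequency_matrix(c("AA", "A")), "equal")
  # property: rows sum to 1 over non-gap residues for random inputs
  set.seed(11)
  for (i in 1:10) {
    peps <- replicate(5, random_peptide(8))
    fm3 <- frequency_matrix(peps)
    expect_equal(rowSums(fm3$freq), rep(1, 8), tolerance = 1e-9)
  }
})

test_that("build_precursor recovers simulator truth end to end", {
  cfg <- simulation_config(seed = 5)
  set.seed(5)
  for (i in 1:25) {
    anc <- make_ancestor(cfg)
    rec <- amp_record(sprintf("r%d", i), anc$nt, "sp", "fam")
    p <- build_precursor(rec)
    expect_equal(p$frame, anc$frame)
    expect_equal(p$aa, anc$aa)
    expect_equal(p$cut_point, anc$cut_point)
    expect_equal(nchar(precursor_segment(p, "mature")), anc$mature_len)
  }
})
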