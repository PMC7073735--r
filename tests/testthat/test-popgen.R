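fam_from <- function(seqs, masks = NULL) {
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  if (is.null(masks)) masks <- list(whole = seq_len(nchar(seqs[1])))
  aligned_family(seqs, family = "f", species = "sp", region_masks = masks)
}

test_that("pi matches hand values and direct recomputation", {
  # two sequences differing at 1 of 10 ungapped sites
  f <- fam_from(c("ACGTACGTAC", "ACGTACGTAT"))
  d <- nucleotide_diversity(f)
  expect_equal(d$pi, 0.1)
  # identical sequences: pi = 0, SD = 0
  f2 <- fam_from(rep("ACGTACGTAC", 4))
  d2 <- nucleotide_diversity(f2)
  expect_equal(d2$pi, 0)
  expect_equal(d2$sd, 0)
  # random families vs the O(n^2 L) oracle
  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    base <- random_codon_string(20)
    seqs <- vapply(seq_len(n), function(j) mutate_codon_string(base, sample(1:6, 1)),
                   character(1))
    f3 <- fam_from(seqs)
    expect_equal(nucleotide_diversity(f3)$pi, oracle_pi(seqs))
  }
})

test_that("pi excludes gap/N columns under complete deletion and errors on singletons", {
  f <- fam_from(c("AC-TACGTAN", "ACGTACGTAT"))
  d <- nucleotide_diversity(f)
  expect_equal(d$sites, 8)
  expect_equal(d$pi, 0)
  expect_error(nucleotide_diversity(fam_from("ACGTACGTAC")), "singleton")
})

test_that("pi is invariant under reordering and increases when a mutant joins", {
  set.seed(32)
  base <- random_codon_string(25)
  seqs <- c(base, mutate_codon_string(base, 3), mutate_codon_string(base, 5))
  p1 <- nucleotide_diversity(fam_from(seqs))$pi
  p2 <- nucleotide_diversity(fam_from(rev(seqs)))$pi
  expect_equal(p1, p2)
  ident <- rep(base, 4)
  p_ident <- nucleotide_diversity(fam_from(ident))$pi
  p_plus <- nucleotide_diversity(fam_from(c(ident, mutate_codon_string(base, 2))))$pi
  expect_equal(p_ident, 0)
  expect_gt(p_plus, p_ident)
})

test_that("ts/tv pooling matches hand counts and brute-force tabulation", {
  # A<->G (ts), C<->T (ts), A<->T (tv): ratio 2
  f <- fam_from(c("AACAAAAAAA", "GATTAAAAAA"))
  tt <- ts_tv(f)
  expect_equal(c(tt$ts, tt$tv), c(2, 1))
  expect_equal(tt$ratio, 2)
  # only A<->G: tv = 0 -> undefined (serialized "-")
  f2 <- fam_from(c("AAAAAAAAAA", "GAAAAAAAAA"))
  expect_true(is.na(ts_tv(f2)$ratio))
  # brute force over random families
  purine <- c("A", "G")
  set.seed(33)
  for (i in 1:10) {
    base <- random_codon_string(15)
    seqs <- vapply(1:4, function(j) mutate_codon_string(base, sample(1:5, 1)),
                   character(1))
    f3 <- fam_from(seqs)
    tt3 <- ts_tv(f3)
    ts_brute <- 0; tv_brute <- 0
    m <- do.call(rbind, strsplit(seqs, ""))
    for (a in 1:3) for (b in (a + 1):4) for (k in seq_len(ncol(m))) {
      x <- m[a, k]; y <- m[b, k]
      if (x == y) next
      if ((x %in% purine) == (y %in% purine)) ts_brute <- ts_brute + 1
      else tv_brute <- tv_brute + 1
    }
    expect_equal(c(tt3$ts, tt3$tv), c(ts_brute, tv_brute))
  }
})

test_that("NG86 behaves on the textbook cases", {
  r <- ng86_pair("ATGAAA", "ATGAAA")
  expect_equal(c(r$Sd, r$Nd, r$dS, r$dN), c(0, 0, 0, 0))
  # Phe codon pair: one synonymous diff against S = 1/3 sites -> pS = 3
  expect_error(ng86_pair("TTT", "TTC"), "JC correction undefined")
  # per-codon site counts sum to 3
  for (cod in sample(oracle_sense_codons, 15)) {
    s <- ampevo:::codon_syn_sites(cod)
    expect_equal(s + (3 - s), 3)
    expect_equal(s, oracle_syn_sites(cod))
  }
})

test_that("NG86 counts equal the exhaustive pathway oracle on random pairs", {
  set.seed(34)
  for (i in 1:40) {
    s1 <- random_codon_string(12)
    s2 <- mutate_codon_string(s1, sample(1:5, 1))
    got <- tryCatch(suppressWarnings(ng86_pair(s1, s2)), error = function(e) NULL)
    if (is.null(got)) next
    want <- oracle_ng86(s1, s2)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    # Sd + Nd equals the differing ungapped site count (pathways conserved)
    diffs <- sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    expect_equal(got$Sd + got$Nd, diffs, tolerance = 1e-9)
  }
})

test_that("gapped and N codons are skipped pairwise in NG86", {
  r <- ng86_pair("ATG---AAA", "ATGAAGAAA")
  expect_equal(r$codons, 2)
  r2 <- ng86_pair("ATGNNNAAA", "ATGAAGAAA")
  expect_equal(r2$codons, 2)
})

test_that("family selection classifies against the neutral line and pools ts/tv", {
  cfg <- simulation_config(seed = 44, omega = 0.15, subs_per_seq = 12)
  set.seed(44)
  anc <- make_ancestor(cfg)
  res <- evolve_family(anc, cfg, n_members = 6)
  s <- family_selection(res$family)
  expect_setequal(s$region, c("propiece", "mature", "whole"))
  mature_row <- s[s$region == "mature", ]
  expect_true(mature_row$classification %in% c("below", "on", "above"))
  expect_true(is.na(s$dS[s$region == "whole"]))  # whole row is ts/tv only
  expect_error(family_selection(fam_from("ACGTACGTAC")), "singleton")
})
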