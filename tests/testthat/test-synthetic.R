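test_that("ancestors respect the architecture constraints", {
  cfg <- simulation_config(seed = 71)
  set.seed(71)
  for (i in 1:20) {
    anc <- make_ancestor(cfg)
    # truth is re-derivable from the emitted cDNA alone
    expect_equal(translate_dna(anc$nt, anc$frame), anc$aa)
    expect_false(grepl("\\*", anc$aa))
    # exactly one qualifying motif, at the cut
    chars <- strsplit(anc$aa, "")[[1]]
    expect_identical(ampevo:::motif_positions(chars), anc$cut_point - 1L)
    # charges follow the drawn counts
    mature <- substr(anc$aa, anc$cut_point + 1, nchar(anc$aa))
    expect_equal(net_charge_integer(mature), anc$mature_charge)
    expect_equal(nchar(mature), anc$mature_len)
  }
})

test_that("rho_length = -1 with zero jitter fixes the propiece+mature sum", {
  cfg <- simulation_config(seed = 72, rho_length = -1, length_jitter = 0)
  set.seed(72)
  sums <- replicate(10, {
    a <- make_ancestor(cfg)
    a$propiece_len + a$mature_len
  })
  expect_equal(length(unique(sums)), 1)
})

test_that("rho_length = -1 with jitter still fixes the sum (complement coupling)", {
  cfg <- simulation_config(seed = 73, rho_length = -1, length_jitter = 5)
  set.seed(73)
  draws <- replicate(30, {
    a <- make_ancestor(cfg)
    c(a$propiece_len + a$mature_len, a$mature_len)
  })
  expect_equal(length(unique(draws[1, ])), 1)
  expect_gt(length(unique(draws[2, ])), 1)
})

test_that("the sample length correlation tracks the configured target", {
  cfg <- simulation_config(seed = 74, rho_length = -0.8)
  set.seed(74)
  lens <- t(replicate(200, {
    a <- make_ancestor(cfg)
    c(a$propiece_len, a$mature_len)
  }))
  expect_lt(abs(cor(lens[, 1], lens[, 2]) - (-0.8)), 0.1)
})

test_that("pick_frame recovers the generator's frame on fresh ancestors", {
  cfg <- simulation_config(seed = 75)
  set.seed(75)
  hits <- 0
  for (i in 1:200) {
    anc <- make_ancestor(cfg)
    if (pick_frame(anc$nt)$frame == anc$frame) hits <- hits + 1
  }
  expect_equal(hits, 200)
})

test_that("zero substitutions give identical members and zero diversity", {
  cfg <- simulation_config(seed = 76, subs_per_seq = 0)
  set.seed(76)
  anc <- make_ancestor(cfg)
  res <- evolve_family(anc, cfg, n_members = 4)
  expect_equal(length(unique(res$family$seqs)), 1)
  expect_equal(nucleotide_diversity(res$family, "whole")$pi, 0)
})

test_that("expected diversity grows with the substitution load", {
  pis <- vapply(c(2, 6, 14), function(lambda) {
    cfg <- simulation_config(seed = 77, subs_per_seq = lambda)
    set.seed(77)
    mean(replicate(6, {
      anc <- make_ancestor(cfg)
      nucleotide_diversity(evolve_family(anc, cfg, n_members = 4)$family)$pi
    }))
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("higher kappa shifts the pooled ts/tv estimator upward", {
  pooled_tstv <- function(kappa, seed) {
    cfg <- simulation_config(seed = seed, kappa = kappa, subs_per_seq = 10)
    set.seed(seed)
    ts <- 0; tv <- 0
    for (i in 1:20) {
      anc <- make_ancestor(cfg)
      fam <- evolve_family(anc, cfg, n_members = 4)$family
      tt <- ts_tv(fam, "whole")
      ts <- ts + tt$ts; tv <- tv + tt$tv
    }
    ts / tv
  }
  expect_gt(pooled_tstv(8, 78), pooled_tstv(1, 78))
})

test_that("segmentation recovers the true cut point on evolved members", {
  cfg <- simulation_config(seed = 79, subs_per_seq = 8)
  set.seed(79)
  total <- 0; hits <- 0
  for (i in 1:20) {
    anc <- make_ancestor(cfg)
    res <- evolve_family(anc, cfg, n_members = 4)
    for (j in seq_along(res$family$seqs)) {
      p <- build_precursor(amp_record("x", res$family$seqs[[j]], "sp", "fam"))
      total <- total + 1
      if (!is.null(p) && p$cut_point == anc$cut_point) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("gold datasets are deterministic and carry 14+7+13 families", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- simulation_config(seed = 80, members_per_family = 2:4, subs_per_seq = 3)
  g1 <- gold_dataset(cfg, d1)
  g2 <- gold_dataset(cfg, d2)
  expect_identical(readLines(g1$fasta), readLines(g2$fasta))
  expect_identical(readLines(g1$truth_file), readLines(g2$truth_file))
  expect_equal(length(unique(g1$truth$family)), 34)
  expect_equal(length(unique(g1$truth$species)), 3)
  # truth is re-derivable from the emitted FASTA
  recs <- read_fasta(g1$fasta)
  expect_equal(length(recs), nrow(g1$truth))
  r1 <- recs[[1]]
  row <- g1$truth[g1$truth$id == r1$id, ]
  p <- build_precursor(r1)
  expect_equal(p$cut_point, row$cut_point)
})
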