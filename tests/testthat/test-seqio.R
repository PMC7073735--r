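test_that("FASTA reading normalizes case and RNA and parses the header dialect", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x|SpeciesA|famZ", "acgt", ">y", "ACGU"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$nt, "ACGT")
  expect_equal(recs[[1]]$species, "SpeciesA")
  expect_equal(recs[[1]]$family, "famZ")
  expect_equal(recs[[2]]$nt, "ACGT")
  expect_equal(recs[[2]]$species, "")
})

test_that("FASTA round trip is byte-faithful for normalized records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- list(amp_record("a1", "ACGTACGTNACGT", "Sp1", "famA"),
               amp_record("b2", "TTTTGGGGCCCC", "Sp2", "famB"))
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "nt"), lapply(recs, `[[`, "nt"))
  expect_equal(lapply(back, `[[`, "id"), lapply(recs, `[[`, "id"))
  expect_equal(lapply(back, `[[`, "family"), lapply(recs, `[[`, "family"))
})

test_that("invalid characters and empty files are rejected with the record named", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "ACGTZ"), f)
  expect_error(read_fasta(f), "bad")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  file.create(f2)
  expect_error(read_fasta(f2))
})

make_genbank_chunk <- function(id, organism, seq, features = character()) {
  c(sprintf("LOCUS       %s             %d bp    mRNA    linear", id, nchar(seq)),
    sprintf("ACCESSION   %s", id),
    "  ORGANISM  " %+% organism,
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    paste("        1", tolower(seq)),
    "//")
}
`%+%` <- function(a, b) paste0(a, b)

test_that("GenBank flat files parse coordinates, organisms and tolerate absent features", {
  f <- withr::local_tempfile(fileext = ".gb")
  seq1 <- paste(rep("ACGT", 10), collapse = "")
  chunk1 <- make_genbank_chunk("AB000001", "Rana synthetica", seq1,
                               c("     CDS             1..39",
                                 "     mat_peptide     10..30"))
  chunk2 <- make_genbank_chunk("AB000002", "Rana synthetica", seq1)
  chunk3 <- make_genbank_chunk("AB000003", "Pelophylax syntheticus", seq1,
                               "     sig_peptide     1..9")
  writeLines(c(chunk1, chunk2, chunk3), f)
  recs <- read_genbank_flat(f)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, character(1), "id"),
               c("AB000001", "AB000002", "AB000003"))
  expect_equal(recs[[1]]$species, "Rana synthetica")
  mat <- recs[[1]]$features[recs[[1]]$features$key == "mat_peptide", ]
  expect_equal(c(mat$start, mat$end), c(10, 30))
  expect_equal(nrow(recs[[2]]$features), 0)
  expect_equal(recs[[1]]$nt, seq1)
})

test_that("GenBank parsing errors on missing ORIGIN and out-of-range features", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X1  10 bp", "//"), f)
  expect_error(read_genbank_flat(f), "ORIGIN")
  f2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_genbank_chunk("X2", "Rana synthetica", "ACGTACGT",
                                "     mat_peptide     2..400"), f2)
  expect_error(read_genbank_flat(f2), "beyond")
})

test_that("metadata join fills labels, prefers the table, and flags strays", {
  recs <- list(amp_record("a", "ACGT"), amp_record("b", "ACGT", "SpX", "famOld"))
  tab <- data.frame(id = c("a", "b", "ghost"),
                    species = c("Sp1", "Sp2", "Sp3"),
                    family = c("famA", "famB", "famC"),
                    stringsAsFactors = FALSE)
  expect_warning(out <- suppressMessages(join_metadata(recs, tab)), "ghost")
  expect_equal(out[[1]]$family, "famA")
  expect_message(join_metadata(recs[2], tab[2, ]), "overridden")
  expect_equal(suppressMessages(join_metadata(recs[2], tab[2, ]))[[1]]$family, "famB")
})

test_that("strict metadata join requires a family for every record", {
  recs <- list(amp_record("a", "ACGT"))
  tab <- data.frame(id = "a", species = "Sp1", family = "", stringsAsFactors = FALSE)
  expect_error(join_metadata(recs, tab, strict = TRUE), "no family")
  out <- join_metadata(recs, tab, strict = FALSE)
  expect_equal(out[[1]]$family, "")
})

test_that("Newick round trip preserves topology, lengths and supports", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.2)0.87:0.05,(C:0.3,D:0.1)0.92:0.07,E:0.4);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(back)), 0)
  expect_equal(sort(back$edge.length), sort(round(tree$edge.length, 6)))
  expect_true("0.87" %in% back$node.label)
})
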