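# Reading and writing of sequence data, metadata and trees.
#
# Internal conventions: sequences are uppercase DNA strings over {A,C,G,T,N};
# feature and segment coordinates are 1-based inclusive (R's native indexing);
# GenBank coordinates are already 1-based inclusive so no conversion is needed
# at that boundary.

.valid_feature_keys <- c("sig_peptide", "propeptide", "mat_peptide", "CDS")

#' Construct a sequence record
#'
#' The atomic unit of the pipeline: one cloned precursor cDNA with its
#' identifier, species and family labels and any annotated features.
#'
#' @param id Unique identifier (e.g. a GenBank accession).
#' @param nt DNA string; lowercase and RNA (`U`) input are normalized.
#' @param species,family Metadata labels; may be empty strings before a
#'   metadata table is joined.
#' @param features A data frame with columns `key`, `start`, `end`, `note`
#'   (1-based inclusive coordinates on `nt`), or `NULL` for none.
#' @return An object of class `amp_record`.
#' @export
amp_record <- function(id, nt, species = "", family = "", features = NULL) {
  nt <- normalize_nt(nt, id = id)
  if (is.null(features)) {
    features <- data.frame(key = character(), start = integer(),
                           end = integer(), note = character(),
                           stringsAsFactors = FALSE)
  }
  if (nrow(features)) {
    stopifnot(all(features$key %in% .valid_feature_keys))
    if (any(features$start < 1L | features$end > nchar(nt) |
            features$start > features$end)) {
      stop("feature coordinates outside sequence bounds in record '", id, "'")
    }
  }
  structure(list(id = id, species = species, family = family,
                 nt = nt, features = features),
            class = "amp_record")
}

#' @export
print.amp_record <- function(x, ...) {
  cat(sprintf("<amp_record %s> %s / %s, %d nt, %d feature(s)\n",
              x$id, x$species, x$family, nchar(x$nt), nrow(x$features)))
  invisible(x)
}

# Uppercase, map RNA U to T, and reject anything outside {A,C,G,T,N}.
normalize_nt <- function(nt, id = "?") {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- chartr("u", "t", toupper(nt))
  nt <- chartr("U", "T", nt)
  if (!nzchar(nt)) stop("empty sequence in record '", id, "'")
  bad <- setdiff(strsplit(nt, "")[[1]], c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("record '", id, "' contains invalid characters: ",
         paste(unique(bad), collapse = ", "))
  }
  nt
}

#' Read precursor cDNAs from a FASTA file
#'
#' Headers may follow the self-describing dialect `id|species|family`, or be
#' a bare id (metadata joined later with [join_metadata()]). Sequences are
#' uppercased and RNA `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @return A list of [amp_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  if (!length(seqs)) stop("empty FASTA file: ", path)
  lapply(seq_along(seqs), function(i) {
    header <- attr(seqs[[i]], "name")
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    amp_record(id = trimws(parts[1]),
               nt = as.character(seqs[[i]]),
               species = if (length(parts) >= 2) trimws(parts[2]) else "",
               family  = if (length(parts) >= 3) trimws(parts[3]) else "")
  })
}

#' Write records to FASTA
#'
#' Emits the `id|species|family` header dialect when metadata is present,
#' otherwise a bare id, so that `read_fasta(write_fasta(x))` round-trips.
#'
#' @param records List of `amp_record` objects.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  headers <- vapply(records, function(r) {
    if (nzchar(r$species) || nzchar(r$family)) {
      paste(r$id, r$species, r$family, sep = "|")
    } else r$id
  }, character(1))
  seqinr::write.fasta(lapply(records, function(r) seqinr::s2c(r$nt)),
                      names = headers, file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a minimal GenBank flat file
#'
#' Parses the subset of the GenBank format the pipeline needs: `LOCUS`,
#' `ORGANISM` (taken as the species), `FEATURES` entries with keys
#' `sig_peptide`, `propeptide`, `mat_peptide` or `CDS` and simple
#' `start..end` locations, and the `ORIGIN` sequence block. Multiple
#' concatenated records (separated by `//`) are supported.
#'
#' @param path Path to a GenBank flat file.
#' @return A list of [amp_record()] objects in file order.
#' @export
read_genbank_flat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0L, which(trimws(lines) == "//"))
  if (length(breaks) == 1L) breaks <- c(0L, length(lines))
  records <- list()
  for (k in seq_len(length(breaks) - 1L)) {
    chunk <- lines[(breaks[k] + 1L):breaks[k + 1L]]
    chunk <- chunk[nzchar(trimws(chunk))]
    if (!length(chunk)) next
    records[[length(records) + 1L]] <- parse_genbank_record(chunk)
  }
  if (!length(records)) stop("no GenBank records found in ", path)
  records
}

parse_genbank_record <- function(chunk) {
  locus_line <- grep("^LOCUS", chunk, value = TRUE)
  id <- if (length(locus_line)) strsplit(trimws(sub("^LOCUS", "", locus_line[1])),
                                         "\\s+")[[1]][1] else "?"
  acc_line <- grep("^ACCESSION", chunk, value = TRUE)
  if (length(acc_line)) {
    id <- strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  }
  org_line <- grep("^\\s+ORGANISM", chunk, value = TRUE)
  species <- if (length(org_line)) trimws(sub("^\\s+ORGANISM", "", org_line[1])) else ""

  origin_at <- grep("^ORIGIN", chunk)
  if (!length(origin_at)) stop("record '", id, "' has no ORIGIN block")
  seq_lines <- chunk[(origin_at[1] + 1L):length(chunk)]
  seq_lines <- seq_lines[trimws(seq_lines) != "//"]
  nt <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))

  feat_at <- grep("^FEATURES", chunk)
  features <- data.frame(key = character(), start = integer(),
                         end = integer(), note = character(),
                         stringsAsFactors = FALSE)
  if (length(feat_at)) {
    feat_lines <- chunk[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    pat <- paste0("^\\s{2,}(", paste(.valid_feature_keys, collapse = "|"),
                  ")\\s+[<>]?(\\d+)\\.\\.[<>]?(\\d+)")
    hits <- regmatches(feat_lines, regexec(pat, feat_lines))
    for (h in hits) {
      if (length(h) == 4L) {
        features <- rbind(features, data.frame(
          key = h[2], start = as.integer(h[3]), end = as.integer(h[4]),
          note = "", stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(features) && any(features$end > nchar(nt))) {
    stop("record '", id, "' has feature coordinates beyond the sequence")
  }
  amp_record(id = id, nt = nt, species = species, features = features)
}

#' Join species/family metadata onto records
#'
#' @param records List of `amp_record` objects.
#' @param table Data frame with columns `id`, `species`, `family`, or a path
#'   to a TSV with those columns.
#' @param strict If `TRUE`, a record with no family label after the join is
#'   an error; otherwise the empty label is retained.
#' @return The records with metadata filled in. The table takes precedence
#'   over labels already on a record; each overwrite is reported as a
#'   warning-free message.
#' @export
join_metadata <- function(records, table, strict = FALSE) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "species", "family") %in% names(table)))
  ids <- vapply(records, `[[`, character(1), "id")
  missing_recs <- setdiff(table$id, ids)
  if (length(missing_recs)) {
    warning("metadata rows with no matching record: ",
            paste(missing_recs, collapse = ", "))
  }
  records <- lapply(records, function(r) {
    row <- match(r$id, table$id)
    if (!is.na(row)) {
      for (fld in c("species", "family")) {
        new <- as.character(table[[fld]][row])
        if (nzchar(r[[fld]]) && r[[fld]] != new) {
          message("record '", r$id, "': ", fld, " '", r[[fld]],
                  "' overridden by metadata table value '", new, "'")
        }
        r[[fld]] <- new
      }
    }
    r
  })
  if (strict) {
    unlabeled <- ids[!vapply(records, function(r) nzchar(r$family), logical(1))]
    if (length(unlabeled)) {
      stop("records with no family after metadata join: ",
           paste(unlabeled, collapse = ", "))
    }
  }
  records
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are written to 6 decimals and internal-node supports (the
#' tree's `node.label`) are kept as internal labels.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- round(tree$edge.length, 6)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

# Write a report table as TSV with "-"/"/" conventions already applied by
# the caller.
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
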