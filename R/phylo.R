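# Distance-based phylogenetics for family clustering: Kimura two-parameter
# distances, neighbor-joining, Felsenstein bootstrap and transfer bootstrap
# expectation (TBE) supports, and monophyly checks.

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q))` with `P` the transition and
#' `Q` the transversion proportion over comparable sites (pairwise deletion
#' of gap/`N` sites).
#'
#' @param s1,s2 Aligned DNA strings of equal length.
#' @return The K2P distance.
#' @export
k2p_distance <- function(s1, s2) {
  stopifnot(nchar(s1) == nchar(s2))
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / L
  Q <- sum(diff & !is_transition(a, b)) / L
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) stop("distance saturated: log argument <= 0")
  -0.5 * log(arg1 * sqrt(arg2))
}

#' K2P distance matrix for a set of aligned sequences
#'
#' @param seqs Named character vector of equal-length DNA strings.
#' @return A symmetric matrix with zero diagonal, labeled by sequence name.
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(seqs[[i]], seqs[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`); negative branch lengths are
#' clamped to zero and the total clamped deficit recorded in the
#' `"clamped_deficit"` attribute.
#'
#' @param d Symmetric distance matrix with at least 3 labeled taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(diag(d) == 0), all(is.finite(d)))
  tree <- ape::nj(as.dist(d))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_deficit") <- deficit
  tree
}

# All non-trivial bipartitions of an unrooted tree as logical membership
# vectors over a fixed leaf order; trivial (leaf) splits optionally kept.
tree_splits <- function(tree, leaf_order, include_trivial = FALSE) {
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, leaf_order)
  stopifnot(!anyNA(idx))
  splits <- list()
  internal <- (n + 2L):(n + tree$Nnode)   # root excluded (its split is trivial)
  if (tree$Nnode >= 2L) {
    desc <- phangorn::Descendants(tree, internal, type = "tips")
    for (k in seq_along(internal)) {
      v <- logical(length(leaf_order))
      v[idx[desc[[k]]]] <- TRUE
      splits[[length(splits) + 1L]] <- v
    }
  }
  if (include_trivial) {
    for (i in seq_len(n)) {
      v <- logical(length(leaf_order))
      v[idx[i]] <- TRUE
      splits[[length(splits) + 1L]] <- v
    }
  }
  splits
}

# Canonical key of a split (orientation-free) for set comparisons.
split_key <- function(v) {
  if (v[1]) v <- !v
  paste(as.integer(v), collapse = "")
}

# Minimum transfer distance from split v to any branch of the replicate
# split set (logical vectors over the same leaf order).
transfer_distance <- function(v, rep_splits) {
  best <- min(sum(v), sum(!v))  # distance to a trivial split bound
  for (w in rep_splits) {
    d <- min(sum(v != w), sum(v == w))
    if (d < best) best <- d
    if (best == 0L) break
  }
  best
}

#' Bootstrap branch supports for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement; each replicate
#' is re-analyzed with the same distance + NJ pipeline. Felsenstein support
#' of a branch is the fraction of replicate trees containing its
#' bipartition; TBE support is `1 - mean(delta / (p - 1))` where `delta` is
#' the minimum transfer distance of the bipartition to any branch of the
#' replicate and `p` is the smaller side of the bipartition. Branches with
#' `p = 1` have support fixed at 1.
#'
#' @param seqs Named character vector of equal-length aligned DNA strings.
#' @param reps Number of bootstrap replicates.
#' @param mode `"tbe"` or `"felsenstein"`.
#' @param seed Integer RNG seed (required: supports are deterministic given
#'   the seed).
#' @param threshold Supports below this value (on the 0-1 scale) are hidden
#'   (`NA`) in the returned tree's node labels; use 0 to keep all.
#' @return The reference NJ tree with `node.label` carrying supports scaled
#'   0-100, plus a `"support_table"` attribute (one row per internal
#'   branch, with both support flavors).
#' @export
bootstrap_supports <- function(seqs, reps = 100L, mode = c("tbe", "felsenstein"),
                               seed, threshold = 0) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1L, !missing(seed))
  leaf_order <- names(seqs)
  ref_tree <- neighbor_joining(k2p_matrix(seqs))
  ref_splits <- tree_splits(ref_tree, leaf_order)
  L <- unique(nchar(seqs))

  set.seed(as.integer(seed))
  rep_split_sets <- vector("list", reps)
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot_seqs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    tr <- tryCatch(neighbor_joining(k2p_matrix(boot_seqs)),
                   error = function(e) NULL)
    rep_split_sets[[r]] <- if (is.null(tr)) list() else
      tree_splits(tr, leaf_order, include_trivial = TRUE)
  }

  n_ref <- length(ref_splits)
  fels <- numeric(n_ref); tbe <- numeric(n_ref)
  for (k in seq_len(n_ref)) {
    v <- ref_splits[[k]]
    p <- min(sum(v), sum(!v))
    if (p <= 1L) { fels[k] <- 1; tbe[k] <- 1; next }
    key <- split_key(v)
    present <- 0L; dist_sum <- 0
    for (r in seq_len(reps)) {
      keys <- vapply(rep_split_sets[[r]], split_key, character(1))
      if (key %in% keys) present <- present + 1L
      dist_sum <- dist_sum + transfer_distance(v, rep_split_sets[[r]])
    }
    fels[k] <- present / reps
    tbe[k] <- 1 - (dist_sum / reps) / (p - 1)
  }

  support <- if (mode == "tbe") tbe else fels
  shown <- ifelse(support >= threshold, round(100 * support), NA)
  # map splits back to internal nodes (tree_splits enumerates nodes root+1..)
  nlab <- rep(NA_real_, ref_tree$Nnode)
  if (n_ref) nlab[2:ref_tree$Nnode] <- shown
  ref_tree$node.label <- ifelse(is.na(nlab), "", as.character(nlab))
  attr(ref_tree, "support_table") <- data.frame(
    split = vapply(ref_splits, split_key, character(1)),
    p = vapply(ref_splits, function(v) min(sum(v), sum(!v)), numeric(1)),
    felsenstein = fels, tbe = tbe, stringsAsFactors = FALSE)
  ref_tree
}

#' Is a set of leaves monophyletic in an unrooted tree?
#'
#' `TRUE` iff some branch of the tree splits exactly the given label set
#' from the rest.
#'
#' @param tree An `ape::phylo` tree.
#' @param labels Subset of the tree's tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  v <- tips %in% labels
  if (all(v) || sum(v) == 1L) return(TRUE)
  target <- split_key(v)
  splits <- tree_splits(tree, tips, include_trivial = FALSE)
  any(vapply(splits, split_key, character(1)) == target)
}
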