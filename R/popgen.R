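# Per-family, per-region molecular-evolution statistics: nucleotide
# diversity (pi) with Nei's sampling variance, pooled transition/
# transversion ratios, and Nei-Gojobori (NG86) dN/dS counting with
# Jukes-Cantor correction.

.codon_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    bases <- c("T", "C", "A", "G")
    codons <- apply(expand.grid(bases, bases, bases, stringsAsFactors = FALSE),
                    1, paste, collapse = "")
    aa <- vapply(codons,
                 function(cd) seqinr::translate(seqinr::s2c(cd)),
                 character(1))
    names(aa) <- codons
    .codon_env$tab <- aa
  }
  .codon_env$tab
}

is_stop_codon <- function(codon) unname(codon_table()[codon] == "*")

#' Construct an aligned family
#'
#' Gap-aware, equal-length nucleotide sequences of one AMP family, with
#' per-region column masks. Masks used for codon statistics must cover
#' whole in-frame codons.
#'
#' @param seqs Named character vector of equal-length DNA strings over
#'   `{A,C,G,T,N,-}`.
#' @param family,species Labels.
#' @param region_masks Named list of integer column vectors, conventionally
#'   `propiece`, `mature` and `whole`.
#' @return An object of class `aligned_family`.
#' @export
aligned_family <- function(seqs, family = "", species = "",
                           region_masks = list()) {
  stopifnot(length(seqs) >= 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  L <- lens[1]
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) stop("invalid alignment characters: ", paste(bad, collapse = ","))
  for (m in region_masks) {
    stopifnot(all(m >= 1L), all(m <= L))
  }
  if (!length(region_masks)) region_masks <- list(whole = seq_len(L))
  structure(list(seqs = seqs, family = family, species = species,
                 region_masks = region_masks, length = L,
                 n = length(seqs)),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("<aligned_family %s> %s, n = %d, %d columns, regions: %s\n",
              x$family, x$species, x$n, x$length,
              paste(names(x$region_masks), collapse = ", ")))
  invisible(x)
}

family_matrix <- function(fam, region) {
  mask <- fam$region_masks[[region]]
  if (is.null(mask)) stop("unknown region '", region, "'")
  m <- do.call(rbind, strsplit(unname(fam$seqs), ""))
  m[, mask, drop = FALSE]
}

#' Nucleotide diversity of a family region
#'
#' Mean pairwise differences per site after complete deletion of columns
#' containing gaps or `N` within the region (pairwise deletion optional).
#' The standard deviation is the square root of Nei's (1987) sampling
#' variance of pi, with no recombination correction:
#' `V = (n+1) pi / (3 (n-1) L) + 2 (n^2+n+3) pi^2 / (9 n (n-1))`.
#'
#' @param fam An [aligned_family()].
#' @param region Region mask name (default `"whole"`).
#' @param deletion `"complete"` (default) drops every column containing a
#'   gap or `N`; `"pairwise"` drops such sites per sequence pair.
#' @return A list of class `diversity_result`: `pi`, `sd`, `n`, `sites`.
#' @export
nucleotide_diversity <- function(fam, region = "whole",
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (fam$n < 2L) stop("singleton family: nucleotide diversity undefined")
  m <- family_matrix(fam, region)
  if (deletion == "complete") {
    keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    m <- m[, keep, drop = FALSE]
    L <- ncol(m)
    if (L < 1L) stop("no columns left after complete deletion")
    n <- fam$n
    total <- 0
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        total <- total + sum(m[i, ] != m[j, ]) / L
      }
    }
    pi_hat <- 2 * total / (n * (n - 1))
    sites <- L
  } else {
    n <- fam$n
    props <- c()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
        if (!any(ok)) stop("no comparable sites for a pair under pairwise deletion")
        props <- c(props, sum(m[i, ok] != m[j, ok]) / sum(ok))
      }
    }
    pi_hat <- mean(props)
    sites <- ncol(m)
  }
  v <- (fam$n + 1) * pi_hat / (3 * (fam$n - 1) * sites) +
    2 * (fam$n^2 + fam$n + 3) * pi_hat^2 / (9 * fam$n * (fam$n - 1))
  structure(list(pi = pi_hat, sd = sqrt(v), n = fam$n, sites = sites),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("pi = %.3f +/- %.3f (n = %d, %d sites)\n",
              x$pi, x$sd, x$n, x$sites))
  invisible(x)
}

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

is_transition <- function(a, b) {
  (a %in% .purines & b %in% .purines) | (a %in% .pyrimidines & b %in% .pyrimidines)
}

#' Pooled transition/transversion ratio of a family region
#'
#' Transition and transversion difference counts are pooled over all
#' sequence pairs (pairwise deletion of gap/`N` sites); the ratio is
#' `sum(ts)/sum(tv)`, or `NA` when no transversions were observed (the
#' report serializes that as `"-"`).
#'
#' @param fam An [aligned_family()].
#' @param region Region mask name.
#' @return A list with `ts`, `tv` (pooled counts) and `ratio` (`NA` if
#'   `tv == 0`).
#' @export
ts_tv <- function(fam, region = "whole") {
  if (fam$n < 2L) stop("singleton family: ts/tv undefined")
  m <- family_matrix(fam, region)
  ts <- 0L; tv <- 0L
  n <- fam$n
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
      diff <- ok & m[i, ] != m[j, ]
      if (!any(diff)) next
      tr <- is_transition(m[i, diff], m[j, diff])
      ts <- ts + sum(tr)
      tv <- tv + sum(!tr)
    }
  }
  list(ts = ts, tv = tv, ratio = if (tv == 0L) NA_real_ else ts / tv)
}

# Synonymous site count of one codon: at each position, the fraction of
# non-stop single-nucleotide neighbors that leave the amino acid unchanged.
# Each position contributes one site, so s + n = 3 per codon.
# Cached: the 61 sense codons recur in every pair of every family.
codon_syn_sites <- function(codon) {
  cache <- .codon_env$syn_sites
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .codon_env$syn_sites <- cache
  }
  hit <- cache[[codon]]
  if (!is.null(hit)) return(hit)
  val <- codon_syn_sites_calc(codon)
  assign(codon, val, envir = cache)
  val
}

codon_syn_sites_calc <- function(codon) {
  tab <- codon_table()
  if (tab[codon] == "*") stop("stop codon has no site counts")
  chars <- strsplit(codon, "")[[1]]
  bases <- c("T", "C", "A", "G")
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(bases, chars[pos])
    neigh <- vapply(alts, function(b) {
      tmp <- chars; tmp[pos] <- b; paste(tmp, collapse = "")
    }, character(1))
    keep <- !is_stop_codon(neigh)
    if (!any(keep)) next
    s <- s + mean(tab[neigh[keep]] == tab[codon])
  }
  s
}

# Synonymous/nonsynonymous difference counts between two codons, averaging
# over all orderings of the single-nucleotide changes and excluding
# pathways that pass through a stop codon.
codon_path_counts <- function(c1, c2) {
  cache <- .codon_env$path_counts
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .codon_env$path_counts <- cache
  }
  key <- paste0(c1, c2)
  hit <- cache[[key]]
  if (!is.null(hit)) return(if (identical(hit, "stops")) NULL else hit)
  val <- codon_path_counts_calc(c1, c2)
  assign(key, if (is.null(val)) "stops" else val, envir = cache)
  val
}

codon_path_counts_calc <- function(c1, c2) {
  tab <- codon_table()
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- all_permutations(diff_pos)
  tot_s <- 0; tot_n <- 0; valid <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- ch1
    s <- 0L; n <- 0L; ok <- TRUE
    for (pos in perms[p, ]) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      cod_from <- paste(cur, collapse = "")
      cod_to <- paste(nxt, collapse = "")
      if (tab[cod_to] == "*") { ok <- FALSE; break }
      if (tab[cod_from] == tab[cod_to]) s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    if (ok) {
      tot_s <- tot_s + s; tot_n <- tot_n + n; valid <- valid + 1L
    }
  }
  if (valid == 0L) return(NULL)  # all pathways pass through stops
  c(sd = tot_s / valid, nd = tot_n / valid)
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, nrow = 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) counts and distances for one sequence pair
#'
#' Synonymous site fractions per codon come from all single-nucleotide
#' neighbors (stop-codon neighbors excluded, with the position's one site
#' apportioned over the remainder); codons differing at several positions
#' are averaged over all orderings of the changes, excluding pathways
#' through stop codons. Sites are averaged between the two sequences and
#' proportions are Jukes-Cantor corrected: `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param s1,s2 In-frame DNA strings of equal length, a multiple of 3, with
#'   no internal stop codons. Codons containing gaps or `N` in either
#'   sequence are skipped pairwise.
#' @return A list with `S`, `N` (site counts averaged over the two
#'   sequences), `Sd`, `Nd` (counted differences), `pS`, `pN`, `dS`, `dN`
#'   and `codons` (codons compared).
#' @export
ng86_pair <- function(s1, s2) {
  stopifnot(nchar(s1) == nchar(s2), nchar(s1) %% 3 == 0)
  n_codons <- nchar(s1) / 3
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; compared <- 0L
  for (k in seq_len(n_codons)) {
    c1 <- substr(s1, 3 * k - 2, 3 * k)
    c2 <- substr(s2, 3 * k - 2, 3 * k)
    ok <- grepl("^[ACGT]{3}$", c1) && grepl("^[ACGT]{3}$", c2)
    if (!ok) next
    if (is_stop_codon(c1) || is_stop_codon(c2)) {
      stop("internal stop codon at codon ", k)
    }
    counts <- codon_path_counts(c1, c2)
    if (is.null(counts)) {
      warning("codon ", k, " skipped: all mutational pathways pass through stops")
      next
    }
    S1 <- S1 + codon_syn_sites(c1)
    S2 <- S2 + codon_syn_sites(c2)
    Sd <- Sd + counts[["sd"]]
    Nd <- Nd + counts[["nd"]]
    compared <- compared + 1L
  }
  if (compared == 0L) stop("no comparable codons")
  S <- (S1 + S2) / 2
  N <- 3 * compared - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 0.75 || pN >= 0.75) stop("JC correction undefined: p >= 3/4")
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = -0.75 * log(1 - 4 * pS / 3), dN = -0.75 * log(1 - 4 * pN / 3),
       codons = compared)
}

#' Per-region selection summary for one family
#'
#' Family `dN` and `dS` are unweighted means of [ng86_pair()] over all
#' sequence pairs (pairs whose correction is undefined are dropped; a
#' region where every pair fails is reported as undefined). Classification
#' against the neutral line uses a 1e-12 tolerance: `"above"` when
#' `dN > dS`, `"below"` when `dN < dS`, `"on"` otherwise. Pooled ts/tv is
#' reported for each codon region and for the whole alignment.
#'
#' @param fam An [aligned_family()] whose `propiece` and `mature` masks
#'   cover whole in-frame codons.
#' @param regions Codon regions to summarize (default propiece and mature).
#' @return A data frame of class `selection_summary`, one row per region
#'   (plus a `whole` ts/tv-only row), with columns family, region, n, S, N,
#'   Sd, Nd, dS, dN, omega, classification, ts, tv, ts_tv.
#' @export
family_selection <- function(fam, regions = c("propiece", "mature")) {
  if (fam$n < 2L) stop("singleton family: selection summary undefined")
  rows <- list()
  for (region in regions) {
    mask <- fam$region_masks[[region]]
    if (is.null(mask)) stop("unknown region '", region, "'")
    if (length(mask) %% 3 != 0) stop("region '", region, "' is not codon-aligned")
    m <- family_matrix(fam, region)
    seqs <- apply(m, 1, paste, collapse = "")
    pairs <- utils::combn(fam$n, 2)
    res <- list()
    for (p in seq_len(ncol(pairs))) {
      r <- tryCatch(ng86_pair(seqs[pairs[1, p]], seqs[pairs[2, p]]),
                    error = function(e) NULL)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
    tt <- ts_tv(fam, region)
    if (!length(res)) {
      rows[[region]] <- data.frame(
        family = fam$family, region = region, n = fam$n,
        S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
        dS = NA_real_, dN = NA_real_, omega = NA_real_,
        classification = NA_character_,
        ts = tt$ts, tv = tt$tv, ts_tv = tt$ratio, stringsAsFactors = FALSE)
      next
    }
    mean_of <- function(fld) mean(vapply(res, `[[`, numeric(1), fld))
    dS <- mean_of("dS"); dN <- mean_of("dN")
    omega <- if (dS <= 1e-12) NA_real_ else dN / dS
    classification <- if (dN > dS + 1e-12) "above"
      else if (dN < dS - 1e-12) "below" else "on"
    rows[[region]] <- data.frame(
      family = fam$family, region = region, n = fam$n,
      S = mean_of("S"), N = mean_of("N"), Sd = mean_of("Sd"), Nd = mean_of("Nd"),
      dS = dS, dN = dN, omega = omega, classification = classification,
      ts = tt$ts, tv = tt$tv, ts_tv = tt$ratio, stringsAsFactors = FALSE)
  }
  if ("whole" %in% names(fam$region_masks)) {
    tt <- ts_tv(fam, "whole")
    rows[["whole"]] <- data.frame(
      family = fam$family, region = "whole", n = fam$n,
      S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
      dS = NA_real_, dN = NA_real_, omega = NA_real_,
      classification = NA_character_,
      ts = tt$ts, tv = tt$tv, ts_tv = tt$ratio, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("selection_summary", class(out))
  out
}
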