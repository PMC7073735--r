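# Independent oracles used across the test suite. Each is a deliberately
# plain re-derivation from first principles, sharing no code with the
# package implementation.

# --- genetic code, written out independently (standard table 1) ----------
oracle_genetic_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_sense_codons <- names(oracle_genetic_code)[oracle_genetic_code != "*"]

# --- NG86 oracle: exhaustive neighbor and pathway enumeration ------------
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_genetic_code[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; usable <- 0
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      neigh <- codon
      substr(neigh, pos, pos) <- b
      if (oracle_genetic_code[[neigh]] == "*") next
      usable <- usable + 1
      if (oracle_genetic_code[[neigh]] == aa) syn <- syn + 1
    }
    if (usable > 0) s <- s + syn / usable
  }
  s
}

# All orderings of the differing positions, dropping pathways through
# stops; returns c(sd, nd) averaged over valid pathways, or NULL.
oracle_path_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diff_pos)) return(c(0, 0))
  orderings <- if (length(diff_pos) == 1) list(diff_pos) else {
    perms <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { perms[[length(perms) + 1]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(), diff_pos)
    perms
  }
  sds <- c(); nds <- c()
  for (ord in orderings) {
    cur <- c1; s <- 0; n <- 0; dead <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (oracle_genetic_code[[nxt]] == "*") { dead <- TRUE; break }
      if (oracle_genetic_code[[cur]] == oracle_genetic_code[[nxt]]) s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    if (!dead) { sds <- c(sds, s); nds <- c(nds, n) }
  }
  if (!length(sds)) return(NULL)
  c(mean(sds), mean(nds))
}

oracle_ng86 <- function(s1, s2) {
  ncod <- nchar(s1) / 3
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (k in seq_len(ncod)) {
    c1 <- substr(s1, 3 * k - 2, 3 * k)
    c2 <- substr(s2, 3 * k - 2, 3 * k)
    if (!grepl("^[ACGT]+$", c1) || !grepl("^[ACGT]+$", c2)) next
    counts <- oracle_path_counts(c1, c2)
    if (is.null(counts)) next
    S1 <- S1 + oracle_syn_sites(c1)
    S2 <- S2 + oracle_syn_sites(c2)
    Sd <- Sd + counts[1]; Nd <- Nd + counts[2]
    used <- used + 1
  }
  list(S = (S1 + S2) / 2, N = 3 * used - (S1 + S2) / 2, Sd = Sd, Nd = Nd)
}

# --- nucleotide diversity: direct O(n^2 L) recomputation -----------------
oracle_pi <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  acc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    acc <- acc + sum(m[i, ] != m[j, ]) / L
  }
  acc / choose(n, 2)
}

# --- pI: fine grid search on an independently coded charge function ------
oracle_charge <- function(aa, pH) {
  ch <- strsplit(aa, "")[[1]]
  pos <- c(K = 10.0, R = 12.0, H = 5.98)
  neg <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ct <- c(D = 4.55, E = 4.75)
  q <- 0
  for (r in names(pos)) q <- q + sum(ch == r) / (1 + 10^(pH - pos[[r]]))
  for (r in names(neg)) q <- q - sum(ch == r) / (1 + 10^(neg[[r]] - pH))
  ntp <- if (ch[1] %in% names(nt)) nt[[ch[1]]] else 7.5
  ctp <- if (ch[length(ch)] %in% names(ct)) ct[[ch[length(ch)]]] else 3.55
  q + 1 / (1 + 10^(pH - ntp)) - 1 / (1 + 10^(ctp - pH))
}

oracle_pi_grid <- function(aa, step = 0.001) {
  grid <- seq(0, 14, by = step)
  # vectorized over pH for speed; same arithmetic as oracle_charge
  ch <- strsplit(aa, "")[[1]]
  pos <- c(K = 10.0, R = 12.0, H = 5.98)
  neg <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ct <- c(D = 4.55, E = 4.75)
  q <- numeric(length(grid))
  for (r in names(pos)) q <- q + sum(ch == r) / (1 + 10^(grid - pos[[r]]))
  for (r in names(neg)) q <- q - sum(ch == r) / (1 + 10^(neg[[r]] - grid))
  ntp <- if (ch[1] %in% names(nt)) nt[[ch[1]]] else 7.5
  ctp <- if (ch[length(ch)] %in% names(ct)) ct[[ch[length(ch)]]] else 3.55
  q <- q + 1 / (1 + 10^(grid - ntp)) - 1 / (1 + 10^(ctp - grid))
  grid[which.min(abs(q))]
}

# --- random peptides and codon strings -----------------------------------
random_peptide <- function(len, residues = c("A", "C", "D", "E", "F", "G", "H",
                                             "I", "K", "L", "M", "N", "P", "Q",
                                             "R", "S", "T", "V", "W", "Y")) {
  paste(sample(residues, len, replace = TRUE), collapse = "")
}

random_codon_string <- function(n_codons) {
  paste(sample(oracle_sense_codons, n_codons, replace = TRUE), collapse = "")
}

# Mutate a codon string at up to k positions, avoiding stop codons.
mutate_codon_string <- function(s, k) {
  repeat {
    chars <- strsplit(s, "")[[1]]
    at <- sample(seq_along(chars), k)
    for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    out <- paste(chars, collapse = "")
    codons <- substring(out, seq(1, nchar(out), 3), seq(3, nchar(out), 3))
    if (all(oracle_genetic_code[codons] != "*")) return(out)
  }
}

# --- permutation test for Pearson r --------------------------------------
oracle_permutation_p <- function(x, y, n_perm = 20000) {
  r_obs <- cor(x, y)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= abs(r_obs) - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}
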