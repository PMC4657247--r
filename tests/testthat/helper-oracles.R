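# Independent oracles, deliberately coded from different formulations than
# the package internals.

# Global affine-gap alignment score by plain recursion with memoisation;
# local score = max over all substring pairs (including empty = 0). Gap of
# length k costs open + k * ext.
oracle_local_score <- function(q, s, sub, open = 11L, ext = 1L) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  # state: i residues of qs left, j of ss, g = 0 none / 1 gap-in-s open /
  # 2 gap-in-q open; returns best score aligning qs[i..] fully vs ss[j..]
  glob <- function(qs, ss) {
    n1 <- length(qs); n2 <- length(ss)
    rec <- function(i, j, g) {
      if (i > n1 && j > n2) return(0L)
      key <- paste(i, j, g)
      if (!is.null(memo[[key]])) return(memo[[key]])
      best <- -1e9
      if (i <= n1 && j <= n2)
        best <- max(best, sub[qs[[i]], ss[[j]]] + rec(i + 1L, j + 1L, 0L))
      if (i <= n1)
        best <- max(best, rec(i + 1L, j, 1L) - ext - if (g == 1L) 0L else open)
      if (j <= n2)
        best <- max(best, rec(i, j + 1L, 2L) - ext - if (g == 2L) 0L else open)
      memo[[key]] <- best
      best
    }
    rec(1L, 1L, 0L)
  }
  best <- 0L
  for (a in seq_along(qc)) for (b in a:length(qc)) {
    for (cc in seq_along(sc)) for (d in cc:length(sc)) {
      memo <- new.env(parent = emptyenv())
      best <- max(best, glob(qc[a:b], sc[cc:d]))
    }
  }
  best
}

# Per-codon translation via direct lookup in the standard genetic code.
oracle_translate <- function(nt) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Two-pass textbook one-way ANOVA.
oracle_anova_F <- function(groups) {
  grand <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1L)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1L)))
  k <- length(groups); N <- length(unlist(groups))
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Full-enumeration two-sided Spearman permutation p-value.
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- oracle_perms(n)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  rho_all <- apply(perms, 1L, function(p) cor(rx, ry[p]))
  mean(abs(rho_all) >= obs - 1e-12)
}

oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow = nrow(sub)))
  }))
}

# Small deterministic fixture: a three-tier cascade with one planted
# homolog per role around a 3-gene proteome.
make_tiny_tiers <- function(ec_protein, csg_protein,
                            curated_target = NULL) {
  decoy <- function(seed, n = 3L) {
    set.seed(seed)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    setNames(vapply(seq_len(n), function(i)
      paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1L)),
      sprintf("d%d_%d", seed, seq_len(n)))
  }
  out_db <- seq_db(c(decoy(11), planted_ec = ec_protein), "protein")
  non_db <- seq_db(decoy(12), "protein")
  lin_nt <- vapply(csg_protein, function(p)
    paste(vapply(strsplit(p, "")[[1L]], function(a) {
      cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
      cods[[1L]]
    }, character(1L)), collapse = ""), character(1L))
  lin_db <- seq_db(c(setNames(lin_nt, "planted_csg"),
                     setNames(paste(rep("ACGT", 40), collapse = ""), "dnt")),
                   "nucleotide")
  cur <- decoy(13)
  if (!is.null(curated_target))
    cur <- c(cur, curated_hit = curated_target)
  tier_config(
    tier("genomes", "outgroup_genomes", list(out_db)),
    tier("nonlineage", "nonlineage_transcripts", list(non_db)),
    tier("lineage", "lineage_transcripts", list(lin_db)),
    tier("curated", "curated_validation", list(seq_db(cur, "protein"))))
}
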