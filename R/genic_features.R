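## Per-gene structural features (exon/intron counts and lengths, GC
## content of exons, introns, the gene span, the spliced CDS and its three
## codon positions), group summaries, one-way ANOVA between gene classes,
## and the chromosome-distribution analysis with Spearman's rank test.

.gc_count <- function(s) {
  ## GC numerator and non-N denominator of a nucleotide string
  g <- nchar(gsub("[^GC]", "", s))
  d <- nchar(gsub("N", "", s))
  c(gc = g, denom = d)
}

.gc_pct <- function(s) {
  x <- .gc_count(paste(s, collapse = ""))
  if (x[["denom"]] == 0L) return(NA_real_)
  100 * x[["gc"]] / x[["denom"]]
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}

.extract <- function(chrom_seq, intervals) {
  ## intervals: 2-col matrix of 1-based inclusive genomic coordinates
  vapply(seq_len(nrow(intervals)), function(k)
    substr(chrom_seq, intervals[k, 1L], intervals[k, 2L]), character(1L))
}

#' Spliced, strand-corrected CDS of a gene model
#'
#' Concatenates the CDS intervals in transcription order (reverse
#' complement on the minus strand) and applies the phase of the first CDS
#' piece, so the returned string starts in-frame.
#'
#' @param model a [gene_model].
#' @param chrom_seq the sequence of the model's chromosome (plain string).
#' @return nucleotide string of the coding sequence.
#' @export
spliced_cds <- function(model, chrom_seq) {
  pieces <- .extract(chrom_seq, model$cds[, 1:2, drop = FALSE])
  phases <- model$cds[, 3L]
  if (model$strand == "-") {
    pieces <- rev(vapply(pieces, .revcomp, character(1L), USE.NAMES = FALSE))
    phases <- rev(phases)
  }
  cds <- paste(pieces, collapse = "")
  first_phase <- phases[[1L]]
  if (first_phase > 0L) cds <- substr(cds, first_phase + 1L, nchar(cds))
  cds
}

#' Compute the genic feature vector of one gene
#'
#' GC denominators exclude `N`. Codon-position GC (`gc1`..`gc3`) is
#' computed on the spliced, strand-corrected CDS including the stop codon.
#' `protein_length` is `CDS length / 3 - 1` when the CDS ends in a stop
#' codon, else `CDS length / 3` (floored). A CDS whose length is not a
#' multiple of 3 after phase adjustment triggers a warning and the codon
#' features are computed on the in-frame prefix.
#'
#' @param model a [gene_model].
#' @param chrom_seq sequence of the model's chromosome (string or
#'   `DNAString`); the model's intervals must lie within it.
#' @return named list (class `feature_vector`): `gene_id`, `exon_count`,
#'   `exon_lengths`, `intron_lengths`, `gene_length`, `cds_length`,
#'   `protein_length`, `gc_exon`, `gc_intron`, `gc_gene`, `gc_cds`, `gc1`,
#'   `gc2`, `gc3` (GC as percent in `[0, 100]`).
#' @export
compute_features <- function(model, chrom_seq) {
  chrom_seq <- toupper(as.character(chrom_seq))
  if (max(model$exons[, 2L]) > nchar(chrom_seq))
    stop("gene ", model$gene_id, " extends past the end of its chromosome")
  exons <- model$exons
  exon_lengths <- exons[, 2L] - exons[, 1L] + 1L
  n_ex <- nrow(exons)
  intron_lengths <- if (n_ex > 1L)
    exons[-1L, 1L] - exons[-n_ex, 2L] - 1L else integer(0L)
  gene_length <- gene_span_length(model)

  exon_seq <- .extract(chrom_seq, exons)
  intron_iv <- if (n_ex > 1L)
    cbind(exons[-n_ex, 2L] + 1L, exons[-1L, 1L] - 1L) else
    matrix(integer(0L), ncol = 2L)
  intron_seq <- .extract(chrom_seq, intron_iv)
  gene_seq <- substr(chrom_seq, min(exons[, 1L]), max(exons[, 2L]))

  cds <- spliced_cds(model, chrom_seq)
  n_cds <- nchar(cds)
  if (n_cds %% 3L != 0L) {
    warning("gene ", model$gene_id, ": CDS length ", n_cds,
            " not a multiple of 3; codon features use the in-frame prefix")
    cds_frame <- substr(cds, 1L, n_cds - n_cds %% 3L)
  } else cds_frame <- cds
  codons <- strsplit(cds_frame, "", fixed = TRUE)[[1L]]
  pos <- (seq_along(codons) - 1L) %% 3L + 1L
  gc_codon <- vapply(1:3, function(p)
    .gc_pct(paste(codons[pos == p], collapse = "")), numeric(1L))

  has_stop <- substr(cds_frame, nchar(cds_frame) - 2L, nchar(cds_frame)) %in%
    c("TAA", "TAG", "TGA")
  protein_length <- if (has_stop) nchar(cds_frame) %/% 3L - 1L else
    nchar(cds_frame) %/% 3L

  structure(list(
    gene_id = model$gene_id,
    exon_count = n_ex,
    exon_lengths = as.integer(exon_lengths),
    intron_lengths = as.integer(intron_lengths),
    gene_length = as.integer(gene_length),
    cds_length = n_cds,
    protein_length = as.integer(protein_length),
    gc_exon = .gc_pct(exon_seq),
    gc_intron = if (length(intron_seq)) .gc_pct(intron_seq) else NA_real_,
    gc_gene = .gc_pct(gene_seq),
    gc_cds = .gc_pct(cds),
    gc1 = gc_codon[[1L]], gc2 = gc_codon[[2L]], gc3 = gc_codon[[3L]]),
    class = "feature_vector")
}

#' Feature table for a set of gene models
#'
#' @param models list of [gene_model] objects.
#' @param genome a nucleotide [seq_db] keyed by chromosome name.
#' @return data.frame with one row per gene (scalar features; exon and
#'   intron lengths as list columns `exon_lengths`, `intron_lengths`).
#' @export
features_table <- function(models, genome) {
  fv <- lapply(models, function(m) {
    if (!m$chromosome %in% names(genome))
      stop("chromosome ", m$chromosome, " of gene ", m$gene_id,
           " not in the genome")
    compute_features(m, genome[[m$chromosome]])
  })
  scalars <- c("gene_id", "exon_count", "gene_length", "cds_length",
               "protein_length", "gc_exon", "gc_intron", "gc_gene",
               "gc_cds", "gc1", "gc2", "gc3")
  df <- do.call(rbind, lapply(fv, function(v)
    as.data.frame(v[scalars], stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df$exon_lengths <- unname(lapply(fv, `[[`, "exon_lengths"))
  df$intron_lengths <- unname(lapply(fv, `[[`, "intron_lengths"))
  df
}

#' Summarize genic features over a group of genes
#'
#' Per-gene features are summarized across genes; exon-length and
#' intron-length statistics are pooled over all individual exons/introns in
#' the group (every exon is one observation; intronless genes contribute
#' nothing to intron statistics). Dispersion is the sample standard
#' deviation (`sd`); the standard error of the mean is also emitted
#' (`se = sd / sqrt(n)`).
#'
#' @param features data.frame from [features_table] (one group's rows).
#' @param per_gene if `TRUE`, average exon/intron lengths per gene before
#'   summarizing instead of pooling per element.
#' @return data.frame with columns `feature`, `mean`, `sd`, `se`,
#'   `median`, `n`.
#' @export
summarize_group <- function(features, per_gene = FALSE) {
  if (!nrow(features)) stop("empty group")
  pool <- function(col) {
    if (per_gene)
      vapply(features[[col]], function(x)
        if (length(x)) mean(x) else NA_real_, numeric(1L))
    else unlist(features[[col]])
  }
  vals <- list(
    exons_per_gene = features$exon_count,
    exon_length = pool("exon_lengths"),
    intron_length = pool("intron_lengths"),
    gene_length = features$gene_length,
    protein_length = features$protein_length,
    gc_exon = features$gc_exon,
    gc_intron = features$gc_intron,
    gc_gene = features$gc_gene,
    gc_cds = features$gc_cds,
    gc1 = features$gc1, gc2 = features$gc2, gc3 = features$gc3)
  rows <- lapply(names(vals), function(f) {
    x <- vals[[f]][!is.na(vals[[f]])]
    data.frame(feature = f,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) sd(x) else NA_real_,
               se = if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_,
               median = if (length(x)) median(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F with `(k - 1, N - k)` degrees of freedom
#' (equal-variance assumption), delegated to [stats::oneway.test]. When
#' every observation is identical within groups: equal group means give
#' `F = 0, p = 1` by convention; unequal means give `F = Inf, p = 0`.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @param log_transform if `TRUE`, analyse `log(x)` (all values must be
#'   positive).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups, log_transform = FALSE) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L))
    stop("each group needs at least 2 observations")
  if (log_transform) {
    if (any(unlist(groups) <= 0)) stop("log transform needs positive values")
    groups <- lapply(groups, log)
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  k <- length(groups)
  N <- length(x)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
  if (ssw == 0) {
    means <- vapply(groups, mean, numeric(1L))
    if (max(means) == min(means))
      return(list(F = 0, p = 1, df1 = k - 1L, df2 = N - k))
    return(list(F = Inf, p = 0, df1 = k - 1L, df2 = N - k))
  }
  fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df1 = unname(fit$parameter[[1L]]), df2 = unname(fit$parameter[[2L]]))
}

#' Per-feature ANOVA across gene classes
#'
#' @param features data.frame from [features_table].
#' @param categories character vector of class labels aligned with
#'   `features` rows (e.g. the cascade's `EC`/`CSG`/`ORPHAN` calls).
#' @param which_features features to test (default: the scalar features).
#' @param log_transform passed to [one_way_anova].
#' @return data.frame `feature`, `F`, `p`.
#' @export
anova_by_class <- function(features, categories,
                           which_features = c("exon_count", "gene_length",
                                              "protein_length", "gc_gene",
                                              "gc_cds"),
                           log_transform = FALSE) {
  stopifnot(length(categories) == nrow(features))
  rows <- lapply(which_features, function(f) {
    groups <- split(features[[f]], categories)
    groups <- lapply(groups, function(x) x[!is.na(x)])
    a <- one_way_anova(groups, log_transform = log_transform)
    data.frame(feature = f, F = a$F, p = a$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman's rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of ranks (average ranks for ties). For
#' `n <= 9` the two-sided p-value is exact, from full enumeration of all
#' `n!` rank permutations (valid with ties); for larger `n` the usual
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`).
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined for a constant vector")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .all_permutations(n)
    ## rho for each permutation of ry against fixed rx, via the closed form
    ## rho = (S - n*mbar^2) / (n * var terms); use cor on centered sums
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    sums <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc)
    rho_all <- sums / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

.perm_cache <- new.env(parent = emptyenv())

.all_permutations <- function(n) {
  ## n! x n matrix of all permutations of 1..n (row-wise), memoised
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  .perm_cache[[key]] <- out
  out
}

#' Chromosome distribution of gene categories
#'
#' Counts genes per chromosome and category; percentages are of the
#' category total among genes with a known (placed) chromosome. Genes on
#' scaffolds matching `unplaced_pattern` are tallied in a separate
#' `"unplaced"` row with `NA` percentages. A chromosome that is neither in
#' `chrom_lengths` nor unplaced is an error.
#'
#' @param outcomes data.frame with `gene_id` and `category` (e.g.
#'   [run_pipeline] outcomes).
#' @param models named list of [gene_model] objects covering the genes.
#' @param chrom_lengths named numeric vector of placed chromosome lengths
#'   (bp), or a data.frame with columns `chromosome` and `length`.
#' @param unplaced_pattern regex identifying unplaced scaffolds.
#' @return list with `table` (data.frame `chromosome`, `category`, `n`,
#'   `pct`, ordered by `chrom_lengths` with the unplaced row last) and
#'   `spearman` (per category, [spearman] of placed counts vs chromosome
#'   lengths).
#' @export
chromosome_distribution <- function(outcomes, models, chrom_lengths,
                                    unplaced_pattern = "^(scaffold|Un)") {
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chromosome)
  missing_models <- setdiff(outcomes$gene_id, names(models))
  if (length(missing_models))
    stop("gene(s) missing from models: ",
         paste(utils::head(missing_models, 3L), collapse = ", "))
  chrom <- vapply(outcomes$gene_id, function(g) models[[g]]$chromosome,
                  character(1L))
  unplaced <- grepl(unplaced_pattern, chrom)
  unknown <- !unplaced & !(chrom %in% names(chrom_lengths))
  if (any(unknown))
    stop("chromosome ", chrom[unknown][[1L]],
         " missing from the chromosome length table")
  cats <- sort(unique(outcomes$category))
  placed_names <- names(chrom_lengths)
  rows <- list()
  sp <- list()
  for (cat in cats) {
    sel <- outcomes$category == cat
    counts <- vapply(placed_names, function(ch)
      sum(sel & chrom == ch & !unplaced), integer(1L))
    total_placed <- sum(counts)
    pct <- if (total_placed > 0L) 100 * counts / total_placed else
      rep(NA_real_, length(counts))
    rows[[cat]] <- data.frame(
      chromosome = c(placed_names, "unplaced"),
      category = cat,
      n = c(counts, sum(sel & unplaced)),
      pct = c(pct, NA_real_), stringsAsFactors = FALSE)
    sp[[cat]] <- if (total_placed > 0L && length(unique(counts)) > 1L &&
                     length(counts) >= 3L)
      spearman(unname(chrom_lengths), unname(counts)) else NULL
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       spearman = sp)
}
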