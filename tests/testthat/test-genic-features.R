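test_that("hand-countable single-exon gene features are exact", {
  m <- gene_model("g1", "c", "+", cbind(1, 9), cbind(1, 9, 0))
  f <- compute_features(m, "ATGGGCTAA")
  expect_equal(f$exon_count, 1L)
  expect_equal(f$gene_length, 9L)
  expect_equal(f$gc_cds, 100 * 4 / 9)
  expect_equal(f$gc1, 100 * 1 / 3)  # A,G,T at codon position 1
  expect_equal(f$gc2, 100 * 1 / 3)  # T,G,A
  expect_equal(f$gc3, 100 * 2 / 3)  # G,C,A
  expect_equal(f$protein_length, 2L)
  expect_equal(length(f$intron_lengths), 0L)
})

test_that("two-exon coordinate arithmetic and N handling are correct", {
  chrom <- paste0("ATGGGCTAAG", strrep("N", 10), "CCCCCGGTAACCGG")
  m <- gene_model("g2", "c", "+", rbind(c(1, 10), c(21, 34)),
                  rbind(c(1, 10, 0), c(21, 34, 2)))
  f <- compute_features(m, chrom)
  expect_equal(f$intron_lengths, 10L)
  expect_equal(f$gene_length, 34L)
  ## all-N intron: excluded from both numerator and denominator
  expect_true(is.na(f$gc_intron))
  ## gc_gene then equals gc over the exonic non-N bases only
  expect_equal(f$gc_gene, f$gc_exon)
})

test_that("minus-strand genes use the reverse complement for codon features", {
  ## CDS on minus strand: genomic revcomp("ATGGGCTAA") = TTAGCCCAT
  m <- gene_model("g3", "c", "-", cbind(1, 9), cbind(1, 9, 0))
  f <- compute_features(m, "TTAGCCCAT")
  expect_equal(f$gc_cds, 100 * 4 / 9)
  expect_equal(f$protein_length, 2L)
  expect_equal(spliced_cds(m, "TTAGCCCAT"), "ATGGGCTAA")
})

test_that("feature identities hold on fuzzed synthetic genes", {
  corpora <- lapply(c(101, 202), function(s)
    simulate_corpus(simulation_config(seed = s, n_ec = 20, n_csg = 15,
                                      n_orphan = 15)))
  n_checked <- 0
  for (corpus in corpora) {
    ft <- features_table(corpus$models, corpus$genome)
    for (i in seq_len(nrow(ft))) {
      expect_equal(ft$gene_length[[i]],
                   sum(ft$exon_lengths[[i]]) + sum(ft$intron_lengths[[i]]))
      expect_equal(length(ft$intron_lengths[[i]]), ft$exon_count[[i]] - 1L)
      ## gc_gene is the length-weighted mix of exon and intron GC
      ex_len <- sum(ft$exon_lengths[[i]])
      in_len <- sum(ft$intron_lengths[[i]])
      mix <- (ft$gc_exon[[i]] * ex_len +
                ifelse(in_len > 0, ft$gc_intron[[i]], 0) * in_len) /
        (ex_len + in_len)
      expect_equal(ft$gc_gene[[i]], mix, tolerance = 1e-12)
      ## mean codon-position GC equals CDS GC (CDS length divisible by 3)
      expect_equal((ft$gc1[[i]] + ft$gc2[[i]] + ft$gc3[[i]]) / 3,
                   ft$gc_cds[[i]], tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
    ## generator GC targets are realized within a percentage point
    for (cl in c("EC", "CSG", "ORPHAN")) {
      got <- mean(ft$gc_gene[corpus$truth$category == cl])
      expect_lt(abs(got - corpus$config$gc_target[[cl]]), 1.0)
    }
  }
  expect_gte(n_checked, 100)
})

test_that("group summaries match an independent recomputation", {
  corpus <- simulate_corpus(simulation_config(seed = 55, n_ec = 10,
                                              n_csg = 10, n_orphan = 5))
  ft <- features_table(corpus$models, corpus$genome)
  sm <- summarize_group(ft)
  expect_equal(sm$mean[sm$feature == "gene_length"], mean(ft$gene_length))
  expect_equal(sm$sd[sm$feature == "gene_length"], sd(ft$gene_length))
  expect_equal(sm$median[sm$feature == "exons_per_gene"],
               median(ft$exon_count))
  ## exon lengths pooled per element, not per gene
  pooled <- unlist(ft$exon_lengths)
  expect_equal(sm$mean[sm$feature == "exon_length"], mean(pooled))
  expect_equal(sm$n[sm$feature == "exon_length"], length(pooled))
  ## intronless genes contribute nothing to intron statistics
  expect_equal(sm$n[sm$feature == "intron_length"],
               sum(ft$exon_count - 1L))
  ## degenerate one-gene group
  one <- summarize_group(ft[1, , drop = FALSE])
  expect_equal(one$median[one$feature == "gene_length"],
               one$mean[one$feature == "gene_length"])
  expect_true(is.na(one$sd[one$feature == "gene_length"]))
})

test_that("one-way ANOVA matches the textbook formula and conventions", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3))),
               list(F = 0, p = 1, df1 = 1L, df2 = 4L))
  sep <- one_way_anova(list(c(0, 0, 0, 0), c(10, 10, 10, 10)))
  expect_equal(sep$p, 0)
  set.seed(66)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(sample(4:12, 1), mean = i / 2))
    a <- one_way_anova(groups)
    expect_equal(a$F, oracle_anova_F(groups), tolerance = 1e-10)
    ## F invariant under shift and scale
    expect_equal(one_way_anova(lapply(groups, `+`, 5))$F, a$F,
                 tolerance = 1e-10)
    expect_equal(one_way_anova(lapply(groups, `*`, 3))$F, a$F,
                 tolerance = 1e-10)
  }
  expect_error(one_way_anova(list(1, c(2, 3))), "at least 2 observations")
})

test_that("anova_by_class separates classes with planted differences", {
  corpus <- simulate_corpus(simulation_config(seed = 77))
  ft <- features_table(corpus$models, corpus$genome)
  av <- anova_by_class(ft, corpus$truth$category)
  ## conserved genes are built longer with more exons than the LSG classes
  expect_lt(av$p[av$feature == "gene_length"], 0.01)
  expect_lt(av$p[av$feature == "exon_count"], 0.01)
})

test_that("spearman matches enumeration, cor.test, and endpoint cases", {
  expect_equal(spearman(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman(1:8, rev(1:8))$rho, -1)
  expect_error(spearman(1:5, rep(2, 5)), "constant")
  set.seed(88)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    s <- spearman(x, y)
    expect_equal(s$method, "exact")
    expect_equal(s$p, oracle_spearman_p(x, y), tolerance = 1e-12)
    ## cor.test's AS89 exact p agrees on tie-free data
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = TRUE))
    expect_equal(s$rho, unname(ref$estimate))
    expect_equal(s$p, ref$p.value, tolerance = 1e-8)
  }
  ## ties: average ranks, permutation p still defined
  s <- spearman(c(1, 1, 2, 3, 4, 5), c(2, 1, 3, 3, 5, 6))
  expect_equal(s$method, "exact")
  expect_true(s$p > 0 && s$p <= 1)
  ## large-n path
  set.seed(89)
  x <- rnorm(30); y <- x + rnorm(30)
  s <- spearman(x, y)
  expect_equal(s$method, "t-approximation")
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s$p, ref$p.value, tolerance = 1e-10)
})

test_that("chromosome distribution normalizes, separates unplaced, errors", {
  models <- list(
    a = gene_model("a", "chr1", "+", cbind(1, 30), cbind(1, 30, 0)),
    b = gene_model("b", "chr1", "+", cbind(41, 70), cbind(41, 70, 0)),
    c = gene_model("c", "chr2", "+", cbind(1, 30), cbind(1, 30, 0)),
    d = gene_model("d", "scaffold_1", "+", cbind(1, 30), cbind(1, 30, 0)))
  outcomes <- data.frame(gene_id = c("a", "b", "c", "d"),
                         category = c("CSG", "CSG", "CSG", "CSG"),
                         stringsAsFactors = FALSE)
  cd <- chromosome_distribution(outcomes, models,
                                c(chr1 = 1000, chr2 = 800))
  tab <- cd$table
  expect_equal(tab$n[tab$chromosome == "chr1"], 2)
  expect_equal(sum(tab$pct[tab$chromosome != "unplaced"]), 100)
  expect_equal(tab$n[tab$chromosome == "unplaced"], 1)
  expect_true(is.na(tab$pct[tab$chromosome == "unplaced"]))
  ## chromosome absent from the length table
  models$c$chromosome <- "chrZ"
  expect_error(chromosome_distribution(outcomes, models,
                                       c(chr1 = 1000, chr2 = 800)),
               "chrZ")
})

test_that("length-proportional placement yields positive count-length rank correlation", {
  ## standalone placement simulation at the chromosome scale of the analysis
  set.seed(99)
  lens <- c(28, 36, 51, 25, 43, 25, 22, 25, 31) * 1e6
  ok <- 0
  for (rep in 1:200) {
    counts <- as.vector(stats::rmultinom(1, 300, prob = lens / sum(lens)))
    if (length(unique(counts)) == 1) next
    s <- spearman(lens, counts)
    if (s$rho > 0 && s$p < 0.05) ok <- ok + 1
  }
  expect_gt(ok / 200, 0.5)
})
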