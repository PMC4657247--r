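mk_cm <- function(counts, lib = NULL, len = NULL) {
  if (is.null(lib)) lib <- setNames(rep(1e6, ncol(counts)), colnames(counts))
  if (is.null(len)) len <- setNames(rep(1000, nrow(counts)), rownames(counts))
  count_matrix(counts, lib, len)
}

test_that("RPKM units, zeros, and scale invariance", {
  cm <- mk_cm(matrix(c(1000, 0), 1, 2,
                     dimnames = list("g", c("t1", "t2"))))
  r <- compute_rpkm(cm)
  expect_equal(unname(r["g", "t1"]), 1000)
  expect_equal(unname(r["g", "t2"]), 0)
  expect_error(count_matrix(cm$counts, cm$mapped_reads, c(g = 0)),
               "exonic length")

  set.seed(41)
  counts <- matrix(rpois(40, 50), 10, 4,
                   dimnames = list(sprintf("g%d", 1:10),
                                   c("a", "b", "c", "d")))
  lib <- setNames(runif(4, 1e6, 3e6), colnames(counts))
  len <- setNames(sample(300:3000, 10), rownames(counts))
  r1 <- compute_rpkm(mk_cm(counts, lib, len))
  r2 <- compute_rpkm(mk_cm(2 * counts, 2 * lib, len))
  expect_equal(r1, r2)
})

test_that("preferential calls follow the two-rule filter literally", {
  r <- rbind(clear = c(10, 1, 1, 1),
             flat = c(3, 2.9, 2.8, 2.7),
             low = c(1.5, 0.2, 0.2, 0.2),
             just_over = c(6.1, 3, 5, 5.9),
             tie2x = c(6, 3, 5, 5.9),
             zero = c(5, 0, 5, 5))
  colnames(r) <- c("callus", "leaf", "flower", "fruit")
  calls <- call_preferential(r)
  expect_equal(calls$preferential_tissue[calls$gene_id == "clear"], "callus")
  ## max 3 is not > 2 * 2.7: rule 2 fails against every tissue
  expect_true(is.na(calls$preferential_tissue[calls$gene_id == "flat"]))
  ## rule 1 fails below the abundance threshold
  expect_true(is.na(calls$preferential_tissue[calls$gene_id == "low"]))
  ## 6.1 > 2 * 3 passes against the weakest tissue (literal rule)
  expect_equal(calls$preferential_tissue[calls$gene_id == "just_over"],
               "callus")
  ## exactly 2-fold is a tie and fails (strict inequality)
  expect_true(is.na(calls$preferential_tissue[calls$gene_id == "tie2x"]))
  ## zero comparison tissue satisfies rule 2 without division
  expect_equal(calls$preferential_tissue[calls$gene_id == "zero"], "callus")
  ## strict mode requires the margin over all other tissues
  strict <- call_preferential(r, strict = TRUE)
  expect_true(is.na(strict$preferential_tissue[strict$gene_id ==
                                                 "just_over"]))
  expect_true(is.na(strict$preferential_tissue[strict$gene_id == "zero"]))
  expect_equal(strict$preferential_tissue[strict$gene_id == "clear"],
               "callus")
  ## constitutive implies expressed_all
  expect_true(all(!calls$constitutive | calls$expressed_all))
})

test_that("expression-class flags use strict thresholds", {
  r <- rbind(all_on = c(2.1, 2.2, 2.3, 2.4),
             border = c(2, 2.1, 2.2, 2.3),
             one_off = c(0, 5, 5, 5))
  colnames(r) <- c("a", "b", "c", "d")
  calls <- call_preferential(r)
  expect_true(calls$constitutive[calls$gene_id == "all_on"])
  expect_false(calls$constitutive[calls$gene_id == "border"])  # 2 is not > 2
  expect_true(calls$expressed_all[calls$gene_id == "border"])
  expect_false(calls$expressed_all[calls$gene_id == "one_off"])
})

test_that("preferential calls are invariant under tissue permutation and
           monotone in the top tissue", {
  set.seed(42)
  r <- matrix(rexp(200, 1 / 3), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), c("a", "b", "c", "d")))
  calls <- call_preferential(r)
  perm <- c(3, 1, 4, 2)
  calls_p <- call_preferential(r[, perm])
  expect_equal(calls$preferential_tissue, calls_p$preferential_tissue)
  ## boosting the winning tissue never revokes a call
  pref <- which(!is.na(calls$preferential_tissue))
  r2 <- r
  for (i in pref) r2[i, calls$preferential_tissue[i]] <-
      r2[i, calls$preferential_tissue[i]] * 5
  calls2 <- call_preferential(r2)
  expect_equal(calls2$preferential_tissue[pref],
               calls$preferential_tissue[pref])
})

test_that("tissue tables reproduce printed-count percentages and tally calls", {
  counts <- matrix(c(45, 19, 19, 22, 101, 27, 30, 25), 2, 4, byrow = TRUE,
                   dimnames = list(c("CSG", "ORPHAN"),
                                   c("callus", "leaf", "flower", "fruit")))
  tab <- summarize_tissue_table(counts)
  expect_equal(round(tab$callus_pct, 2), c(42.86, 55.19))
  expect_equal(round(tab$leaf_pct, 2), c(18.10, 14.75))
  expect_equal(round(tab$flower_pct, 2), c(18.10, 16.39))
  expect_equal(round(tab$fruit_pct, 2), c(20.95, 13.66))
  expect_equal(tab$total, c(105, 183), ignore_attr = TRUE)
  ## percentages sum to 100 per row
  pct <- as.matrix(tab[, grep("_pct$", names(tab))])
  expect_equal(unname(rowSums(pct)), c(100, 100))

  ## per-gene path: counts tallied from calls + categories, empty category
  r <- rbind(g1 = c(9, 1, 1, 1), g2 = c(1, 9, 1, 1), g3 = c(3, 3, 3, 3))
  colnames(r) <- c("callus", "leaf", "flower", "fruit")
  calls <- call_preferential(r)
  cats <- c(g1 = "CSG", g2 = "CSG", g3 = "EC")
  out <- summarize_tissue_table(calls, cats)
  expect_equal(out$preferential$callus_n[out$preferential$category == "CSG"],
               1)
  expect_equal(out$preferential$total[out$preferential$category == "EC"], 0)
  expect_true(is.na(
    out$preferential$callus_pct[out$preferential$category == "EC"]))
  ## high abundance counts cells, not genes: g3 has all four tissues > 2
  expect_equal(out$high_abundance$total[
    out$high_abundance$category == "EC"], 4)
  expect_error(summarize_tissue_table(calls, c(g1 = "CSG")), "no category")
})

test_that("ddCt fold changes follow the closed form", {
  ct <- expand.grid(gene = c("ref", "tgt"), condition = c("control", "heat"),
                    timepoint = c(0, 6), replicate = 1:2,
                    stringsAsFactors = FALSE)
  ct <- ct[!(ct$condition == "control" & ct$timepoint != 0) &
             !(ct$condition == "heat" & ct$timepoint == 0), ]
  ct$ct <- ifelse(ct$gene == "ref", 20, 25)
  ## treatment dCt equals control dCt -> fold 1
  fc <- ddct_fold_change(ct, "ref", "control")
  expect_equal(fc$fold, 1)
  ## ddCt = -2 -> fold 4
  ct$ct[ct$gene == "tgt" & ct$condition == "heat"] <- 23
  fc <- ddct_fold_change(ct, "ref", "control")
  expect_equal(fc$ddct, -2)
  expect_equal(fc$fold, 4)
  ## missing reference well is named
  expect_error(ddct_fold_change(ct[ct$gene != "ref" | ct$condition != "heat", ],
                                "ref", "control"),
               "condition=heat")
})

test_that("stress-responsiveness calls honor the fold threshold", {
  folds <- data.frame(gene = rep(c("a", "b", "c"), each = 3),
                      condition = "heat", timepoint = rep(c(6, 12, 24), 3),
                      fold = c(1.0, 1.1, 0.95, 1.2, 4, 1.1, 0.9, 0.4, 1),
                      stringsAsFactors = FALSE)
  cs <- call_stress_responsive(folds, threshold = 2)
  expect_equal(cs$calls$call[cs$calls$gene == "a"], "unchanged")
  expect_equal(cs$calls$call[cs$calls$gene == "b"], "up")
  expect_equal(cs$calls$call[cs$calls$gene == "c"], "down")
  expect_equal(cs$responsive, c("b", "c"))
  expect_error(call_stress_responsive(folds, threshold = 1), "exceed 1")
})
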