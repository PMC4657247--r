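scheme <- scoring_scheme()

test_that("six-frame translation matches a per-codon oracle", {
  nt <- strrep("ATGAAA", 10)
  fr <- translate_six_frames(nt)
  expect_equal(fr[["+1"]], strrep("MK", 10))
  ## reverse complement reads the same peptide in frame -1
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
  expect_equal(translate_six_frames(rc)[["-1"]], strrep("MK", 10))

  set.seed(31)
  for (rep in 1:5) {
    nt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    fr <- translate_six_frames(nt, min_len = 1)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
    for (f in 1:3) {
      fwd_pep <- oracle_translate(substr(nt, f, nchar(nt)))
      expect_equal(fr[[paste0("+", f)]],
                   Filter(nzchar, strsplit(fwd_pep, "*", fixed = TRUE)[[1]]))
      rev_pep <- oracle_translate(substr(rc, f, nchar(rc)))
      expect_equal(fr[[paste0("-", f)]],
                   Filter(nzchar, strsplit(rev_pep, "*", fixed = TRUE)[[1]]))
    }
  }
  ## short input yields empty output, segments under min_len dropped
  expect_equal(translate_six_frames("AT")[["+1"]], character(0))
  expect_equal(translate_six_frames(strrep("ATGAAA", 3))[["+1"]],
               character(0))  # 6 residues < default min_len 10
})

test_that("identity and all-negative alignments score as expected", {
  a <- align_local("MKVLA", "MKVLA", scheme)
  expect_equal(a$score, 5 + 5 + 4 + 4 + 4)  # BLOSUM62 diagonal sums
  expect_equal(c(a$q_start, a$q_end, a$s_start, a$s_end), c(1, 5, 1, 5))
  b <- align_local("AAAA", "WWWW", scheme)
  expect_equal(b$score, 0)
  expect_equal(b$q_start, 0)  # empty span
  expect_error(align_local("MKB2", "MKV", scheme), "position 4")
})

test_that("alignment equals the exhaustive oracle on tiny instances", {
  sub <- scheme$substitution
  aa <- c("A", "V", "L")
  set.seed(5)
  for (rep in 1:25) {
    q <- paste(sample(aa, sample(1:4, 1), replace = TRUE), collapse = "")
    s <- paste(sample(aa, sample(1:4, 1), replace = TRUE), collapse = "")
    expect_equal(align_local(q, s, scheme)$score,
                 oracle_local_score(q, s, sub),
                 info = paste(q, s))
  }
})

test_that("alignment score is symmetric and monotone under extension", {
  set.seed(6)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:20) {
    q <- paste(sample(aa, 25, replace = TRUE), collapse = "")
    s <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    expect_equal(align_local(q, s, scheme)$score,
                 align_local(s, q, scheme)$score)
    flank1 <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    flank2 <- paste(sample(aa, 10, replace = TRUE), collapse = "")
    expect_gte(align_local(q, paste0(flank1, s, flank2), scheme)$score,
               align_local(q, s, scheme)$score)
  }
})

test_that("E-values follow the closed form and its monotonicities", {
  expect_equal(evalue(0, 10, 100, scheme), scheme$K * 10 * 100)
  expect_equal(evalue(50, 10, 200, scheme), 2 * evalue(50, 10, 100, scheme))
  expect_equal(evalue(57, 100, 1e6, scheme),
               0.041 * 100 * 1e6 * exp(-0.267 * 57))
  ## strictly decreasing in score
  e <- evalue(1:60, 100, 1e6, scheme)
  expect_true(all(diff(e) < 0))
})

test_that("search finds self-hits, ranks them, and rejects noise", {
  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  target <- paste(sample(aa, 80, replace = TRUE), collapse = "")
  decoys <- setNames(vapply(1:50, function(i)
    paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1)),
    sprintf("decoy%02d", 1:50))
  db <- seq_db(c(decoys, self = target), "protein")
  hits <- search_db(setNames(target, "q"), db)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$subject_id[[1]], "self")
  expect_true(all(diff(hits$evalue) >= 0))

  ## unrelated random sequences at a stringent cutoff: empty
  q2 <- setNames(paste(sample(aa, 60, replace = TRUE), collapse = ""), "q2")
  expect_equal(nrow(search_db(q2, seq_db(decoys, "protein"),
                              evalue_cutoff = 1e-20)), 0L)

  ## planted diverged homolog among decoys is the top hit
  hom <- mutate_sequence(target, 0.3, seed = 99)
  db2 <- seq_db(c(decoys, planted = hom), "protein")
  h2 <- search_db(setNames(target, "q"), db2)
  expect_equal(h2$subject_id[[1]], "planted")

  ## mode/moltype mismatch
  expect_error(search_db(q2, db2, mode = "translated_nucleotide"),
               "nucleotide")
})

test_that("translated search reports the best frame per subject", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  code <- Biostrings::GENETIC_CODE
  cds <- paste(vapply(strsplit(prot, "")[[1]], function(a)
    names(code)[code == a][[1]], character(1)), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cds, "")[[1]]),
                                     collapse = ""))
  db <- seq_db(c(minus = paste0("AC", rc, "GT")), "nucleotide")
  hits <- search_db(setNames(prot, "q"), db,
                    mode = "translated_nucleotide")
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$frame[[1]], 0)  # encoded on the reverse strand
  expect_equal(hits$raw_score[[1]], align_local(prot, prot, scheme)$score)
})

test_that("has_significant_hit agrees with search non-emptiness", {
  expect_false(has_significant_hit("MKVLA",
                                   seq_db(character(0), "protein"))$significant)
  set.seed(9)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  db <- seq_db(setNames(vapply(1:12, function(i)
    paste(sample(aa, 70, replace = TRUE), collapse = ""), character(1)),
    sprintf("s%02d", 1:12)), "protein")
  for (rep in 1:40) {
    if (runif(1) < 0.5) {
      q <- paste(sample(aa, 50, replace = TRUE), collapse = "")
    } else {
      q <- mutate_sequence(db[[sample(12, 1)]], runif(1, 0, 0.4))
    }
    full <- search_db(setNames(q, "q"), db)
    quick <- has_significant_hit(setNames(q, "q"), db)
    expect_equal(quick$significant, nrow(full) > 0)
    if (quick$significant) expect_true(quick$hit$subject_id %in%
                                         full$subject_id)
  }
})

test_that("adding database sequences never removes a hit", {
  set.seed(10)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- setNames(vapply(1:6, function(i)
    paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1)),
    sprintf("b%d", 1:6))
  q <- setNames(mutate_sequence(base[[2]], 0.2), "q")
  extra <- setNames(vapply(1:6, function(i)
    paste(sample(aa, 60, replace = TRUE), collapse = ""), character(1)),
    sprintf("x%d", 1:6))
  small <- has_significant_hit(q, seq_db(base, "protein"))$significant
  big <- has_significant_hit(q, seq_db(c(base, extra), "protein"))$significant
  expect_true(small)
  expect_true(big)
})
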