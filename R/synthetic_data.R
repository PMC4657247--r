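## Synthetic corpus generator. Emits every input the pipeline consumes --
## focal proteome, genome + annotation realizing it, tiered homology
## databases with planted homologs at controlled divergence, count
## matrices with planted tissue-preferential genes, and qPCR Ct tables
## with planted fold changes -- together with the ground-truth labels, so
## classification, feature and expression calls are testable hermetically.
##
## All randomness flows from a single integer seed; per-component
## sub-streams are derived from it so that, e.g., changing the number of
## genes does not perturb the expression noise.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 7919L + as.integer(h %% 100000L)) %% 2147483629L
}

#' Simulation configuration
#'
#' Defaults define the reference desk-scale study conditions: a 60-gene
#' focal proteome (30 conserved, 20 lineage-specific, 10 orphan), four
#' outgroup species (alternating annotated-protein and raw-genome
#' databases, mirroring a BLASTp + tBLASTn first tier), four non-lineage
#' and three lineage transcript sets, homolog divergence 0.2 expected
#' substitutions per site, four tissues with 40 planted
#' tissue-preferential genes at an 8-fold margin, and an 82-gene qPCR
#' panel with 12 planted stress-responsive genes.
#'
#' @param seed mandatory integer seed.
#' @param ... overrides for any default listed above (see the source for
#'   the full field list).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    n_ec = 30L, n_csg = 20L, n_orphan = 10L,
    n_outgroup = 4L, n_nonlineage = 4L, n_lineage = 3L,
    divergence = 0.2, indel_rate = 0,
    frac_ec_nonlineage_only = 0.3, frac_ec_curated_only = 0.1,
    decoys_per_db = 8L, decoy_len = c(60L, 150L),
    protein_len = list(EC = c(120L, 280L), CSG = c(60L, 150L),
                       ORPHAN = c(60L, 150L)),
    exon_count_weights = list(EC = c(1, 2, 3, 3, 2, 1, 1, 1),
                              CSG = c(5, 3, 2), ORPHAN = c(5, 3, 2)),
    intron_len = c(80L, 400L),
    gc_target = c(EC = 38.5, CSG = 42.5, ORPHAN = 43.0),
    n_chromosomes = 9L, frac_unplaced = 0.1,
    chromosome_weights = seq(1.5, 0.5, length.out = 9L),
    intergenic_len = c(200L, 600L),
    tissues = c("callus", "leaf", "flower", "fruit"),
    library_size = c(2.0e6, 2.2e6, 1.8e6, 2.1e6),
    n_preferential = 40L, pref_fold = 8, pref_base_rpkm = 3,
    nb_size = 10,
    qpcr_n_genes = 82L, qpcr_n_responsive = 12L,
    qpcr_conditions = list(heat = c(6, 12, 24), cold = c(24, 72, 120),
                           uv = c(1, 2, 4)),
    qpcr_replicates = 3L, qpcr_ct_noise_sd = 0.2,
    qpcr_fold_range = c(4, 16), qpcr_frac_down = 0.25,
    reference_gene = "ref_actin")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$divergence < 0 || cfg$divergence >= 1)
    stop("divergence must be in [0, 1)")
  if (cfg$n_csg > 0L && cfg$n_lineage == 0L)
    stop("CSG genes requested with zero lineage transcript sets")
  if (cfg$n_ec > 0L && cfg$n_outgroup == 0L && cfg$n_nonlineage == 0L)
    stop("EC genes requested with no outgroup or non-lineage databases")
  structure(cfg, class = "simulation_config")
}

#' Mutate a sequence at a controlled divergence
#'
#' Per-site substitution with probability `divergence`; protein
#' substitutions are drawn uniformly from the other 19 residues
#' (nucleotide: the other 3 bases). Indels off by default: with
#' `indel_rate > 0`, each site is additionally deleted with probability
#' `indel_rate / 2` and a random residue inserted after it with
#' probability `indel_rate / 2`.
#'
#' @param seq residue string.
#' @param divergence expected substitutions per site, in `[0, 0.9]`.
#' @param seed optional integer; when given, the RNG is seeded for a
#'   reproducible standalone call.
#' @param moltype `"protein"` or `"nucleotide"`.
#' @param indel_rate per-site indel probability.
#' @return mutated string.
#' @export
mutate_sequence <- function(seq, divergence, seed = NULL,
                            moltype = c("protein", "nucleotide"),
                            indel_rate = 0) {
  moltype <- match.arg(moltype)
  if (divergence < 0 || divergence > 0.9)
    stop("divergence must be in [0, 0.9]")
  if (!is.null(seed)) set.seed(seed)
  alph <- if (moltype == "protein") .AA20 else c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(chars)) < divergence
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(c0)
      sample(setdiff(alph, c0), 1L), character(1L), USE.NAMES = FALSE)
  if (indel_rate > 0) {
    keep <- runif(length(chars)) >= indel_rate / 2
    ins <- runif(length(chars)) < indel_rate / 2
    out <- character(0L)
    for (k in seq_along(chars)) {
      if (keep[[k]]) out <- c(out, chars[[k]])
      if (ins[[k]]) out <- c(out, sample(alph, 1L))
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

.random_protein <- function(len) {
  paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE), collapse = ""))
}

.random_dna <- function(len, gc = 0.40) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.codon_map <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

## Reverse-translate a protein (plus stop) choosing synonymous codons with
## a running-GC thermostat toward gc_target (fraction); with probability
## 0.3 a codon is drawn uniformly instead, so sequences differ across
## genes at equal targets.
.rev_translate <- function(protein, gc_target, codon_map = .codon_map()) {
  aas <- c(strsplit(protein, "", fixed = TRUE)[[1L]], "*")
  gc_of <- function(codons) nchar(gsub("[^GC]", "", codons))
  run_gc <- 0L
  run_len <- 0L
  out <- character(length(aas))
  for (k in seq_along(aas)) {
    cands <- codon_map[[aas[[k]]]]
    if (length(cands) > 1L && runif(1L) < 0.3) {
      pick <- sample(cands, 1L)
    } else {
      frac <- (run_gc + gc_of(cands)) / (run_len + 3L)
      pick <- cands[[which.min(abs(frac - gc_target))]]
    }
    out[[k]] <- pick
    run_gc <- run_gc + gc_of(pick)
    run_len <- run_len + 3L
  }
  paste(out, collapse = "")
}

## Build one annotated gene: split the CDS over n_exons exons, generate
## introns at the class GC target, return the gene-region sequence plus
## exon/CDS intervals relative to the region start (1-based).
.build_gene_region <- function(cds, n_exons, gc_target, intron_len, strand) {
  L <- nchar(cds)
  n_exons <- min(n_exons, L %/% 30L + 1L)  # keep exons >= ~30 bp
  if (n_exons > 1L) {
    cuts <- sort(sample(seq(30L, L - 30L), n_exons - 1L))
    bounds <- c(0L, cuts, L)
  } else bounds <- c(0L, L)
  exon_lens <- diff(bounds)
  intron_lens <- if (n_exons > 1L)
    sample(seq(intron_len[[1L]], intron_len[[2L]]), n_exons - 1L,
           replace = TRUE) else integer(0L)
  exon_seqs <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1L])
  intron_seqs <- vapply(intron_lens, .random_dna, character(1L),
                        gc = gc_target)
  ## transcript-order region and piece offsets
  pieces <- character(0L)
  types <- character(0L)
  for (k in seq_len(n_exons)) {
    pieces <- c(pieces, exon_seqs[[k]])
    types <- c(types, "exon")
    if (k < n_exons) {
      pieces <- c(pieces, intron_seqs[[k]])
      types <- c(types, "intron")
    }
  }
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  region <- paste(pieces, collapse = "")
  R <- nchar(region)
  ## phases in transcript order
  cum_cds <- c(0L, cumsum(exon_lens))[seq_len(n_exons)]
  phases <- (3L - cum_cds %% 3L) %% 3L
  ex_idx <- which(types == "exon")
  if (strand == "+") {
    exons <- cbind(starts[ex_idx], ends[ex_idx])
  } else {
    region <- .revcomp(region)
    exons <- cbind(R - ends[ex_idx] + 1L, R - starts[ex_idx] + 1L)
    ord <- order(exons[, 1L])
    exons <- exons[ord, , drop = FALSE]
    phases <- phases[ord]  # phases now aligned to genomic-sorted exons
  }
  list(region = region, exons = exons, phases = phases)
}

#' Generate a complete synthetic corpus with planted ground truth
#'
#' Emits the focal proteome, a genome + annotation that realizes it (the
#' spliced CDS of every gene translates exactly to its protein), the
#' tiered homology databases with homologs planted at the configured
#' divergence, and a truth table. Conserved (EC) genes carry a diverged
#' copy in an outgroup database (protein or nucleotide), in a non-lineage
#' transcript set only, or in the curated protein database only; CSG
#' genes only in lineage transcript sets; orphan genes nowhere.
#'
#' @param config a [simulation_config].
#' @return list with `proteome` ([seq_db]), `genome` ([seq_db]), `models`
#'   (named list of [gene_model]), `chrom_lengths` (named vector, placed
#'   chromosomes only), `tiers` ([tier_config] with in-memory databases),
#'   `truth` (data.frame `gene_id`, `category`, `planted_db`,
#'   `divergence`) and `config`.
#' @export
simulate_corpus <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()")
  cfg <- config
  n <- cfg$n_ec + cfg$n_csg + cfg$n_orphan
  ids <- sprintf("g%03d", seq_len(n))
  category <- rep(c("EC", "CSG", "ORPHAN"),
                  c(cfg$n_ec, cfg$n_csg, cfg$n_orphan))

  ## --- focal proteins -----------------------------------------------------
  set.seed(.sub_seed(cfg$seed, "proteome"))
  lens <- vapply(category, function(cl) {
    r <- cfg$protein_len[[cl]]
    sample(seq(r[[1L]], r[[2L]]), 1L)
  }, integer(1L))
  proteins <- setNames(vapply(lens, .random_protein, character(1L)), ids)

  ## --- planted homolog placement ------------------------------------------
  set.seed(.sub_seed(cfg$seed, "planting"))
  planted_db <- rep(NA_character_, n)
  ec_idx <- which(category == "EC")
  n_cur <- round(cfg$frac_ec_curated_only * length(ec_idx))
  n_nl <- round(cfg$frac_ec_nonlineage_only * length(ec_idx))
  ec_curated <- ec_idx[seq_len(n_cur)]
  ec_nonlineage <- ec_idx[n_cur + seq_len(n_nl)]
  ec_outgroup <- setdiff(ec_idx, c(ec_curated, ec_nonlineage))
  csg_idx <- which(category == "CSG")

  outgroup_names <- sprintf("outgroup%02d", seq_len(cfg$n_outgroup))
  outgroup_type <- rep(c("protein", "nucleotide"),
                       length.out = cfg$n_outgroup)
  nonlineage_names <- sprintf("nonlineage%02d", seq_len(cfg$n_nonlineage))
  lineage_names <- sprintf("lineage%02d", seq_len(cfg$n_lineage))

  db_members <- list()  # db name -> named character of sequences
  add_member <- function(db, id, seq) {
    cur <- db_members[[db]] %||% character(0L)
    cur[[id]] <- seq
    db_members[[db]] <<- cur
  }
  codon_map <- .codon_map()
  embed_cds <- function(protein, flank = 120L) {
    cds <- .rev_translate(protein, 0.45, codon_map)
    paste0(.random_dna(flank), cds, .random_dna(flank))
  }
  for (i in ec_outgroup) {
    sp <- outgroup_names[[(match(i, ec_outgroup) - 1L) %%
                            cfg$n_outgroup + 1L]]
    hom <- mutate_sequence(proteins[[i]], cfg$divergence,
                           indel_rate = cfg$indel_rate)
    if (outgroup_type[[match(sp, outgroup_names)]] == "protein")
      add_member(sp, paste0(sp, "_", ids[[i]]), hom)
    else
      add_member(sp, paste0(sp, "_", ids[[i]]), embed_cds(hom))
    planted_db[[i]] <- sp
  }
  for (i in ec_nonlineage) {
    sp <- nonlineage_names[[(match(i, ec_nonlineage) - 1L) %%
                              cfg$n_nonlineage + 1L]]
    hom <- mutate_sequence(proteins[[i]], cfg$divergence,
                           indel_rate = cfg$indel_rate)
    add_member(sp, paste0(sp, "_", ids[[i]]), embed_cds(hom, flank = 40L))
    planted_db[[i]] <- sp
  }
  for (i in ec_curated) {
    hom <- mutate_sequence(proteins[[i]], cfg$divergence,
                           indel_rate = cfg$indel_rate)
    add_member("curated", paste0("curated_", ids[[i]]), hom)
    planted_db[[i]] <- "curated"
  }
  for (i in csg_idx) {
    sp <- lineage_names[[(match(i, csg_idx) - 1L) %% cfg$n_lineage + 1L]]
    hom <- mutate_sequence(proteins[[i]], cfg$divergence,
                           indel_rate = cfg$indel_rate)
    add_member(sp, paste0(sp, "_", ids[[i]]), embed_cds(hom, flank = 40L))
    planted_db[[i]] <- sp
  }
  ## decoys
  all_dbs <- c(outgroup_names, nonlineage_names, lineage_names, "curated")
  db_type <- setNames(c(outgroup_type,
                        rep("nucleotide", cfg$n_nonlineage),
                        rep("nucleotide", cfg$n_lineage), "protein"),
                      all_dbs)
  for (db in all_dbs) {
    for (k in seq_len(cfg$decoys_per_db)) {
      len <- sample(seq(cfg$decoy_len[[1L]], cfg$decoy_len[[2L]]), 1L)
      id <- sprintf("%s_decoy%02d", db, k)
      if (db_type[[db]] == "protein") add_member(db, id, .random_protein(len))
      else add_member(db, id, .random_dna(len * 3L))
    }
  }

  ## --- genome + annotation -------------------------------------------------
  set.seed(.sub_seed(cfg$seed, "annotation"))
  chrom_of <- character(n)
  n_unplaced <- round(cfg$frac_unplaced * n)
  unplaced_genes <- sample(n, n_unplaced)
  w <- cfg$chromosome_weights / sum(cfg$chromosome_weights)
  chrom_of[] <- paste0("chr", sample(cfg$n_chromosomes, n, replace = TRUE,
                                     prob = w))
  chrom_of[unplaced_genes] <- sprintf("scaffold_%03d",
                                      seq_along(unplaced_genes))
  strand_of <- sample(c("+", "-"), n, replace = TRUE)
  regions <- vector("list", n)
  for (i in seq_len(n)) {
    wts <- cfg$exon_count_weights[[category[[i]]]]
    n_ex <- sample(seq_along(wts), 1L, prob = wts)
    gc_t <- cfg$gc_target[[category[[i]]]] / 100
    cds <- .rev_translate(proteins[[i]], gc_t, codon_map)
    regions[[i]] <- .build_gene_region(cds, n_ex, gc_t, cfg$intron_len,
                                       strand_of[[i]])
  }
  chrom_names <- unique(chrom_of)
  chrom_seq <- setNames(character(length(chrom_names)), chrom_names)
  models <- vector("list", n)
  names(models) <- ids
  for (ch in chrom_names) {
    genes_here <- which(chrom_of == ch)
    pos <- 0L
    seqs <- character(0L)
    for (i in genes_here) {
      gap <- sample(seq(cfg$intergenic_len[[1L]], cfg$intergenic_len[[2L]]),
                    1L)
      seqs <- c(seqs, .random_dna(gap, 0.35), regions[[i]]$region)
      offset <- pos + gap
      r <- regions[[i]]
      models[[ids[[i]]]] <- gene_model(
        gene_id = ids[[i]], chromosome = ch, strand = strand_of[[i]],
        exons = r$exons + offset,
        cds = cbind(r$exons + offset, r$phases),
        protein_id = paste0(ids[[i]], ".t1"))
      pos <- offset + nchar(r$region)
    }
    tail_gap <- sample(seq(cfg$intergenic_len[[1L]],
                           cfg$intergenic_len[[2L]]), 1L)
    seqs <- c(seqs, .random_dna(tail_gap, 0.35))
    chrom_seq[[ch]] <- paste(seqs, collapse = "")
  }
  genome <- seq_db(chrom_seq, moltype = "nucleotide")
  placed <- grep("^chr", chrom_names, value = TRUE)
  placed <- placed[order(as.integer(sub("chr", "", placed)))]
  chrom_lengths <- setNames(nchar(chrom_seq[placed]), placed)

  ## --- tier configuration --------------------------------------------------
  mk_db <- function(nm) seq_db(db_members[[nm]],
                               moltype = db_type[[nm]])
  tiers <- tier_config(
    tier("outgroup_genomes", "outgroup_genomes",
         lapply(outgroup_names, mk_db)),
    tier("nonlineage_transcripts", "nonlineage_transcripts",
         lapply(nonlineage_names, mk_db)),
    tier("lineage_transcripts", "lineage_transcripts",
         lapply(lineage_names, mk_db)),
    tier("curated_validation", "curated_validation",
         list(mk_db("curated"))))

  truth <- data.frame(gene_id = ids, category = category,
                      planted_db = planted_db,
                      divergence = ifelse(is.na(planted_db), NA_real_,
                                          cfg$divergence),
                      stringsAsFactors = FALSE)
  list(proteome = seq_db(proteins, moltype = "protein"),
       genome = genome, models = models, chrom_lengths = chrom_lengths,
       tiers = tiers, truth = truth, config = cfg)
}

#' Simulate an RNA-seq count matrix with planted preferential genes
#'
#' Baseline per-gene RPKM is log-normal (median 1) and flat across
#' tissues; `n_preferential` genes instead get `pref_base_rpkm` in their
#' off-tissues and `pref_base_rpkm * pref_fold` in a planted tissue.
#' Counts are negative-binomial around the implied means (`nb_size = Inf`
#' gives noise-free rounded means); library sizes per
#' `config$library_size`.
#'
#' @param corpus output of [simulate_corpus] (supplies gene ids and
#'   exon-model lengths).
#' @param config a [simulation_config]; defaults to the corpus's.
#' @return list with `counts` (a [count_matrix]) and `truth` (data.frame
#'   `gene_id`, `true_preferential`, `base_rpkm`).
#' @export
simulate_counts <- function(corpus, config = corpus$config) {
  cfg <- config
  if (length(cfg$tissues) < 2L) stop("need at least 2 tissues")
  set.seed(.sub_seed(cfg$seed, "counts"))
  ids <- corpus$truth$gene_id
  exonic_length <- vapply(corpus$models[ids], function(m)
    sum(m$exons[, 2L] - m$exons[, 1L] + 1L), numeric(1L))
  n <- length(ids)
  tiss <- cfg$tissues
  lib <- setNames(cfg$library_size[seq_along(tiss)], tiss)
  n_pref <- min(cfg$n_preferential, n)
  pref_genes <- sample(n, n_pref)
  pref_tissue <- sample(tiss, n_pref, replace = TRUE)
  base <- exp(rnorm(n, 0, 1))  # flat decoy baseline, median 1 RPKM
  rpkm_mean <- matrix(base, n, length(tiss),
                      dimnames = list(ids, tiss))
  rpkm_mean[pref_genes, ] <- cfg$pref_base_rpkm
  rpkm_mean[cbind(pref_genes, match(pref_tissue, tiss))] <-
    cfg$pref_base_rpkm * cfg$pref_fold
  mu <- sweep(rpkm_mean * exonic_length / 1000, 2L, lib / 1e6, `*`)
  counts <- if (is.infinite(cfg$nb_size)) round(mu) else
    matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_size),
           nrow = n, dimnames = dimnames(mu))
  truth <- data.frame(gene_id = ids,
                      true_preferential = NA_character_,
                      base_rpkm = base, stringsAsFactors = FALSE)
  truth$true_preferential[pref_genes] <- pref_tissue
  truth$base_rpkm[pref_genes] <- cfg$pref_base_rpkm
  list(counts = count_matrix(counts, lib, setNames(exonic_length, ids)),
       truth = truth)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each target gene and sample, `Ct = baseline - log2(fold) + noise`;
#' the reference gene's fold is fixed at 1 everywhere. Responsive genes
#' carry their planted fold at every timepoint of one stress condition
#' (a configured fraction down-regulated, the rest up); all other folds
#' are exactly 1. The control condition is `"control"` at timepoint 0.
#'
#' @param config a [simulation_config].
#' @param gene_ids optional gene ids to use (default `q001`..);
#'   `config$qpcr_n_genes` genes are generated.
#' @return list with `ct` (data.frame `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct`), `truth` (data.frame `gene`, `condition`,
#'   `timepoint`, `true_fold`) and `responsive` (character vector).
#' @export
simulate_qpcr <- function(config, gene_ids = NULL) {
  cfg <- config
  if (cfg$qpcr_replicates < 1L) stop("need at least 1 replicate")
  set.seed(.sub_seed(cfg$seed, "qpcr"))
  n <- cfg$qpcr_n_genes
  genes <- gene_ids %||% sprintf("q%03d", seq_len(n))
  n <- length(genes)
  resp <- sample(genes, min(cfg$qpcr_n_responsive, n))
  resp_cond <- sample(names(cfg$qpcr_conditions), length(resp),
                      replace = TRUE)
  down <- runif(length(resp)) < cfg$qpcr_frac_down
  magnitude <- runif(length(resp), cfg$qpcr_fold_range[[1L]],
                     cfg$qpcr_fold_range[[2L]])
  resp_fold <- ifelse(down, 1 / magnitude, magnitude)
  baseline <- setNames(runif(n, 22, 30), genes)
  samples <- data.frame(condition = "control", timepoint = 0,
                        stringsAsFactors = FALSE)
  for (cond in names(cfg$qpcr_conditions))
    samples <- rbind(samples,
                     data.frame(condition = cond,
                                timepoint = cfg$qpcr_conditions[[cond]],
                                stringsAsFactors = FALSE))
  rows <- list()
  truth_rows <- list()
  all_genes <- c(cfg$reference_gene, genes)
  for (g in all_genes) {
    for (s in seq_len(nrow(samples))) {
      cond <- samples$condition[[s]]
      tp <- samples$timepoint[[s]]
      fold <- 1
      if (g %in% resp) {
        k <- match(g, resp)
        if (cond == resp_cond[[k]]) fold <- resp_fold[[k]]
      }
      if (g != cfg$reference_gene && cond != "control")
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = tp, true_fold = fold,
          stringsAsFactors = FALSE)
      base_g <- if (g == cfg$reference_gene) 20 else baseline[[g]]
      for (r in seq_len(cfg$qpcr_replicates)) {
        ct <- base_g - log2(fold) + rnorm(1L, 0, cfg$qpcr_ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = tp, replicate = r,
          ct = ct, stringsAsFactors = FALSE)
      }
    }
  }
  list(ct = do.call(rbind, rows), truth = do.call(rbind, truth_rows),
       responsive = sort(resp))
}

#' Write a simulated corpus to disk
#'
#' Emits `proteome.faa`, `genome.fna`, `annotation.gff3`,
#' `chrom_lengths.tsv`, `truth_table.tsv`, one FASTA per homology
#' database under `dbs/`, and a `tiers.yaml` cascade configuration
#' loadable with [read_tier_config].
#'
#' @param corpus output of [simulate_corpus].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "dbs"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(corpus$proteome, file.path(dir, "proteome.faa"))
  write_fasta(corpus$genome, file.path(dir, "genome.fna"))
  write_gene_models(corpus$models, file.path(dir, "annotation.gff3"))
  write_table(data.frame(chromosome = names(corpus$chrom_lengths),
                         length = unname(corpus$chrom_lengths)),
              file.path(dir, "chrom_lengths.tsv"))
  write_table(corpus$truth, file.path(dir, "truth_table.tsv"))
  tiers_yaml <- list(tiers = list())
  for (t in corpus$tiers$tiers) {
    dbs <- list()
    for (k in seq_along(t$databases)) {
      db <- t$databases[[k]]
      fn <- sprintf("dbs/%s_db%02d.fasta", t$name, k)
      write_fasta(db, file.path(dir, fn))
      dbs[[k]] <- list(path = fn, moltype = attr(db, "moltype"))
    }
    tiers_yaml$tiers[[length(tiers_yaml$tiers) + 1L]] <-
      list(name = t$name, role = t$role, databases = dbs,
           evalue_cutoff = t$evalue_cutoff)
  }
  yaml::write_yaml(tiers_yaml, file.path(dir, "tiers.yaml"))
  invisible(dir)
}
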