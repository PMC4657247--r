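## RPKM quantification, expression-class calls (expressed in all tissues,
## constitutive, tissue-preferential), tissue-pattern summary tables, and
## qPCR 2^-ddCt fold changes with stress-responsiveness calls.

#' Assemble a count matrix with its normalization metadata
#'
#' @param counts genes x tissues matrix of non-negative integer raw read
#'   counts, with gene ids as rownames and tissue names as colnames.
#' @param mapped_reads named positive numeric: total mapped reads per
#'   tissue (library size).
#' @param exonic_length named positive numeric: per-gene exon-model length
#'   in bp.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, mapped_reads, exonic_length) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs gene rownames and tissue colnames")
  if (ncol(counts) < 2L) stop("need at least 2 tissues")
  if (any(counts < 0)) stop("negative counts")
  if (!all(colnames(counts) %in% names(mapped_reads)))
    stop("mapped_reads missing for some tissues")
  if (!all(rownames(counts) %in% names(exonic_length)))
    stop("exonic_length missing for some genes")
  mapped_reads <- mapped_reads[colnames(counts)]
  exonic_length <- exonic_length[rownames(counts)]
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  if (any(exonic_length <= 0)) stop("zero exonic length for gene ",
                                    names(exonic_length)[exonic_length <= 0][[1L]])
  structure(list(counts = counts, mapped_reads = mapped_reads,
                 exonic_length = exonic_length), class = "count_matrix")
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm = count / (exonic_length / 1000) / (mapped_reads / 1e6)`.
#'
#' @param cm a [count_matrix].
#' @return genes x tissues numeric matrix of RPKM (zeros preserved).
#' @export
compute_rpkm <- function(cm) {
  if (!inherits(cm, "count_matrix")) stop("not a count_matrix")
  sweep(cm$counts / (cm$exonic_length / 1000), 2L,
        cm$mapped_reads / 1e6, `/`)
}

#' Transcripts per million (labeled extra)
#'
#' Length-normalized counts rescaled so each tissue sums to 1e6. Provided
#' for convenience; every call in this package is made on RPKM.
#'
#' @param cm a [count_matrix].
#' @return genes x tissues numeric matrix of TPM.
#' @export
compute_tpm <- function(cm) {
  r <- cm$counts / cm$exonic_length
  sweep(r, 2L, colSums(r) / 1e6, `/`)
}

#' Expression-class and tissue-preferential calls
#'
#' `expressed_all`: RPKM strictly above 0 in every tissue. `constitutive`:
#' RPKM strictly above `abundance_threshold` (default 2) in every tissue.
#' A gene is called preferential for its highest-RPKM tissue when both
#' rules hold: (1) at least one tissue above `abundance_threshold` RPKM;
#' (2) the top tissue exceeds `fold` times the RPKM of at least one other
#' tissue (`strict = FALSE`, the default, the literal reading) or of
#' every other tissue (`strict = TRUE`). All comparisons are strict
#' (ties at exactly `fold`-change fail); a zero comparison tissue
#' satisfies rule 2 without division. Ties for the top tissue are broken
#' by column order.
#'
#' @param rpkm genes x tissues RPKM matrix.
#' @param abundance_threshold RPKM threshold for rule 1 and the
#'   constitutive call.
#' @param fold fold-change required by rule 2.
#' @param strict require the fold margin over all other tissues.
#' @return data.frame: `gene_id`, `expressed_all`, `constitutive`,
#'   `preferential_tissue` (`NA` when not preferential), plus one RPKM
#'   column per tissue.
#' @export
call_preferential <- function(rpkm, abundance_threshold = 2, fold = 2,
                              strict = FALSE) {
  if (ncol(rpkm) < 2L) stop("need at least 2 tissues")
  tissues <- colnames(rpkm)
  top <- apply(rpkm, 1L, which.max)
  maxv <- rpkm[cbind(seq_len(nrow(rpkm)), top)]
  others_extreme <- vapply(seq_len(nrow(rpkm)), function(i) {
    o <- rpkm[i, -top[[i]]]
    if (strict) max(o) else min(o)
  }, numeric(1L))
  rule1 <- maxv > abundance_threshold
  rule2 <- maxv > fold * others_extreme
  pref <- ifelse(rule1 & rule2, tissues[top], NA_character_)
  out <- data.frame(
    gene_id = rownames(rpkm),
    expressed_all = apply(rpkm > 0, 1L, all),
    constitutive = apply(rpkm > abundance_threshold, 1L, all),
    preferential_tissue = pref,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rpkm, stringsAsFactors = FALSE))
}

#' Tissue expression pattern summary by gene category
#'
#' Two panels. `preferential`: per category, the number of genes called
#' preferential in each tissue, with percentages of the category's row
#' total. `high_abundance`: per category, the number of (gene, tissue)
#' cells with RPKM above `abundance_threshold` (a gene may count in
#' several tissues), with percentages of the row total. An empty category
#' row keeps zero counts and `NA` percentages.
#'
#' @param calls data.frame from [call_preferential] (must include the
#'   per-tissue RPKM columns), or a pre-tabulated category x tissue count
#'   matrix (then only row percentages are computed for that panel).
#' @param categories named character vector mapping gene_id to category;
#'   ignored when `calls` is already a count matrix.
#' @param tissues tissue column names (default: taken from the matrix).
#' @param abundance_threshold RPKM threshold for the high-abundance panel.
#' @return for data.frame input, list of two data.frames (`preferential`,
#'   `high_abundance`) with columns `category`, one `<tissue>_n` and
#'   `<tissue>_pct` pair per tissue, and `total`; for matrix input, a
#'   single data.frame of that shape.
#' @export
summarize_tissue_table <- function(calls, categories = NULL, tissues = NULL,
                                   abundance_threshold = 2) {
  if (is.matrix(calls)) return(.row_pct_table(calls))
  if (is.null(categories)) stop("categories required with per-gene calls")
  if (is.null(names(categories))) stop("categories must be named by gene id")
  unknown <- setdiff(calls$gene_id, names(categories))
  if (length(unknown))
    stop("no category for gene(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  cat_of <- categories[calls$gene_id]
  if (is.null(tissues))
    tissues <- setdiff(names(calls),
                       c("gene_id", "expressed_all", "constitutive",
                         "preferential_tissue"))
  cats <- sort(unique(unname(cat_of)))
  pref <- t(vapply(cats, function(cc)
    vapply(tissues, function(tt)
      sum(cat_of == cc & !is.na(calls$preferential_tissue) &
            calls$preferential_tissue == tt), integer(1L)),
    integer(length(tissues))))
  dimnames(pref) <- list(cats, tissues)
  high <- t(vapply(cats, function(cc)
    vapply(tissues, function(tt)
      sum(cat_of == cc & calls[[tt]] > abundance_threshold), integer(1L)),
    integer(length(tissues))))
  dimnames(high) <- list(cats, tissues)
  list(preferential = .row_pct_table(pref),
       high_abundance = .row_pct_table(high))
}

.row_pct_table <- function(counts) {
  if (is.null(colnames(counts))) stop("count matrix needs tissue colnames")
  totals <- rowSums(counts)
  out <- data.frame(category = rownames(counts) %||%
                      paste0("row", seq_len(nrow(counts))),
                    stringsAsFactors = FALSE)
  for (tt in colnames(counts)) {
    out[[paste0(tt, "_n")]] <- counts[, tt]
    out[[paste0(tt, "_pct")]] <- ifelse(totals > 0,
                                        100 * counts[, tt] / totals,
                                        NA_real_)
  }
  out$total <- totals
  rownames(out) <- NULL
  out
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference` (reference matched on
#' condition, timepoint and replicate). Per (gene, condition, timepoint),
#' `ddCt = mean dCt(treatment) - mean dCt(control)` and
#' `fold = 2^-ddCt`. The control mean is taken over all control-condition
#' samples of the gene. No amplification-efficiency correction is applied.
#'
#' @param ct data.frame with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct`.
#' @param reference_gene id of the internal reference gene; it must be
#'   measured in every (condition, timepoint, replicate) that any target
#'   occupies.
#' @param control_condition value of `condition` to use as calibrator.
#' @return data.frame: `gene`, `condition`, `timepoint`, `ddct`, `fold`,
#'   `fold_sd` (spread over per-replicate `2^-ddCt` values computed
#'   against the mean control dCt), `n_replicates`.
#' @export
ddct_fold_change <- function(ct, reference_gene, control_condition) {
  need <- c("gene", "condition", "timepoint", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (!reference_gene %in% ct$gene)
    stop("reference gene ", reference_gene, " not in the Ct table")
  if (!control_condition %in% ct$condition)
    stop("control condition ", control_condition, " not in the Ct table")
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  ref_key <- paste(ref$condition, ref$timepoint, ref$replicate, sep = "\r")
  targets <- ct[ct$gene != reference_gene, , drop = FALSE]
  key <- paste(targets$condition, targets$timepoint, targets$replicate,
               sep = "\r")
  miss <- !(key %in% ref_key)
  if (any(miss)) {
    k <- which(miss)[[1L]]
    stop("reference well missing for sample (condition=",
         targets$condition[[k]], ", timepoint=", targets$timepoint[[k]],
         ", replicate=", targets$replicate[[k]], ")")
  }
  targets$dct <- targets$ct - ref$ct[match(key, ref_key)]
  rows <- list()
  for (g in unique(targets$gene)) {
    tg <- targets[targets$gene == g, , drop = FALSE]
    ctrl <- tg$dct[tg$condition == control_condition]
    if (!length(ctrl))
      stop("gene ", g, " has no control-condition measurements")
    ctrl_mean <- mean(ctrl)
    trt <- tg[tg$condition != control_condition, , drop = FALSE]
    for (cond in unique(trt$condition)) {
      for (tp in unique(trt$timepoint[trt$condition == cond])) {
        d <- trt$dct[trt$condition == cond & trt$timepoint == tp]
        ddct <- mean(d) - ctrl_mean
        per_rep <- 2^-(d - ctrl_mean)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = tp, ddct = ddct,
          fold = 2^-ddct,
          fold_sd = if (length(per_rep) > 1L) sd(per_rep) else NA_real_,
          n_replicates = length(d), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Call stress-responsive genes from qPCR fold changes
#'
#' Per (gene, stress condition): `"up"` if `fold >= threshold` at any
#' post-treatment timepoint, `"down"` if `fold <= 1/threshold` at any
#' timepoint, `"unchanged"` otherwise (a gene both up and down across
#' timepoints is reported `"up_down"`). A gene is responsive if up or
#' down for at least one stress.
#'
#' @param folds data.frame from [ddct_fold_change].
#' @param threshold fold-change cutoff (> 1; default 2).
#' @return list with `calls` (data.frame `gene`, `condition`, `call`) and
#'   `responsive` (character vector of responsive gene ids).
#' @export
call_stress_responsive <- function(folds, threshold = 2) {
  if (threshold <= 1) stop("threshold must exceed 1")
  keys <- unique(folds[, c("gene", "condition")])
  call <- character(nrow(keys))
  for (k in seq_len(nrow(keys))) {
    f <- folds$fold[folds$gene == keys$gene[[k]] &
                      folds$condition == keys$condition[[k]]]
    up <- any(f >= threshold)
    down <- any(f <= 1 / threshold)
    call[[k]] <- if (up && down) "up_down" else if (up) "up" else
      if (down) "down" else "unchanged"
  }
  keys$call <- call
  rownames(keys) <- NULL
  list(calls = keys,
       responsive = sort(unique(keys$gene[keys$call != "unchanged"])))
}
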