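## Sequence sets, gene models, and the tabular reports the pipeline emits.
##
## A sequence set (`seq_db`) is a named character vector of residue strings
## with a `moltype` attribute ("protein" or "nucleotide") and an optional
## `descriptions` attribute. Coordinates everywhere follow the GFF3
## convention: 1-based, inclusive, genomic.

.PROTEIN_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX*"
.NT_ALPHABET <- "ACGTN"

#' Construct a sequence set
#'
#' @param residues named character vector of residue strings; names are the
#'   sequence ids (whitespace-free, unique).
#' @param moltype `"protein"` or `"nucleotide"`.
#' @param descriptions optional character vector of free-text descriptions,
#'   same length as `residues`.
#' @return a `seq_db` object (named character vector with attributes).
#' @export
seq_db <- function(residues, moltype = c("protein", "nucleotide"),
                   descriptions = NULL) {
  moltype <- match.arg(moltype)
  if (length(residues) == 0L)
    return(structure(setNames(character(0L), character(0L)),
                     moltype = moltype, descriptions = NULL,
                     cache = new.env(parent = emptyenv()),
                     class = "seq_db"))
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id")
  if (any(grepl("[[:space:]]", ids)))
    stop("sequence ids must not contain whitespace")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[[1L]])
  residues <- toupper(as.character(residues))
  names(residues) <- ids
  if (any(!nzchar(residues)))
    stop("empty residue string for id: ", ids[!nzchar(residues)][[1L]])
  .check_alphabet(residues, moltype)
  structure(residues, moltype = moltype,
            descriptions = descriptions, cache = new.env(parent = emptyenv()),
            class = "seq_db")
}

.check_alphabet <- function(residues, moltype) {
  allowed <- if (moltype == "protein") .PROTEIN_ALPHABET else .NT_ALPHABET
  bad <- regexpr(sprintf("[^%s]", gsub("\\*", "\\\\*", allowed)), residues)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[[1L]]
    stop(sprintf("illegal %s residue '%s' at position %d in sequence '%s'",
                 moltype, substr(residues[[k]], bad[[k]], bad[[k]]),
                 bad[[k]], names(residues)[[k]]))
  }
  invisible(TRUE)
}

#' @export
print.seq_db <- function(x, ...) {
  cat(sprintf("<seq_db: %d %s sequence(s), %d residues>\n",
              length(x), attr(x, "moltype"), sum(nchar(x))))
  invisible(x)
}

#' @export
`[.seq_db` <- function(x, i) {
  seq_db(unclass(x)[i], moltype = attr(x, "moltype"),
         descriptions = attr(x, "descriptions")[i])
}

#' Read a FASTA file
#'
#' Residues are uppercased; record order is preserved. The id is the first
#' whitespace-delimited token of the header, the remainder (if any) the
#' description.
#'
#' @param path path to a FASTA file.
#' @param moltype `"protein"` or `"nucleotide"`; residues are validated
#'   against the corresponding alphabet (protein: the 20 amino acids plus
#'   `X` and `*`; nucleotide: `ACGTN`).
#' @return a [seq_db] object.
#' @export
read_fasta <- function(path, moltype = c("protein", "nucleotide")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  res <- setNames(as.character(set), ids)
  seq_db(res, moltype = moltype, descriptions = desc)
}

#' Write a FASTA file
#'
#' @param db a [seq_db] object.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  ids <- names(db)
  desc <- attr(db, "descriptions")
  headers <- if (is.null(desc)) ids else
    ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(db)) {
    writeLines(paste0(">", headers[[k]]), con)
    seqk <- db[[k]]
    starts <- seq.int(1L, nchar(seqk), by = width)
    writeLines(substring(seqk, starts, pmin(starts + width - 1L, nchar(seqk))),
               con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' Intervals are 1-based inclusive genomic coordinates. Exons must be
#' non-overlapping; they are stored sorted ascending. Every CDS interval
#' must fall within the exon union.
#'
#' @param gene_id,chromosome,strand,protein_id scalar identifiers; strand is
#'   `"+"` or `"-"`.
#' @param exons two-column matrix (start, end).
#' @param cds three-column matrix (start, end, phase); phase per GFF3.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds,
                       protein_id = gene_id) {
  if (!strand %in% c("+", "-"))
    stop("unknown strand symbol '", strand, "' for gene ", gene_id)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene ", gene_id, " has no exons")
  if (any(exons[, 1L] > exons[, 2L]))
    stop("exon with start > end in gene ", gene_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping exons in gene ", gene_id)
  cds <- matrix(as.integer(cds), ncol = 3L,
                dimnames = list(NULL, c("start", "end", "phase")))
  if (any(cds[, 1L] > cds[, 2L]))
    stop("CDS with start > end in gene ", gene_id)
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  for (k in seq_len(nrow(cds))) {
    inside <- any(cds[k, 1L] >= exons[, 1L] & cds[k, 2L] <= exons[, 2L])
    if (!inside)
      stop("CDS interval [", cds[k, 1L], ",", cds[k, 2L],
           "] outside exons in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 exons = exons, cds = cds, protein_id = protein_id),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s: %s%s, %d exon(s), span %d-%d>\n",
              x$gene_id, x$chromosome, x$strand, nrow(x$exons),
              min(x$exons[, 1L]), max(x$exons[, 2L])))
  invisible(x)
}

#' Genomic span length of a gene model
#' @param model a [gene_model].
#' @return integer: `max(exon end) - min(exon start) + 1`.
#' @export
gene_span_length <- function(model) {
  max(model$exons[, 2L]) - min(model$exons[, 1L]) + 1L
}

#' Read gene models from a GFF3 annotation
#'
#' Expects `gene`, `mRNA`, `exon` and `CDS` features linked by `ID`/`Parent`
#' attributes. Genes with several mRNAs are resolved to the single transcript
#' with the longest total CDS (ties broken by mRNA id, lexicographic).
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model] objects, in file order of the genes.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand", "phase"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type == "mRNA", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  cdss <- g[g$type == "CDS", , drop = FALSE]
  out <- vector("list", nrow(genes))
  for (k in seq_len(nrow(genes))) {
    gid <- genes$ID[[k]]
    mk <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, , drop = FALSE]
    if (nrow(mk) == 0L) stop("gene ", gid, " has no mRNA")
    cds_len <- vapply(mk$ID, function(mid) {
      ck <- cdss[cdss$Parent == mid, , drop = FALSE]
      sum(ck$end - ck$start + 1L)
    }, integer(1L))
    pick <- mk$ID[order(-cds_len, mk$ID)][[1L]]
    ek <- exons[exons$Parent == pick, , drop = FALSE]
    ck <- cdss[cdss$Parent == pick, , drop = FALSE]
    if (nrow(ek) == 0L) stop("mRNA ", pick, " has no exons")
    strand <- as.character(genes$strand[[k]])
    phase <- suppressWarnings(as.integer(as.character(ck$phase)))
    phase[is.na(phase)] <- 0L
    out[[k]] <- gene_model(
      gene_id = gid, chromosome = as.character(genes$seqid[[k]]),
      strand = strand,
      exons = cbind(ek$start, ek$end),
      cds = cbind(ck$start, ck$end, phase),
      protein_id = pick)
  }
  names(out) <- genes$ID
  out
}

#' Write gene models as GFF3
#'
#' @param models list of [gene_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons[, 1L]), max(m$exons[, 2L]))
    row <- function(type, s, e, phase, attrs)
      paste(m$chromosome, "lsgkit", type, s, e, ".", m$strand,
            phase, attrs, sep = "\t")
    lines <- c(lines,
               row("gene", span[1L], span[2L], ".",
                   paste0("ID=", m$gene_id)),
               row("mRNA", span[1L], span[2L], ".",
                   paste0("ID=", m$protein_id, ";Parent=", m$gene_id)))
    for (k in seq_len(nrow(m$exons)))
      lines <- c(lines, row("exon", m$exons[k, 1L], m$exons[k, 2L], ".",
                            paste0("ID=", m$protein_id, ".exon", k,
                                   ";Parent=", m$protein_id)))
    ## GFF3 phase is given in transcription order
    ord <- if (m$strand == "+") seq_len(nrow(m$cds)) else rev(seq_len(nrow(m$cds)))
    for (k in ord)
      lines <- c(lines, row("CDS", m$cds[k, 1L], m$cds[k, 2L],
                            m$cds[k, 3L],
                            paste0("ID=", m$protein_id, ".cds",
                                   ";Parent=", m$protein_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a tab-separated report
#'
#' Header line first, UTF-8, `"."` for missing values.
#'
#' @param rows a data.frame, or a list of uniform named lists/vectors.
#' @param path output path.
#' @param columns optional character vector giving column order.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, columns = NULL) {
  if (!is.data.frame(rows)) {
    if (!length(rows) && !is.null(columns)) {
      rows <- as.data.frame(setNames(rep(list(character(0L)),
                                         length(columns)), columns))
      columns <- NULL
    } else if (length(rows)) {
      schema <- names(rows[[1L]])
      ok <- vapply(rows, function(r) identical(names(r), schema), logical(1L))
      if (!all(ok)) stop("ragged rows: row ", which(!ok)[[1L]],
                         " does not match the schema of row 1")
      rows <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      stop("cannot infer a schema from an empty list; pass `columns`")
    }
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(rows))
    if (length(missing_cols))
      stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
    rows <- rows[, columns, drop = FALSE]
  }
  write.table(rows, path, sep = "\t", quote = FALSE, na = ".",
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated report written by [write_table]
#' @param path input path.
#' @return a data.frame; `"."` cells become `NA`.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", na.strings = ".", check.names = FALSE,
             stringsAsFactors = FALSE)
}
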