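## Reference homology-search engine: Smith-Waterman affine-gap local
## alignment scored with BLOSUM62 by default, significance from
## Karlin-Altschul statistics E = K * m * n * exp(-lambda * S), and a
## six-frame translated mode for protein-vs-nucleotide searches.
##
## Heuristic seeding (word hits, two-hit extension), composition-based
## statistics and HSP chaining are deliberately out of scope: at desk scale
## exact Smith-Waterman is affordable and makes the thresholding behaviour
## fully deterministic.

#' Built-in BLOSUM62 substitution matrix
#'
#' The BLOSUM62 matrix shipped with Biostrings (24-letter alphabet including
#' `B`, `Z`, `X` and `*`).
#'
#' @return integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "integer"
  m
}

#' Scoring scheme for local alignment and E-values
#'
#' Gap cost convention: a gap of length `k` costs
#' `gap_open + k * gap_extend`. The Karlin-Altschul parameters default to
#' published values for gapped BLOSUM62 with these penalties
#' (`lambda = 0.267`, `K = 0.041`); absolute E-values are therefore
#' comparable across runs but are not calibrated against any particular
#' external search tool.
#'
#' @param substitution symmetric integer substitution matrix with residue
#'   dimnames; default [blosum62()].
#' @param gap_open,gap_extend positive integer gap penalties;
#'   `gap_extend <= gap_open`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(substitution = blosum62(), gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (is.null(rownames(substitution)) ||
      !identical(rownames(substitution), colnames(substitution)))
    stop("substitution matrix needs identical row/column residue names")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  storage.mode(substitution) <- "integer"
  structure(list(substitution = substitution,
                 alphabet = paste(rownames(substitution), collapse = ""),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Read an NCBI-format substitution matrix file
#'
#' Plain-text matrix with a header row of residues and one labelled row per
#' residue; `#` lines are comments.
#'
#' @param path path to the matrix file.
#' @return integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  body <- strsplit(trimws(lines[-1L]), "\\s+")
  rows <- vapply(body, `[[`, character(1L), 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1L]),
                   integer(length(header))))
  dimnames(vals) <- list(rows, header)
  vals
}

## vectorized codon translation against the standard genetic code
## (Biostrings' GENETIC_CODE table); codons containing N or any other
## ambiguity translate to X
.translate_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the given strand, -1..-3 the reverse complement,
#' under the standard genetic code. Each frame is split into peptide
#' segments at stop codons; segments shorter than `min_len` residues are
#' discarded (sub-10-residue segments cannot reach significance at the
#' default E-value cutoff).
#'
#' @param nt a nucleotide string (codons containing `N` translate to `X`).
#' @param min_len minimum segment length to keep.
#' @return named list of six character vectors of peptide segments, names
#'   `"+1" "+2" "+3" "-1" "-2" "-3"`.
#' @export
translate_six_frames <- function(nt, min_len = 10L) {
  nt <- toupper(as.character(nt)[[1L]])
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- setNames(vector("list", 6L), frames)
  if (nchar(nt) < 3L) {
    out[] <- list(character(0L))
    return(out)
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      src <- if (strand == "+") nt else rc
      pep <- .translate_codons(substr(src, f, nchar(src)))
      segs <- strsplit(pep, "*", fixed = TRUE)[[1L]]
      out[[paste0(strand, f)]] <- segs[nchar(segs) >= min_len]
    }
  }
  out
}

#' Optimal local alignment of two peptides
#'
#' Smith-Waterman with affine gaps under `scheme`. Ties are broken
#' deterministically: the reported alignment ends at the first maximal cell
#' in query-then-subject scan order, and the traceback prefers diagonal
#' over gap-in-subject over gap-in-query.
#'
#' @param query,subject peptide strings.
#' @param scheme a [scoring_scheme].
#' @return list with `score` (integer >= 0) and 1-based inclusive spans
#'   `q_start`, `q_end`, `s_start`, `s_end` (all 0 when the optimal score
#'   is 0, i.e. no positive-scoring path exists).
#' @export
align_local <- function(query, subject, scheme = scoring_scheme()) {
  query <- as.character(query)[[1L]]
  subject <- as.character(subject)[[1L]]
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty")
  sw_align_cpp(query, subject, scheme$substitution, scheme$alphabet,
               scheme$gap_open, scheme$gap_extend)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a search of a length-`m` query
#' against `n` database residues.
#'
#' @param raw_score integer alignment score.
#' @param m query length in residues.
#' @param n database size in residues.
#' @param scheme a [scoring_scheme] supplying `lambda` and `K`.
#' @return positive E-value (vectorized over `raw_score`).
#' @export
evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1L) || any(n < 1L)) stop("m and n must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue
#' @return normalized score in bits.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

.db_residue_count <- function(db, mode, min_len = 10L) {
  if (mode == "protein") return(sum(nchar(db)))
  ## translated mode: residues actually searched (kept peptide segments)
  sum(vapply(names(db), function(sid)
    sum(nchar(unlist(.six_frame_cached(db, sid, min_len)))),
    numeric(1L)))
}

.six_frame_cached <- function(db, sid, min_len = 10L) {
  ## memoise six-frame translations on the seq_db so repeated queries
  ## against the same database translate each subject once
  cache <- attr(db, "cache")
  if (is.null(cache)) return(translate_six_frames(db[[sid]], min_len))
  key <- paste0(sid, "#", min_len)
  if (is.null(cache[[key]]))
    cache[[key]] <- translate_six_frames(db[[sid]], min_len)
  cache[[key]]
}

.align_subject <- function(query, db, sid, mode, scheme, min_len = 10L) {
  ## best alignment of query against one subject; translated mode scans all
  ## six frames and reports the best frame/segment
  if (mode == "protein") {
    a <- align_local(query, db[[sid]], scheme)
    return(c(a, list(frame = 0L)))
  }
  frames <- .six_frame_cached(db, sid, min_len)
  segs <- unlist(frames, use.names = FALSE)
  if (is.null(segs) || !length(segs))
    return(list(score = 0L, q_start = 0L, q_end = 0L, s_start = 0L,
                s_end = 0L, frame = 0L))
  seg_frame <- rep(names(frames), lengths(frames))
  a <- sw_best_cpp(query, segs, scheme$substitution, scheme$alphabet,
                   scheme$gap_open, scheme$gap_extend)
  frame <- if (a$index > 0L) as.integer(seg_frame[[a$index]]) else 0L
  list(score = a$score, q_start = a$q_start, q_end = a$q_end,
       s_start = a$s_start, s_end = a$s_end, frame = frame)
}

#' Search a peptide query against a sequence database
#'
#' Every database sequence is aligned with [align_local] (translated mode:
#' against every six-frame peptide segment, reporting the best frame per
#' subject) and hits with `evalue < evalue_cutoff` (strict) are returned
#' sorted by ascending E-value, ties by subject id. The database size `n`
#' for the E-value is the total residue count actually searched.
#'
#' @param query a single named peptide (named character of length 1), or an
#'   unnamed string (query_id `"query"`).
#' @param db a [seq_db]; moltype must match `mode`.
#' @param mode `"protein"` (BLASTp-like) or `"translated_nucleotide"`
#'   (tBLASTn-like).
#' @param scheme a [scoring_scheme].
#' @param evalue_cutoff strict significance cutoff (default `1e-5`).
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `raw_score`, `bitscore`, `evalue`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `frame` (0 for protein subjects; translated spans are in the
#'   coordinates of the best-scoring peptide segment).
#' @export
search_db <- function(query, db, mode = c("protein", "translated_nucleotide"),
                      scheme = scoring_scheme(), evalue_cutoff = 1e-5) {
  mode <- match.arg(mode)
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  if (length(db) == 0L) stop("database is empty")
  .check_search_mode(db, mode)
  qid <- if (!is.null(names(query))) names(query)[[1L]] else "query"
  qseq <- as.character(query)[[1L]]
  n <- .db_residue_count(db, mode)
  m <- nchar(qseq)
  rows <- list()
  for (sid in names(db)) {
    a <- .align_subject(qseq, db, sid, mode, scheme)
    if (a$score <= 0L) next
    e <- evalue(a$score, m, n, scheme)
    if (e < evalue_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid, raw_score = a$score,
        bitscore = bitscore(a$score, scheme), evalue = e,
        q_start = a$q_start, q_end = a$q_end,
        s_start = a$s_start, s_end = a$s_end, frame = a$frame,
        stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(0L), subject_id = character(0L),
               raw_score = integer(0L), bitscore = numeric(0L),
               evalue = numeric(0L), q_start = integer(0L),
               q_end = integer(0L), s_start = integer(0L),
               s_end = integer(0L), frame = integer(0L),
               stringsAsFactors = FALSE)
  hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
}

.check_search_mode <- function(db, mode) {
  want <- if (mode == "protein") "protein" else "nucleotide"
  have <- attr(db, "moltype")
  if (!identical(have, want))
    stop("search mode '", mode, "' requires a ", want,
         " database, got ", have)
  invisible(TRUE)
}

#' Does a query have any significant hit in a database?
#'
#' Equivalent to `nrow(search_db(...)) > 0` but short-circuits on the first
#' subject with `evalue < evalue_cutoff`. The hit returned is the first
#' significant one encountered in database order (the full ranking is
#' available from [search_db]).
#'
#' @inheritParams search_db
#' @return list with `significant` (logical) and `hit` (one-row hit
#'   data.frame, or `NULL`).
#' @export
has_significant_hit <- function(query, db,
                                mode = c("protein", "translated_nucleotide"),
                                scheme = scoring_scheme(),
                                evalue_cutoff = 1e-5) {
  mode <- match.arg(mode)
  if (length(db) == 0L) return(list(significant = FALSE, hit = NULL))
  .check_search_mode(db, mode)
  qid <- if (!is.null(names(query))) names(query)[[1L]] else "query"
  qseq <- as.character(query)[[1L]]
  n <- .db_residue_count(db, mode)
  m <- nchar(qseq)
  for (sid in names(db)) {
    a <- .align_subject(qseq, db, sid, mode, scheme)
    if (a$score <= 0L) next
    e <- evalue(a$score, m, n, scheme)
    if (e < evalue_cutoff) {
      hit <- data.frame(query_id = qid, subject_id = sid,
                        raw_score = a$score,
                        bitscore = bitscore(a$score, scheme), evalue = e,
                        q_start = a$q_start, q_end = a$q_end,
                        s_start = a$s_start, s_end = a$s_end,
                        frame = a$frame, stringsAsFactors = FALSE)
      return(list(significant = TRUE, hit = hit))
    }
  }
  list(significant = FALSE, hit = NULL)
}
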