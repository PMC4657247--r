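## The classification cascade: every focal gene is pushed through ordered
## homology tiers and eliminated at the first tier where it finds a
## significant hit.
##
##   outgroup_genomes hit        -> EC (evolutionarily conserved)
##   nonlineage_transcripts hit  -> EC
##   lineage_transcripts hit     -> provisional CSG (lineage-specific with
##                                  relatives inside the lineage)
##   no hit anywhere             -> provisional ORPHAN
##   curated_validation hit      -> provisional CSG/ORPHAN reassigned to EC
##
## The curated tier models post-hoc screening against curated protein
## knowledgebases; an allowlist of gene ids can force-retain genes as LSGs
## in place of manual curation of the alignments.

.TIER_ROLES <- c("outgroup_genomes", "nonlineage_transcripts",
                 "lineage_transcripts", "curated_validation")

#' Define one homology tier
#'
#' @param name tier label used in outcomes and the stage ledger.
#' @param role one of `"outgroup_genomes"`, `"nonlineage_transcripts"`,
#'   `"lineage_transcripts"`, `"curated_validation"`.
#' @param databases list of databases; each either a [seq_db] or a list
#'   `list(path=, moltype=)` to be loaded lazily. A tier may mix protein
#'   databases (searched BLASTp-like) and nucleotide databases (searched
#'   tBLASTn-like via six-frame translation).
#' @param evalue_cutoff strict significance cutoff for this tier.
#' @return a `tier` object.
#' @export
tier <- function(name, role, databases, evalue_cutoff = 1e-5) {
  role <- match.arg(role, .TIER_ROLES)
  if (!length(databases)) stop("tier '", name, "' has no databases")
  databases <- lapply(databases, function(d) {
    if (inherits(d, "seq_db")) return(d)
    if (is.list(d) && !is.null(d$path))
      return(read_fasta(d$path, moltype = d$moltype))
    stop("each database must be a seq_db or list(path=, moltype=)")
  })
  empty <- vapply(databases, length, integer(1L)) == 0L
  if (any(empty)) stop("tier '", name, "' contains an empty database")
  structure(list(name = name, role = role, databases = databases,
                 evalue_cutoff = evalue_cutoff), class = "tier")
}

#' Assemble an ordered tier configuration
#'
#' Tiers must appear in cascade order (outgroup genomes, then non-lineage
#' transcripts, then lineage transcripts, then optionally curated
#' validation); the three decision-making roles are mandatory.
#'
#' @param ... [tier] objects in cascade order.
#' @param allowlist character vector of gene ids to force-retain as LSGs at
#'   the curated tier (the reproducible stand-in for manual curation).
#' @return a `tier_config` object.
#' @export
tier_config <- function(..., allowlist = character(0L)) {
  tiers <- list(...)
  if (length(tiers) == 1L && !inherits(tiers[[1L]], "tier"))
    tiers <- tiers[[1L]]
  if (!length(tiers)) stop("empty tier list")
  roles <- vapply(tiers, `[[`, character(1L), "role")
  need <- c("outgroup_genomes", "nonlineage_transcripts",
            "lineage_transcripts")
  if (!all(need %in% roles))
    stop("missing decision-making tier role(s): ",
         paste(setdiff(need, roles), collapse = ", "))
  if (is.unsorted(match(roles, .TIER_ROLES)))
    stop("tiers out of cascade order: ", paste(roles, collapse = " -> "))
  structure(list(tiers = tiers, allowlist = allowlist),
            class = "tier_config")
}

#' Read a tier configuration from a YAML file
#'
#' Schema: top-level `tiers:` list, each with `name`, `role`, `databases`
#' (list of `{path, moltype}`), optional `evalue_cutoff`; optional top-level
#' `allowlist` (list of gene ids) and `defaults: {evalue_cutoff}`.
#'
#' @param path YAML config path; relative database paths are resolved
#'   against the config file's directory.
#' @return a `tier_config` object.
#' @export
read_tier_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  default_cutoff <- cfg$defaults$evalue_cutoff %||% 1e-5
  tiers <- lapply(cfg$tiers, function(t) {
    dbs <- lapply(t$databases, function(d) {
      p <- d$path
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
      list(path = p, moltype = d$moltype)
    })
    tier(t$name, t$role, dbs, t$evalue_cutoff %||% default_cutoff)
  })
  tier_config(tiers, allowlist = as.character(unlist(cfg$allowlist)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.search_mode_for <- function(db) {
  if (attr(db, "moltype") == "protein") "protein" else "translated_nucleotide"
}

.tier_hit <- function(protein, t, scheme) {
  ## databases inside one tier are tried in listed order with short-circuit;
  ## by the order-independence property this is an optimization only
  for (db in t$databases) {
    r <- has_significant_hit(protein, db, mode = .search_mode_for(db),
                             scheme = scheme,
                             evalue_cutoff = t$evalue_cutoff)
    if (r$significant) return(r$hit)
  }
  NULL
}

#' Classify one gene through the cascade
#'
#' @param protein named character of length 1: the gene's protein sequence,
#'   named by its gene id.
#' @param tiers a [tier_config].
#' @param scheme a [scoring_scheme].
#' @return list with `gene_id`, `category` (`"EC"`, `"CSG"` or
#'   `"ORPHAN"`), `eliminated_at` (tier name or `NA`) and `best_hit`
#'   (one-row hit data.frame or `NULL`). Proteins consisting solely of
#'   ambiguity residues (`X`) carry no alignable signal and are classified
#'   ORPHAN with a warning.
#' @export
classify_gene <- function(protein, tiers, scheme = scoring_scheme()) {
  if (!inherits(tiers, "tier_config")) stop("tiers must be a tier_config")
  gid <- names(protein)[[1L]]
  if (is.null(gid)) stop("protein must be named by its gene id")
  if (!nzchar(protein[[1L]])) stop("empty protein for gene ", gid)
  if (grepl("^X+$", protein[[1L]])) {
    warning("gene ", gid, " is all-ambiguity (X); classified ORPHAN")
    return(list(gene_id = gid, category = "ORPHAN",
                eliminated_at = NA_character_, best_hit = NULL,
                provisional_category = "ORPHAN"))
  }
  category <- NA_character_   # provisional CSG once a lineage hit is found
  eliminated_at <- NA_character_
  best_hit <- NULL
  for (t in tiers$tiers) {
    if (t$role == "curated_validation") {
      ## only provisional LSGs are re-screened
      if (gid %in% tiers$allowlist) next
      hit <- .tier_hit(protein, t, scheme)
      if (!is.null(hit)) {
        provisional <- if (identical(category, "CSG")) "CSG" else "ORPHAN"
        return(list(gene_id = gid, category = "EC", eliminated_at = t$name,
                    best_hit = hit, provisional_category = provisional))
      }
      next
    }
    if (!is.na(category)) next  # already provisionally CSG; decision stands
    hit <- .tier_hit(protein, t, scheme)
    if (is.null(hit)) next
    if (t$role %in% c("outgroup_genomes", "nonlineage_transcripts")) {
      return(list(gene_id = gid, category = "EC", eliminated_at = t$name,
                  best_hit = hit, provisional_category = "EC"))
    }
    ## lineage_transcripts: provisional CSG, may still be reassigned by the
    ## curated tier
    category <- "CSG"
    eliminated_at <- t$name
    best_hit <- hit
  }
  if (is.na(category)) category <- "ORPHAN"
  list(gene_id = gid, category = category, eliminated_at = eliminated_at,
       best_hit = best_hit, provisional_category = category)
}

#' Run the full classification cascade over a proteome
#'
#' @param proteome a protein [seq_db] (one protein per gene; ids unique).
#' @param tiers a [tier_config].
#' @param scheme a [scoring_scheme].
#' @return list with `outcomes` (data.frame: `gene_id`, `category`,
#'   `eliminated_at`, `best_subject`, `best_evalue`) and `ledger` (a
#'   [stage_ledger]); the ledger is reconciled before return.
#' @export
run_pipeline <- function(proteome, tiers, scheme = scoring_scheme()) {
  if (anyDuplicated(names(proteome)))
    stop("duplicate gene ids in proteome")
  outcomes <- vector("list", length(proteome))
  for (k in seq_along(proteome)) {
    gid <- names(proteome)[[k]]
    o <- tryCatch(
      classify_gene(setNames(proteome[[k]], gid), tiers, scheme),
      error = function(e) stop("gene ", gid, ": ", conditionMessage(e),
                               call. = FALSE))
    outcomes[[k]] <- o
  }
  df <- data.frame(
    gene_id = vapply(outcomes, `[[`, character(1L), "gene_id"),
    category = vapply(outcomes, `[[`, character(1L), "category"),
    eliminated_at = vapply(outcomes, `[[`, character(1L), "eliminated_at"),
    best_subject = vapply(outcomes, function(o)
      if (is.null(o$best_hit)) NA_character_ else o$best_hit$subject_id,
      character(1L)),
    best_evalue = vapply(outcomes, function(o)
      if (is.null(o$best_hit)) NA_real_ else o$best_hit$evalue,
      numeric(1L)),
    provisional_category = vapply(outcomes, `[[`, character(1L),
                                  "provisional_category"),
    stringsAsFactors = FALSE)
  ledger <- .ledger_from_outcomes(df, tiers)
  reconcile_ledger(ledger)
  list(outcomes = df, ledger = ledger)
}

.ledger_from_outcomes <- function(df, tiers) {
  roles <- vapply(tiers$tiers, `[[`, character(1L), "role")
  names(roles) <- vapply(tiers$tiers, `[[`, character(1L), "name")
  at_role <- function(role) !is.na(df$eliminated_at) &
    roles[df$eliminated_at] == role
  stage_ledger(
    total_input = nrow(df),
    eliminated_outgroup = sum(at_role("outgroup_genomes")),
    eliminated_nonlineage = sum(at_role("nonlineage_transcripts")),
    provisional_csg = sum(df$provisional_category == "CSG"),
    provisional_orphan = sum(df$provisional_category == "ORPHAN"),
    curated_eliminated_csg = sum(df$category == "EC" &
                                   df$provisional_category == "CSG"),
    curated_eliminated_orphan = sum(df$category == "EC" &
                                      df$provisional_category == "ORPHAN"))
}

#' Per-stage elimination bookkeeping for a cascade run
#'
#' All counts are gene counts. `provisional_csg`/`provisional_orphan` are
#' the pre-curated-tier categories; the curated eliminations are split by
#' prior provisional category.
#'
#' @param total_input genes entering the cascade.
#' @param eliminated_outgroup genes with a hit in the outgroup-genomes tier.
#' @param eliminated_nonlineage genes with a hit in the non-lineage
#'   transcripts tier.
#' @param provisional_csg,provisional_orphan provisional category counts
#'   after the lineage tier.
#' @param curated_eliminated_csg,curated_eliminated_orphan provisional
#'   CSG/ORPHAN genes reassigned to EC at the curated tier.
#' @return a `stage_ledger` object with derived survivor and final counts.
#' @export
stage_ledger <- function(total_input, eliminated_outgroup,
                         eliminated_nonlineage, provisional_csg,
                         provisional_orphan, curated_eliminated_csg = 0L,
                         curated_eliminated_orphan = 0L) {
  l <- list(total_input = total_input,
            eliminated_outgroup = eliminated_outgroup,
            eliminated_nonlineage = eliminated_nonlineage,
            provisional_csg = provisional_csg,
            provisional_orphan = provisional_orphan,
            curated_eliminated_csg = curated_eliminated_csg,
            curated_eliminated_orphan = curated_eliminated_orphan)
  bad <- vapply(l, function(x) !is.numeric(x) || length(x) != 1L || x < 0,
                logical(1L))
  if (any(bad)) stop("ledger counts must be non-negative scalars")
  l$survivors_after_outgroup <- total_input - eliminated_outgroup
  l$survivors_after_nonlineage <- l$survivors_after_outgroup -
    eliminated_nonlineage
  l$final_csg <- provisional_csg - curated_eliminated_csg
  l$final_orphan <- provisional_orphan - curated_eliminated_orphan
  l$curated_reassigned <- curated_eliminated_csg + curated_eliminated_orphan
  l$final_ec <- eliminated_outgroup + eliminated_nonlineage +
    l$curated_reassigned
  l$total_lsg <- l$final_csg + l$final_orphan
  structure(l, class = "stage_ledger")
}

#' @export
print.stage_ledger <- function(x, ...) {
  cat("<stage_ledger>\n")
  cat(sprintf("  input genes          %d\n", x$total_input))
  cat(sprintf("  - outgroup genomes   %d eliminated -> %d remain\n",
              x$eliminated_outgroup, x$survivors_after_outgroup))
  cat(sprintf("  - non-lineage PUTs   %d eliminated -> %d remain\n",
              x$eliminated_nonlineage, x$survivors_after_nonlineage))
  cat(sprintf("  - lineage PUTs       %d provisional CSG / %d provisional orphan\n",
              x$provisional_csg, x$provisional_orphan))
  cat(sprintf("  - curated screen     %d reassigned EC (%d CSG + %d orphan)\n",
              x$curated_reassigned, x$curated_eliminated_csg,
              x$curated_eliminated_orphan))
  cat(sprintf("  final: %d EC, %d CSG, %d orphan (%d LSGs)\n",
              x$final_ec, x$final_csg, x$final_orphan, x$total_lsg))
  invisible(x)
}

#' Recompute and verify a stage ledger's derived counts
#'
#' Recomputes every survivor count and final category total from the
#' elimination counts and checks the partition identities; any mismatch
#' with the stored values is an error naming the offending stage.
#'
#' @param ledger a [stage_ledger].
#' @return (invisibly) a named list of the derived counts:
#'   `survivors_after_outgroup`, `survivors_after_nonlineage`,
#'   `provisional_csg`, `provisional_orphan`, `final_ec`, `final_csg`,
#'   `final_orphan`, `curated_reassigned`, `total_lsg`.
#' @export
reconcile_ledger <- function(ledger) {
  if (!inherits(ledger, "stage_ledger")) stop("not a stage_ledger")
  d <- list()
  d$survivors_after_outgroup <- ledger$total_input - ledger$eliminated_outgroup
  d$survivors_after_nonlineage <- d$survivors_after_outgroup -
    ledger$eliminated_nonlineage
  d$provisional_csg <- ledger$provisional_csg
  d$provisional_orphan <- ledger$provisional_orphan
  d$final_csg <- ledger$provisional_csg - ledger$curated_eliminated_csg
  d$final_orphan <- ledger$provisional_orphan -
    ledger$curated_eliminated_orphan
  d$curated_reassigned <- ledger$curated_eliminated_csg +
    ledger$curated_eliminated_orphan
  d$final_ec <- ledger$eliminated_outgroup + ledger$eliminated_nonlineage +
    d$curated_reassigned
  d$total_lsg <- d$final_csg + d$final_orphan
  checks <- c(
    "lineage stage: provisional CSG + provisional orphan must equal survivors" =
      ledger$provisional_csg + ledger$provisional_orphan ==
        d$survivors_after_nonlineage,
    "curated stage: cannot eliminate more CSGs than provisional CSGs" =
      ledger$curated_eliminated_csg <= ledger$provisional_csg,
    "curated stage: cannot eliminate more orphans than provisional orphans" =
      ledger$curated_eliminated_orphan <= ledger$provisional_orphan,
    "outgroup stage: survivors must be non-negative" =
      d$survivors_after_outgroup >= 0,
    "non-lineage stage: survivors must be non-negative" =
      d$survivors_after_nonlineage >= 0,
    "partition: EC + CSG + orphan must equal total input" =
      d$final_ec + d$final_csg + d$final_orphan == ledger$total_input)
  stored <- c(
    "survivors_after_outgroup", "survivors_after_nonlineage",
    "final_csg", "final_orphan", "curated_reassigned", "final_ec",
    "total_lsg")
  for (s in stored) {
    if (!is.null(ledger[[s]]) && ledger[[s]] != d[[s]])
      stop("ledger inconsistency at '", s, "': stored ", ledger[[s]],
           ", derived ", d[[s]])
  }
  if (!all(checks))
    stop("ledger inconsistency: ",
         paste(names(checks)[!checks], collapse = "; "))
  invisible(d)
}
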