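# The taxonomy adjudication cascade: confidence filtering, banned-keyword
# removal, genus-ambiguity detection, criterion-ranked tie-breaking, top-hit
# assignment and second-database fallback.

.assignStatuses <- c("assigned_top_hit", "assigned_tiebreak",
                     "unassigned_no_hit", "unassigned_all_filtered",
                     "removed_banned", "dubious")

.rankCols <- c("kingdom", "phylum", "class", "order", "family")

#' Confidence-filter homology hits
#'
#' A hit survives iff alignment length, identity, query coverage and gap
#' count all meet the thresholds and no banned keyword appears
#' (case-insensitive, whole word) in its subject title. Each removed hit is
#' labelled with the first violated rule, in the order: alignment length,
#' identity, coverage, gaps, banned keyword.
#'
#' @param hits data.frame of hits (12-column layout).
#' @param thresholds a [filterThresholds()].
#' @return list with `surviving` (hits data.frame) and `removals` (the
#'   removed hits plus a `reason` column).
#' @export
filterHits <- function(hits, thresholds = filterThresholds()) {
  if (!nrow(hits))
    return(list(surviving = hits,
                removals = cbind(hits, data.frame(reason = character(0)))))
  banned <- thresholds@bannedTitleKeywords
  bannedRe <- paste0("\\b(", paste(banned, collapse = "|"), ")\\b")
  hasBanned <- grepl(bannedRe, hits$stitle, ignore.case = TRUE)
  reason <- rep(NA_character_, nrow(hits))
  reason[is.na(reason) & hits$length < thresholds@minAlignmentLength] <-
    "alignment_length"
  reason[is.na(reason) & hits$pident < thresholds@minPident] <- "identity"
  reason[is.na(reason) & hits$qcovs < thresholds@requiredQcovs] <- "coverage"
  reason[is.na(reason) & hits$gaps > thresholds@maxGaps] <- "gaps"
  reason[is.na(reason) & hasBanned] <- "banned_keyword"
  keep <- is.na(reason)
  removals <- hits[!keep, , drop = FALSE]
  removals$reason <- reason[!keep]
  rownames(removals) <- NULL
  surv <- hits[keep, , drop = FALSE]
  rownames(surv) <- NULL
  list(surviving = surv, removals = removals)
}

#' Rank hits by the adjudication criteria
#'
#' Total order used to break dubious cases: percent identity descending,
#' then e-value ascending, then query coverage descending, then gaps
#' ascending, with subject id (lexicographic ascending) as the final
#' deterministic tie-break. The result is invariant to the input row order.
#'
#' @param hits data.frame of (already confidence-filtered) hits.
#' @return The same data.frame, rows reordered.
#' @export
rankHits <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  ord <- order(-hits$pident, hits$evalue, -hits$qcovs, hits$gaps,
               hits$sseqid, method = "radix")
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Does `win` strictly beat `other` on the first differing ranked criterion?
.strictlyBeats <- function(win, other) {
  if (win$pident != other$pident) return(win$pident > other$pident)
  if (win$evalue != other$evalue) return(win$evalue < other$evalue)
  if (win$qcovs != other$qcovs) return(win$qcovs > other$qcovs)
  if (win$gaps != other$gaps) return(win$gaps < other$gaps)
  FALSE
}

.emptyEvidence <- function() .emptyHitFrame()

#' Adjudicate the taxonomy of one OTU
#'
#' Runs the classification cascade on the hit lists of a single OTU:
#' \enumerate{
#'   \item use the primary-database hits; when there are none, fall back to
#'     the second database; when both are empty the OTU is
#'     `unassigned_no_hit`;
#'   \item at most 5 hits are considered (excess rows are ignored with a
#'     warning, matching a max-target-seqs 5 search);
#'   \item confidence-filter the chosen list ([filterHits()]); if nothing
#'     survives the OTU is `unassigned_all_filtered`, or `removed_banned`
#'     when every removal was for a banned title keyword;
#'   \item if all surviving hits share one genus, the OTU is
#'     `assigned_top_hit` with the lineage of the [rankHits()] winner;
#'   \item if the surviving hits span two or more genera, the ranked winner
#'     must strictly beat every other-genus hit on the first differing
#'     criterion to be `assigned_tiebreak`; otherwise the OTU is flagged
#'     `dubious` (manual-curation territory) with no lineage.
#' }
#'
#' @param otuId the query id.
#' @param primaryHits,fallbackHits data.frames of hits for this OTU (either
#'   may be empty or NULL); `fallbackHits` are interpreted in the fallback
#'   dialect (taxon parsed from `sseqid`) unless they carry a `dialect`
#'   attribute saying otherwise.
#' @param thresholds a [filterThresholds()].
#' @param lineage optional genus-to-higher-rank map ([lineageMap()]) used to
#'   fill kingdom..family.
#' @return One-row data.frame: `otu_id`, `kingdom`..`family`, `genus`,
#'   `species`, `status`, `source_db`, `best_sseqid`, `best_pident`,
#'   `best_evalue`, and the ordered surviving hits in the list column
#'   `evidence`.
#' @export
assignTaxonomy <- function(otuId, primaryHits = NULL, fallbackHits = NULL,
                           thresholds = filterThresholds(), lineage = NULL) {
  empty <- function(h) is.null(h) || nrow(h) == 0L
  if (!empty(primaryHits)) {
    hits <- primaryHits
    src <- "primary"
    dialect <- attr(primaryHits, "dialect")
    if (is.null(dialect)) dialect <- "primary"
  } else if (!empty(fallbackHits)) {
    hits <- fallbackHits
    src <- "fallback"
    dialect <- attr(fallbackHits, "dialect")
    if (is.null(dialect)) dialect <- "fallback"
  } else {
    return(.assignmentRow(otuId, status = "unassigned_no_hit",
                          source = NA_character_,
                          evidence = .emptyEvidence()))
  }
  if (nrow(hits) > 5L) {
    warning("OTU ", otuId, ": ", nrow(hits),
            " hits supplied, only the first 5 are considered")
    hits <- hits[1:5, , drop = FALSE]
  }
  f <- filterHits(hits, thresholds)
  if (!nrow(f$surviving)) {
    status <- if (nrow(f$removals) &&
                  all(f$removals$reason == "banned_keyword"))
      "removed_banned" else "unassigned_all_filtered"
    return(.assignmentRow(otuId, status = status, source = src,
                          evidence = .emptyEvidence()))
  }
  ranked <- rankHits(f$surviving)
  tax <- hitTaxon(ranked, dialect)
  genera <- unique(tax$genus)
  winner <- ranked[1, , drop = FALSE]
  winTax <- tax[1, , drop = FALSE]
  if (length(genera) == 1L) {
    return(.assignmentRow(otuId, status = "assigned_top_hit", source = src,
                          genus = winTax$genus, species = winTax$species,
                          best = winner, evidence = ranked,
                          lineage = lineage))
  }
  others <- which(tax$genus != winTax$genus)
  beaten <- vapply(others, function(j)
    .strictlyBeats(winner, ranked[j, , drop = FALSE]), logical(1))
  if (all(beaten)) {
    .assignmentRow(otuId, status = "assigned_tiebreak", source = src,
                   genus = winTax$genus, species = winTax$species,
                   best = winner, evidence = ranked, lineage = lineage)
  } else {
    .assignmentRow(otuId, status = "dubious", source = src,
                   evidence = ranked)
  }
}

.assignmentRow <- function(otuId, status, source, genus = NA_character_,
                           species = NA_character_, best = NULL,
                           evidence, lineage = NULL) {
  higher <- setNames(rep(NA_character_, length(.rankCols)), .rankCols)
  if (!is.null(lineage) && !is.na(genus)) {
    hit <- match(genus, lineage$genus)
    if (!is.na(hit))
      higher[.rankCols] <- unlist(lineage[hit, .rankCols])
  }
  out <- data.frame(otu_id = otuId, t(higher), genus = genus,
                    species = species, status = status,
                    source_db = source,
                    best_sseqid = if (is.null(best)) NA_character_ else best$sseqid,
                    best_pident = if (is.null(best)) NA_real_ else best$pident,
                    best_evalue = if (is.null(best)) NA_real_ else best$evalue,
                    stringsAsFactors = FALSE)
  out$evidence <- list(evidence)
  out
}

#' Adjudicate all OTUs of a survey
#'
#' Applies [assignTaxonomy()] to every OTU, pairing each id with its
#' primary- and fallback-database hits.
#'
#' @param otuIds character vector of OTU ids to adjudicate.
#' @param primaryMap,fallbackMap named lists of per-query hit data.frames,
#'   as returned by [parseHitTable()] (or built from [genHitTable()]).
#' @param thresholds a [filterThresholds()].
#' @param lineage optional [lineageMap()].
#' @return data.frame with one row per OTU (see [assignTaxonomy()]).
#' @export
adjudicateAll <- function(otuIds, primaryMap = list(), fallbackMap = list(),
                          thresholds = filterThresholds(), lineage = NULL) {
  if (!length(otuIds)) {
    skeleton <- .assignmentRow("x", status = "unassigned_no_hit",
                               source = NA_character_,
                               evidence = .emptyEvidence())
    return(skeleton[0, ])
  }
  rows <- lapply(otuIds, function(id)
    assignTaxonomy(id, primaryMap[[id]], fallbackMap[[id]], thresholds,
                   lineage))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize an assignment table
#'
#' @param assignments data.frame from [adjudicateAll()].
#' @return list with `status` (counts over all six statuses),
#'   `deepest_rank` (counts of OTUs by their deepest assigned rank, `none`
#'   for unassigned), `source_db` counts, and the cumulative `n_genus` /
#'   `n_species` (every species-level OTU also counts at genus level, so
#'   `n_species <= n_genus`).
#' @export
summarizeAssignments <- function(assignments) {
  status <- table(factor(assignments$status, levels = .assignStatuses))
  deepest <- ifelse(!is.na(assignments$species), "species",
                    ifelse(!is.na(assignments$genus), "genus", "none"))
  list(status = as.list(status),
       deepest_rank = as.list(table(factor(deepest,
                                           levels = c("species", "genus",
                                                      "none")))),
       source_db = as.list(table(factor(assignments$source_db,
                                        levels = c("primary", "fallback")))),
       n_genus = sum(!is.na(assignments$genus)),
       n_species = sum(!is.na(assignments$species)),
       n_otus = nrow(assignments))
}

#' Write assignments to CSV (evidence column dropped)
#'
#' @param assignments data.frame from [adjudicateAll()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssignmentsCsv <- function(assignments, path) {
  utils::write.csv(assignments[, setdiff(names(assignments), "evidence")],
                   path, row.names = FALSE)
  invisible(path)
}
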