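# Screening of species-level COI assignments against local NIS checklists.

.normSpecies <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Screen assignments against non-indigenous-species checklists
#'
#' Emits one record per OTU that (i) carries an `assigned_*` status with a
#' species binomial, (ii) whose species exactly matches a checklist entry
#' after case/whitespace normalization (optionally through a synonym map),
#' and (iii) whose sequence passes translation validation
#' ([orfValidate()]) — pseudogene-like sequences with internal stop codons
#' are excluded. Source tags of all checklists containing the species are
#' aggregated.
#'
#' @param assignments data.frame from [adjudicateAll()].
#' @param checklist data.frame with columns `species`, `source_tag` (one or
#'   several checklists concatenated).
#' @param sequences named character vector or `DNAStringSet` of OTU
#'   sequences (names matching `otu_id`).
#' @param codes genetic-code tables for validation, default
#'   `c(1, 2, 4, 5, 9)`.
#' @param synonyms optional data.frame with columns `from`, `to` mapping
#'   assignment binomials onto checklist binomials.
#' @return data.frame of reported NIS: `otu_id`, `species`, `source_tags`
#'   (comma-separated), `frame`, `genetic_code_id`, `translation_ok`. The
#'   full candidate table (including translation failures and OTUs with
#'   missing sequences, which are excluded from the report) is attached as
#'   attribute `"candidates"`. The output depends only on the inputs as
#'   sets; input order does not matter.
#' @examples
#' # see the package vignette for an end-to-end planted example
#' @export
matchChecklist <- function(assignments, checklist, sequences,
                           codes = c(1, 2, 4, 5, 9), synonyms = NULL) {
  sequences <- setNames(toupper(as.character(sequences)), names(sequences))
  emptyOut <- data.frame(otu_id = character(0), species = character(0),
                         source_tags = character(0), frame = integer(0),
                         genetic_code_id = numeric(0),
                         translation_ok = logical(0),
                         stringsAsFactors = FALSE)
  if (!nrow(checklist) || !nrow(assignments)) {
    attr(emptyOut, "candidates") <- emptyOut
    return(emptyOut)
  }
  clSpecies <- .normSpecies(checklist$species)
  sp <- assignments$species
  if (!is.null(synonyms) && nrow(synonyms)) {
    idx <- match(.normSpecies(sp), .normSpecies(synonyms$from))
    sp[!is.na(idx)] <- synonyms$to[idx[!is.na(idx)]]
  }
  spNorm <- .normSpecies(sp)
  isCand <- grepl("^assigned_", assignments$status) & !is.na(sp) &
    spNorm %in% clSpecies
  cand <- assignments[isCand, c("otu_id", "species"), drop = FALSE]
  cand$species <- sp[isCand]
  if (!nrow(cand)) {
    attr(emptyOut, "candidates") <- emptyOut
    return(emptyOut)
  }
  cand <- cand[order(cand$otu_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    id <- cand$otu_id[i]
    spI <- cand$species[i]
    tags <- sort(unique(checklist$source_tag[clSpecies == .normSpecies(spI)]))
    base <- data.frame(otu_id = id, species = spI,
                       source_tags = paste(tags, collapse = ","),
                       frame = NA_integer_, genetic_code_id = NA_real_,
                       translation_ok = FALSE, stringsAsFactors = FALSE)
    sq <- sequences[id]
    if (is.na(sq)) {
      warning("no sequence for NIS candidate ", id, "; excluded")
      return(base)
    }
    v <- orfValidate(sq, codes)
    if (v$pass) {
      base$frame <- v$best$frame
      base$genetic_code_id <- v$best$genetic_code_id
      base$translation_ok <- TRUE
    }
    base
  })
  cands <- do.call(rbind, rows)
  rownames(cands) <- NULL
  out <- cands[cands$translation_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "candidates") <- cands
  out
}

#' Read a checklist CSV
#'
#' @param path CSV with columns `species`, `source_tag`.
#' @return data.frame.
#' @export
readChecklistCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "source_tag") %in% names(df)))
    stop("checklist must have columns 'species' and 'source_tag'")
  df
}

#' Write a checklist CSV
#'
#' @param checklist data.frame with columns `species`, `source_tag`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeChecklistCsv <- function(checklist, path) {
  utils::write.csv(checklist, path, row.names = FALSE)
  invisible(path)
}
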