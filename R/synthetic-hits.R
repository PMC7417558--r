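# Synthetic homology-hit tables with planted adjudication cases.

.hitCases <- c("clean", "no_hit", "low_confidence", "ambiguous",
               "banned_keyword", "nis")

.newHitRow <- function(qseqid, genus, epithet, len, pident, gaps, qcovs,
                       staxid, banned = NULL) {
  sseqid <- sprintf("ACC%06d.1", sample(1e6, 1) - 1L)
  bitscore <- round(1.8 * len * pident / 100, 1)
  evalue <- signif(1e3 * 2^(-pmin(bitscore, 980) / 3), 4)
  stitle <- if (is.null(banned))
    paste(genus, epithet, "voucher", sseqid,
          "cytochrome c oxidase subunit I gene")
  else paste(banned, "organism clone", sseqid, "marker gene sequence")
  sstart <- sample(1:50, 1)
  data.frame(qseqid = qseqid, sseqid = sseqid, length = len,
             pident = pident, gaps = gaps, sstart = sstart,
             send = sstart + len - 1L, qcovs = qcovs, evalue = evalue,
             bitscore = bitscore, staxids = as.character(staxid),
             stitle = stitle, stringsAsFactors = FALSE)
}

.distinctPidents <- function(k, lo = 92, hi = 99.4) {
  sort(round(runif(k, lo, hi) + seq_len(k) * 1e-3, 3), decreasing = TRUE)
}

#' Generate a homology-hit table with planted adjudication cases
#'
#' Emulates 12-column tabular BLAST output (`-max_target_seqs 5`) for a set
#' of query OTUs, planting one of six ground-truth cases per query so every
#' branch of the adjudication cascade can be exercised and scored:
#' \describe{
#'   \item{clean}{2--5 hits, all passing the confidence filters, one genus;
#'     adjudicates to `assigned_top_hit`.}
#'   \item{no_hit}{no rows; adjudicates to `unassigned_no_hit`.}
#'   \item{low_confidence}{every hit violates at least one confidence
#'     threshold; adjudicates to `unassigned_all_filtered`.}
#'   \item{ambiguous}{passing hits span two or more genera with a strict
#'     winner under the criterion ranking; adjudicates to
#'     `assigned_tiebreak`.}
#'   \item{banned_keyword}{all hit titles carry one of the banned words;
#'     adjudicates to `removed_banned`.}
#'   \item{nis}{a clean case whose species is drawn from `checklist`.}
#' }
#' E-values are a decreasing function of bitscore so the rank correlations
#' the tie-break assumes are preserved.
#'
#' @param queries character vector of query (OTU) ids.
#' @param taxa data.frame from [genReferenceTaxa()] supplying genera/species.
#' @param caseFractions named numeric over the six cases, summing to 1
#'   (tolerance 1e-9).
#' @param checklist data.frame from [genChecklist()]; required when the `nis`
#'   fraction is positive, and must share species with `taxa`.
#' @param seed integer seed.
#' @return list with `hits` (12-column data.frame in the tabular hit column
#'   order) and `truth` (data.frame `query_id`, `planted_case`, `true_genus`,
#'   `true_species`).
#' @examples
#' taxa <- genReferenceTaxa(12, markers = "COI", seed = 1)
#' tab <- genHitTable(paste0("OTU_", 1:6), taxa,
#'                    caseFractions = c(clean = 0.5, no_hit = 0.5),
#'                    seed = 3)
#' table(tab$truth$planted_case)
#' @export
genHitTable <- function(queries, taxa,
                        caseFractions = c(clean = 1),
                        checklist = NULL, seed) {
  if (!all(names(caseFractions) %in% .hitCases))
    stop("unknown case names: ",
         paste(setdiff(names(caseFractions), .hitCases), collapse = ", "))
  fr <- setNames(numeric(length(.hitCases)), .hitCases)
  fr[names(caseFractions)] <- caseFractions
  counts <- apportion(length(queries), fr)
  names(counts) <- .hitCases
  if (counts["nis"] > 0) {
    if (is.null(checklist) || !nrow(checklist))
      stop("a non-empty 'checklist' is required to plant nis cases")
    nisPool <- intersect(unique(checklist$species), unique(taxa$species))
    if (!length(nisPool))
      stop("'checklist' shares no species with 'taxa'")
  }
  # species never on any checklist are used for non-NIS planted cases
  offList <- if (is.null(checklist)) unique(taxa$species)
             else setdiff(unique(taxa$species), checklist$species)
  if (counts["clean"] + counts["ambiguous"] > 0 && !length(offList))
    stop("'taxa' has no species off the checklist to plant clean cases")
  withSeed(seed, {
    caseOf <- sample(rep(.hitCases, counts))
    rows <- list()
    truth <- data.frame(query_id = queries, planted_case = caseOf,
                        true_genus = NA_character_,
                        true_species = NA_character_,
                        stringsAsFactors = FALSE)
    taxaU <- unique(taxa[, c("genus", "species")])
    taxaU$epithet <- sub("^\\S+\\s+", "", taxaU$species)
    pickSpecies <- function(pool) {
      sp <- if (length(pool) == 1L) pool else sample(pool, 1)
      taxaU[match(sp, taxaU$species), ]
    }
    for (i in seq_along(queries)) {
      q <- queries[i]
      cs <- caseOf[i]
      if (cs == "no_hit") next
      if (cs %in% c("clean", "nis")) {
        rec <- pickSpecies(if (cs == "nis")
          intersect(unique(checklist$species), unique(taxa$species))
          else offList)
        k <- sample(2:5, 1)
        pid <- .distinctPidents(k)
        hs <- lapply(seq_len(k), function(j)
          .newHitRow(q, rec$genus, rec$epithet, sample(200:400, 1), pid[j],
                     0L, 100L, sample(1e5, 1)))
        truth$true_genus[i] <- rec$genus
        truth$true_species[i] <- rec$species
      } else if (cs == "low_confidence") {
        k <- sample(1:5, 1)
        hs <- lapply(seq_len(k), function(j) {
          rec <- pickSpecies(unique(taxa$species))
          len <- sample(200:400, 1); pid <- round(runif(1, 92, 99), 2)
          gaps <- 0L; qc <- 100L
          for (v in sample(c("len", "pid", "qc", "gap"),
                           sample(1:2, 1))) {
            if (v == "len") len <- sample(50:199, 1)
            if (v == "pid") pid <- round(runif(1, 60, 89.8), 2)
            if (v == "qc") qc <- sample(40:99, 1)
            if (v == "gap") gaps <- sample(1:5, 1)
          }
          .newHitRow(q, rec$genus, rec$epithet, len, pid, gaps, qc,
                     sample(1e5, 1))
        })
      } else if (cs == "ambiguous") {
        pool <- taxaU[taxaU$species %in% offList, , drop = FALSE]
        gpool <- unique(pool$genus)
        if (length(gpool) < 2L)
          stop("ambiguous cases need at least two off-checklist genera")
        gs <- sample(gpool, 2)
        win <- pool[match(gs[1], pool$genus), ]
        k <- sample(3:5, 1)
        pid <- .distinctPidents(k, lo = 92, hi = 98.5)
        pid[1] <- pid[1] + 0.6   # strict winner on the first criterion
        hs <- vector("list", k)
        hs[[1]] <- .newHitRow(q, win$genus, win$epithet,
                              sample(200:400, 1), pid[1], 0L, 100L,
                              sample(1e5, 1))
        for (j in 2:k) {
          g <- if (j == 2) gs[2] else sample(gs, 1)
          rec <- pool[match(g, pool$genus), ]
          hs[[j]] <- .newHitRow(q, rec$genus, rec$epithet,
                                sample(200:400, 1), pid[j], 0L, 100L,
                                sample(1e5, 1))
        }
        truth$true_genus[i] <- win$genus
        truth$true_species[i] <- win$species
      } else { # banned_keyword
        k <- sample(1:5, 1)
        banned <- c("Uncultured", "Unidentified", "Unclassified",
                    "Environmental")
        hs <- lapply(seq_len(k), function(j)
          .newHitRow(q, NA, NA, sample(200:400, 1),
                     .distinctPidents(1), 0L, 100L, sample(1e5, 1),
                     banned = sample(banned, 1)))
      }
      hs <- do.call(rbind, hs)
      rows[[q]] <- hs[sample(nrow(hs)), , drop = FALSE]
    }
    hits <- if (length(rows)) do.call(rbind, rows)
      else .emptyHitFrame()
    rownames(hits) <- NULL
    list(hits = hits, truth = truth)
  })
}

.hitColumns <- c("qseqid", "sseqid", "length", "pident", "gaps", "sstart",
                 "send", "qcovs", "evalue", "bitscore", "staxids", "stitle")

.emptyHitFrame <- function() {
  out <- data.frame(qseqid = character(0), sseqid = character(0),
                    length = integer(0), pident = numeric(0),
                    gaps = integer(0), sstart = integer(0), send = integer(0),
                    qcovs = numeric(0), evalue = numeric(0),
                    bitscore = numeric(0), staxids = character(0),
                    stitle = character(0), stringsAsFactors = FALSE)
  out
}
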