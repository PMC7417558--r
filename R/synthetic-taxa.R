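# Synthetic reference taxa and NIS checklists.
#
# All names live in a reserved pseudo-Latin namespace (genera prefixed
# "Ficto") so generated binomials can never collide with entries of real
# invasive-species checklists.

.markers <- c("16S", "18S", "23S", "COI")

.genusSyllables <- c("ceras", "mya", "pora", "thrix", "nema", "spira",
                     "zoon", "phyra", "bdella", "chaeta", "cystis", "soma")
.epithets <- c("simulans", "fictus", "portuensis", "atlanticus", "navalis",
               "adhaerens", "litoralis", "pictus", "ferrugineus", "vernalis",
               "maritimus", "obscurus", "tenuis", "gracilis", "robustus",
               "variegatus", "profundus", "borealis", "australis", "medius")
.kingdoms <- c("Animalia", "Plantae", "Chromista", "Fungi")
.phylaPool <- c("Fictozoa", "Fictophyta", "Fictomycota", "Fictista",
                "Fictopoda", "Fictophora")

# Codons that are never a stop under NCBI genetic codes 1, 2, 4, 5 and 9:
# excludes TAA, TAG, TGA (stops in 1/4/9 or reassigned) and AGA/AGG (stops
# in the vertebrate mitochondrial code 2). COI-like sequences are built from
# these so clean barcodes translate without internal stops.
.codingCodons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA", "AGA", "AGG"))
})

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

randomCoding <- function(nCodons) {
  paste(sample(.codingCodons, nCodons, replace = TRUE), collapse = "")
}

#' Generate synthetic reference taxa
#'
#' Builds a reference table emulating database entries for the four survey
#' markers (16S, 18S, 23S, COI): each taxon gets a full pseudo-Latin lineage
#' (kingdom to genus plus a species binomial) and one sequence per requested
#' marker. COI sequences are assembled from codons that are never stops under
#' NCBI genetic codes 1, 2, 4, 5 and 9, so genuine barcodes pass translation
#' validation; rRNA sequences are unconstrained random DNA.
#'
#' @param nTaxa number of taxa (>= 1).
#' @param markers subset of `c("16S","18S","23S","COI")`.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with one row per (taxon, marker): `taxon_id`, lineage
#'   columns `kingdom`..`genus`, `species`, `marker`, `sequence`.
#' @examples
#' taxa <- genReferenceTaxa(5, markers = "COI", seed = 1)
#' taxa$species
#' @export
genReferenceTaxa <- function(nTaxa, markers = .markers, seed) {
  if (length(nTaxa) != 1L || is.na(nTaxa) || nTaxa < 1)
    stop("'nTaxa' must be >= 1")
  markers <- match.arg(markers, .markers, several.ok = TRUE)
  withSeed(seed, {
    nGenera <- if (nTaxa >= 2) max(2L, ceiling(nTaxa / 3)) else 1L
    genera <- unique(paste0("Ficto",
                            sample(.genusSyllables, nGenera * 3, replace = TRUE),
                            rep(c("", "n", "r"), length.out = nGenera * 3)))
    while (length(genera) < nGenera)
      genera <- unique(c(genera, paste0("Ficto",
                                        sample(.genusSyllables, 1),
                                        sample(letters, 1))))
    genera <- genera[seq_len(nGenera)]
    genusOf <- genera[((seq_len(nTaxa) - 1L) %% nGenera) + 1L]
    epi <- .epithets[((seq_len(nTaxa) - 1L) %% length(.epithets)) + 1L]
    # distinct binomials even when genus repeats within an epithet cycle
    dup <- duplicated(paste(genusOf, epi))
    epi[dup] <- paste0(epi[dup], letters[((seq_len(sum(dup)) - 1L) %% 26L) + 1L])
    gIdx <- match(genusOf, genera)
    lineage <- data.frame(
      kingdom = .kingdoms[(gIdx %% length(.kingdoms)) + 1L],
      phylum = .phylaPool[(gIdx %% length(.phylaPool)) + 1L],
      class = paste0(.phylaPool[(gIdx %% length(.phylaPool)) + 1L], "ceae"),
      order = paste0(genusOf, "iformes"),
      family = paste0(genusOf, "idae"),
      genus = genusOf,
      species = paste(genusOf, epi),
      stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(markers, function(mk) {
      seqs <- vapply(seq_len(nTaxa), function(i) {
        if (mk == "COI") randomCoding(sample(110:160, 1))
        else randomDna(sample(320:520, 1))
      }, character(1))
      cbind(data.frame(taxon_id = sprintf("TAX%04d_%s", seq_len(nTaxa), mk),
                       stringsAsFactors = FALSE),
            lineage,
            data.frame(marker = mk, sequence = seqs, stringsAsFactors = FALSE))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic NIS checklist
#'
#' Draws a reproducible subset of the species binomials in a reference table
#' and tags each with one (sometimes two) invasive-species database stand-in
#' labels, emulating local copies of GISD / CABI / AquaNIS / NEMESIS lookups.
#'
#' @param taxa data.frame from [genReferenceTaxa()].
#' @param nisFraction fraction of distinct species to list, in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with columns `species`, `source_tag`; zero rows when
#'   `nisFraction = 0`.
#' @examples
#' taxa <- genReferenceTaxa(10, markers = "COI", seed = 1)
#' genChecklist(taxa, nisFraction = 0.3, seed = 2)
#' @export
genChecklist <- function(taxa, nisFraction, seed) {
  stopifnotFraction(nisFraction, "nisFraction")
  species <- sort(unique(taxa$species))
  k <- round(nisFraction * length(species))
  withSeed(seed, {
    chosen <- if (k) sort(sample(species, k)) else character(0)
    tags <- c("GISD", "CABI", "AquaNIS", "NEMESIS")
    rows <- lapply(chosen, function(sp) {
      t1 <- sample(tags, 1)
      if (runif(1) < 0.3) {
        t2 <- sample(setdiff(tags, t1), 1)
        data.frame(species = sp, source_tag = c(t1, t2),
                   stringsAsFactors = FALSE)
      } else data.frame(species = sp, source_tag = t1,
                        stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows)
    else data.frame(species = character(0), source_tag = character(0),
                    stringsAsFactors = FALSE)
  })
}

#' Genus-to-higher-rank lineage map of a reference table
#'
#' @param taxa data.frame from [genReferenceTaxa()].
#' @return data.frame with one row per genus and columns
#'   `genus`, `kingdom`, `phylum`, `class`, `order`, `family`.
#' @export
lineageMap <- function(taxa) {
  u <- unique(taxa[, c("genus", "kingdom", "phylum", "class", "order", "family")])
  rownames(u) <- NULL
  u
}
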