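#' Survey sampling design
#'
#' Bookkeeping for the one-year panel survey: how many panels are sampled
#' each month, how many grids are scraped per panel, and how scrapes are
#' pooled into DNA extracts. The defaults are the survey's design: 12
#' months, 2 painted panels and 4 bare panels sampled per month, 3 grids per
#' panel per month (6 painted + 12 bare grids monthly), 2 extra whole-panel
#' scrapes in the final month, and 2 DNA pools per month (one painted, one
#' bare).
#'
#' @param months number of sampling months.
#' @param paintedPanels painted panels sampled each month.
#' @param barePanelsSampledPerMonth bare panels sampled each month.
#' @param gridsPerPanelPerMonth grids scraped per panel per month.
#' @param extraWholePanelScrapes additional whole-panel scrapes (end of
#'   survey).
#' @param poolsPerMonth DNA extract pools formed per month.
#' @return A validated `SamplingDesign` list.
#' @examples
#' samplingDesign()
#' @export
samplingDesign <- function(months = 12, paintedPanels = 2,
                           barePanelsSampledPerMonth = 4,
                           gridsPerPanelPerMonth = 3,
                           extraWholePanelScrapes = 2,
                           poolsPerMonth = 2) {
  d <- list(months = months, paintedPanels = paintedPanels,
            barePanelsSampledPerMonth = barePanelsSampledPerMonth,
            gridsPerPanelPerMonth = gridsPerPanelPerMonth,
            extraWholePanelScrapes = extraWholePanelScrapes,
            poolsPerMonth = poolsPerMonth)
  if (any(vapply(d, function(x) length(x) != 1L || is.na(x) || x < 0,
                 logical(1))))
    stop("all design counts must be single non-negative numbers")
  structure(lapply(d, as.integer), class = "SamplingDesign")
}

#' Build the sampling manifest of a survey design
#'
#' Expands a [samplingDesign()] into totals and per-month rows:
#' `grids_total = months * (paintedPanels + barePanelsSampledPerMonth) *
#' gridsPerPanelPerMonth`, `scraped_samples_total = grids_total +
#' extraWholePanelScrapes`, and `dna_pools_total = months * poolsPerMonth +
#' extraWholePanelScrapes`. Under the default design this reproduces the
#' survey's 216 scraped grids, 218 scraped samples and 26 DNA extract pools.
#'
#' @param design a `SamplingDesign`, default [samplingDesign()].
#' @return list with `grids_total`, `scraped_samples_total`,
#'   `dna_pools_total` and a `per_month` data.frame.
#' @examples
#' buildSamplingManifest()$grids_total  # 216
#' @export
buildSamplingManifest <- function(design = samplingDesign()) {
  if (!inherits(design, "SamplingDesign"))
    stop("'design' must come from samplingDesign()")
  panels <- design$paintedPanels + design$barePanelsSampledPerMonth
  gridsPerMonth <- panels * design$gridsPerPanelPerMonth
  gridsTotal <- design$months * gridsPerMonth
  perMonth <- data.frame(
    month = seq_len(design$months),
    painted_grids = design$paintedPanels * design$gridsPerPanelPerMonth,
    bare_grids = design$barePanelsSampledPerMonth * design$gridsPerPanelPerMonth,
    grids = gridsPerMonth,
    pools = design$poolsPerMonth)
  if (design$months > 0) {
    perMonth$extra_whole_panel_scrapes <- 0L
    perMonth$extra_whole_panel_scrapes[design$months] <-
      design$extraWholePanelScrapes
  }
  list(grids_total = gridsTotal,
       scraped_samples_total = gridsTotal + design$extraWholePanelScrapes,
       dna_pools_total = design$months * design$poolsPerMonth +
         design$extraWholePanelScrapes,
       per_month = perMonth)
}

#' Write a sampling manifest to JSON
#'
#' @param manifest list from [buildSamplingManifest()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeManifestJson <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
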