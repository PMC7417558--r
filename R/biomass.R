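#' Effective panel area from its geometry
#'
#' Area of a square settlement panel minus the fixture patches where
#' carabiners attach. The survey's 20 cm x 20 cm panels with four 16 cm^2
#' attachment patches give the default effective area of 336 cm^2.
#'
#' @param sideCm panel side length in cm (default 20).
#' @param nAttachments number of fixture patches (default 4).
#' @param attachmentAreaCm2 area of each patch in cm^2 (default 16).
#' @return Effective area in cm^2.
#' @examples
#' effectiveArea()  # 336
#' @export
effectiveArea <- function(sideCm = 20, nAttachments = 4,
                          attachmentAreaCm2 = 16) {
  area <- sideCm^2 - nAttachments * attachmentAreaCm2
  if (area <= 0) stop("attachments cover the whole panel")
  area
}

#' Biomass per effective panel area
#'
#' Wet panel weight corrected by the clean (non-fouled) panel weight and
#' divided by the effective panel area. Negative differences (a fouled
#' panel lighter than its clean weight) are clipped to zero with a warning.
#'
#' @param wetWeight wet panel weight in g.
#' @param cleanPanelWeight non-fouled panel weight in g.
#' @param effectiveAreaCm2 effective area in cm^2 (default
#'   [effectiveArea()], 336).
#' @return list with `wet_weight`, `clean_panel_weight`, `effective_area`
#'   and `biomass_per_area` (g/cm^2).
#' @examples
#' biomassPerArea(403.2, 336)$biomass_per_area  # 0.2
#' @export
biomassPerArea <- function(wetWeight, cleanPanelWeight,
                           effectiveAreaCm2 = effectiveArea()) {
  if (effectiveAreaCm2 <= 0) stop("'effectiveAreaCm2' must be > 0")
  if (wetWeight < 0 || cleanPanelWeight < 0)
    stop("weights must be >= 0")
  diffG <- wetWeight - cleanPanelWeight
  if (diffG < 0) {
    warning("wet weight below clean weight; biomass clipped to 0")
    diffG <- 0
  }
  list(wet_weight = wetWeight, clean_panel_weight = cleanPanelWeight,
       effective_area = effectiveAreaCm2,
       biomass_per_area = diffG / effectiveAreaCm2)
}
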