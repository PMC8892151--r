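#' Non-fibrous carbohydrates by difference
#'
#' `NFC = 1000 - (NDFom + CP + EE + ash)` on the g/kg DM scale. Vectorized
#' over feeds.
#'
#' @param cp Crude protein (g/kg DM).
#' @param ee Ether extract (g/kg DM).
#' @param ndfom Ash-corrected neutral detergent fiber (g/kg DM).
#' @param ash Ash (g/kg DM).
#' @return NFC in g/kg DM.
#' @examples
#' nfc(cp = 83, ee = 35, ndfom = 129, ash = 26)  # corn grain: 727
#' @export
nfc <- function(cp, ee, ndfom, ash) {
  vals <- cbind(cp, ee, ndfom, ash)
  if (any(vals < 0) || any(vals > 1000))
    stop("analytes must lie in [0, 1000] g/kg DM")
  s <- cp + ee + ndfom + ash
  if (any(s > 1000))
    stop("analytes sum to more than 1000 g/kg DM: impossible composition")
  1000 - s
}

#' Chemical composition of the six experimental feeds
#'
#' Proximate analytes (g/kg DM) of the feeds used in the validation
#' experiment — alfalfa hay, wheat straw, corn silage, barley grain, corn
#' grain and a total mixed ration — with the tabulated NFC for
#' cross-checking against [nfc()].
#'
#' @return data.frame `feed_id`, `dm`, `cp`, `ee`, `ndfom`, `adfom`, `ash`,
#'   `nfc`.
#' @export
load_feed_composition <- function() {
  path <- system.file("extdata", "feed_composition.csv", package = "gasferm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Validate a feed composition table
#'
#' Checks analyte ranges, `adfom <= ndfom`, and that the non-NFC analytes
#' sum to at most 1000 g/kg DM.
#'
#' @param comp data.frame with columns `cp`, `ee`, `ndfom`, `adfom`, `ash`.
#' @return Invisibly `TRUE`; stops with a message otherwise.
#' @export
validate_feed_composition <- function(comp) {
  analytes <- c("cp", "ee", "ndfom", "adfom", "ash")
  stopifnot(all(analytes %in% names(comp)))
  for (a in analytes)
    if (any(comp[[a]] < 0 | comp[[a]] > 1000))
      stop("analyte ", a, " outside [0, 1000] g/kg DM")
  if (any(comp$adfom > comp$ndfom))
    stop("ADFom exceeds NDFom for some feed")
  if (any(comp$cp + comp$ee + comp$ndfom + comp$ash > 1000))
    stop("analytes sum to more than 1000 g/kg DM")
  invisible(TRUE)
}

#' Published technique mean gas production (reference benchmark)
#'
#' Mean cumulative GP (mL per g incubated DM) at 6, 12, 24 and 48 h for the
#' automated and manual techniques, as tabulated in the validation study of
#' the automated equipment. Used to benchmark the automated-vs-manual
#' percent difference (e.g. +11.5 percent at 24 h).
#'
#' @return data.frame `technique`, `endpoint_h`, `gp_mL_per_g`.
#' @export
reference_technique_means <- function() {
  path <- system.file("extdata", "reference_gp_means.csv",
                      package = "gasferm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
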