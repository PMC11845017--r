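#' Indicator registry
#'
#' An indicator registry declares, for every measured trait, its units and
#' its direction with respect to the growth-promotion effect being scored:
#' \code{"positive"} means larger values indicate stronger promotion,
#' \code{"inverse"} means smaller values do (the membership evaluation then
#' uses the complementary F2 score). Of the standard tobacco pot-trial panel
#' only malondialdehyde (MDA), a lipid-peroxidation stress marker, is
#' inverse.
#'
#' @param name character vector of unique indicator names.
#' @param units character vector of measurement units, recycled if length 1.
#' @param direction \code{"positive"} or \code{"inverse"} per indicator,
#'   recycled if length 1.
#' @return A data frame of class \code{amf_registry} with columns
#'   \code{name}, \code{units}, \code{direction}.
#' @examples
#' indicator_registry(c("plant_height", "mda_content"),
#'                    units = c("cm", "umol/g"),
#'                    direction = c("positive", "inverse"))
#' @export
indicator_registry <- function(name, units = "", direction = "positive") {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicate indicator names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  units <- rep_len(as.character(units), length(name))
  direction <- rep_len(as.character(direction), length(name))
  bad <- !direction %in% c("positive", "inverse")
  if (any(bad))
    stop("direction must be 'positive' or 'inverse'; offending: ",
         paste(name[bad], collapse = ", "))
  out <- data.frame(name = name, units = units, direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("amf_registry", "data.frame")
  out
}

#' Default indicator registry for the tobacco pot-trial panel
#'
#' The 19 physiological indicators entering the membership evaluation
#' (growth, antioxidant enzymes, hormones, pigments, osmolytes, phenolics)
#' plus the four root-colonization quantities recorded alongside them.
#' MDA is the one inverse-direction indicator.
#'
#' @return An \code{amf_registry} data frame.
#' @export
default_indicators <- function() {
  indicator_registry(
    name = c("plant_height", "root_length", "leaf_area", "stem_diameter",
             "aboveground_biomass", "belowground_biomass", "total_biomass",
             "sod_activity", "pod_activity", "ppo_activity", "pal_activity",
             "iaa_content", "ctk_content", "chlorophyll_content",
             "soluble_sugar_content", "proline_content", "mda_content",
             "total_phenol_content", "flavonoids_content",
             "infection_rate", "infection_density", "arbuscular_abundance",
             "spore_density"),
    units = c("cm", "cm", "cm2", "cm", "g", "g", "g",
              "U/g", "U/g", "U/g", "U/g",
              "ng/g", "ng/g", "mg/g",
              "mg/g", "ug/g", "umol/g",
              "mg/g", "mg/g",
              "%", "%", "%", "spores per 25 g soil"),
    direction = c(rep("positive", 16), "inverse", "positive", "positive",
                  rep("positive", 4))
  )
}

#' Default treatment labels
#'
#' Seven groups of the screening design: uninoculated control (CK), five
#' single AMF inoculants (Ab, Ce, Sv, Fm, Ri) and a mixed inoculant (H).
#'
#' @return Character vector of treatment labels in design order.
#' @export
default_treatments <- function() c("CK", "Ab", "Ce", "Sv", "Fm", "Ri", "H")

#' The 19 indicators entering the membership evaluation, in panel order.
#' @return Character vector of indicator names.
#' @export
evaluation_indicators <- function() {
  setdiff(default_indicators()$name,
          c("infection_rate", "infection_density", "arbuscular_abundance",
            "spore_density"))
}

indicator_direction <- function(registry, indicator) {
  i <- match(indicator, registry$name)
  if (anyNA(i))
    stop("unknown indicator(s): ",
         paste(indicator[is.na(i)], collapse = ", "))
  registry$direction[i]
}

# round-half-up at d decimals; base round() uses round-half-even which does
# not reproduce published tables at ties
round_half_up <- function(x, d = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d
}
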