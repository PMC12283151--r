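#' Behavioral-context vocabulary
#'
#' The ten behavioral contexts a song can be annotated with, each defined by
#' an inclusion criterion (what qualifies a song for the context) and an
#' exclusion criterion (near-misses that must not be annotated with it).
#' The token order returned here is the canonical order used throughout the
#' package, e.g. for deterministic tie-breaking of modal votes.
#'
#' @return A data.frame with columns `context`, `inclusion`, `exclusion`,
#'   one row per context, in canonical order.
#' @export
#' @examples
#' context_vocabulary()$context
context_vocabulary <- function() {
  data.frame(
    context = c("dance", "healing", "love", "lullaby", "play",
                "procession", "mourning", "work", "story", "praise"),
    inclusion = c(
      "Sung with the goal of a person or persons dancing along to it.",
      "Sung in a healing ceremony with the goal of curing sickness.",
      "Sung to express love directly to another person or to describe currently felt love.",
      "Sung to an infant or child with the goal of soothing, calming, or putting to sleep.",
      "Sung to excite a child or infant and engage them in play; can include singing games.",
      "Sung to accompany a formalized march, entrance, or parade, such as during a wedding, funeral, or the introduction of a leader.",
      "Sung to express grief or sadness about the death of a person, in the present or past.",
      "Sung to accompany work activities, including planting, grinding, harvesting, processing, tool-making.",
      "Sung to recount historical or mythological events, or narrate a sequence of activities by one or more persons.",
      "Sung to express admiration for the traits or accomplishments of a person, animal, location, or item of property."
    ),
    exclusion = c(
      "Songs that happen to be accompanied by dancing but are used for other goals.",
      "Songs describing sick people or a past epidemic.",
      "Songs about unrequited love, deceased loved ones, or love for animals or property.",
      "Songs designed to excite the listener (e.g., play songs); singing games.",
      "Children's songs for soothing, calming, or putting to sleep.",
      "Processions of dancing.",
      "Songs for sick or dying people, or laments about events other than the death of a person.",
      "Hunting songs (to celebrate successful hunts, prepare for hunts).",
      "Lullabies that include stories.",
      "A song expressing love for another person or explicitly religious songs (like devotionals)."
    ),
    stringsAsFactors = FALSE
  )
}

#' Canonical context tokens
#'
#' @return Character vector of the ten context tokens in canonical order.
#' @export
context_tokens <- function() context_vocabulary()$context

#' Geographic-region vocabulary
#'
#' Fixed vocabulary of 38 world-region tokens: the eHRAF subregion taxonomy
#' (a reconstruction of its 35 subregions, excluding the ambiguous
#' "Regional, Ethnic, and Diaspora Cultures" entry) plus Western, Central and
#' Eastern Europe. Callers with corpora annotated under a different regional
#' scheme can pass their own vocabulary to [load_metadata()].
#'
#' @return Character vector of 38 region tokens.
#' @export
region_tokens <- function() {
  c(
    # Africa
    "Central Africa", "Eastern Africa", "Northern Africa", "Southern Africa",
    "Western Africa",
    # Asia
    "Central Asia", "East Asia", "North Asia", "South Asia", "Southeast Asia",
    "Inner Asia", "Island Southeast Asia",
    # Europe (eHRAF)
    "British Isles", "Scandinavia", "Southeastern Europe", "Southern Europe",
    # Middle America and the Caribbean
    "Caribbean", "Central America", "Maya Area", "Northern Mexico",
    # Middle East
    "Middle East",
    # North America
    "Arctic and Subarctic", "Eastern Woodlands",
    "Northwest Coast and California", "Plains and Plateau",
    "Southwest and Basin",
    # Oceania
    "Australia", "Melanesia", "Micronesia", "Polynesia",
    # South America
    "Amazon and Orinoco", "Andes", "Eastern South America",
    "Northwestern South America", "Southern South America",
    # Europe additions beyond eHRAF
    "Western Europe", "Central Europe", "Eastern Europe"
  )
}
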