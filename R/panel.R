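#' Default 22-odor panel with innate valence structure
#'
#' A panel of 22 odorants mirroring the layout of a locust innate-preference
#' assay: hexanol at three dilutions plus 19 further odorants spanning
#' appetitive (green-leaf volatiles, fruity esters), neutral, and unappetitive
#' (pesticide-like, aversive aldehyde/terpene) classes. Each odor carries the
#' probability that a starved locust opens its maxillary palps (POR) on a
#' single presentation; the panel median sits near 0.4 so that preference
#' indices (median-subtracted response fractions) straddle zero.
#'
#' @return A tibble with columns `odor_id`, `valence`
#'   (`"appetitive"`, `"neutral"`, `"unappetitive"`) and `por_prob`.
#' @export
#' @examples
#' default_odor_panel()
default_odor_panel <- function() {
  tibble::tribble(
    ~odor_id,            ~valence,       ~por_prob,
    "hexanol_10pct",     "appetitive",   0.88,
    "hexanol_1pct",      "appetitive",   0.77,
    "isoamyl_acetate",   "appetitive",   0.73,
    "hexanol_0.1pct",    "appetitive",   0.65,
    "2_octanol",         "appetitive",   0.62,
    "hexanal",           "neutral",      0.55,
    "geraniol",          "neutral",      0.52,
    "ethyl_acetate",     "neutral",      0.48,
    "apple",             "neutral",      0.46,
    "grass",             "neutral",      0.44,
    "1_octanol",         "neutral",      0.42,
    "benzyl_alcohol",    "neutral",      0.38,
    "methyl_salicylate", "neutral",      0.36,
    "eugenol",           "neutral",      0.33,
    "mint",              "neutral",      0.30,
    "cyclohexanone",     "unappetitive", 0.24,
    "octanoic_acid",     "unappetitive", 0.22,
    "garlic",            "unappetitive", 0.20,
    "vinegar",           "unappetitive", 0.18,
    "benzaldehyde",      "unappetitive", 0.15,
    "citral",            "unappetitive", 0.10,
    "linalool",          "unappetitive", 0.05
  )
}

#' The four conditioning odorants
#'
#' Convenience accessor for the odors used in the appetitive-conditioning
#' stages: two innately appetitive (hexanol, isoamyl acetate) and two
#' non-appetitive (benzaldehyde, citral).
#'
#' @return Character vector of four odor ids present in
#'   [default_odor_panel()].
#' @export
conditioning_odors <- function() {
  c("hexanol_1pct", "isoamyl_acetate", "benzaldehyde", "citral")
}
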