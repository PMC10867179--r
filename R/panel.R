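#' The 13-marker chromogenic IHC panel
#'
#' Marker names used throughout the package: one melanoma marker (S100), one
#' epithelial marker (panCK), four blood-vessel markers (AQP1, CD34, aSMA,
#' MECA79), two lymphatic markers (PDPN, LYVE1), four leukocyte markers
#' (CD45, CD8, CD20, CD68), plus the hematoxylin nuclear counterstain.
#'
#' @return Character vector of the 13 marker names.
#' @export
marker_panel <- function() {
  c("S100", "panCK", "AQP1", "CD34", "aSMA", "MECA79", "PDPN", "LYVE1",
    "CD45", "CD8", "CD20", "CD68", "hematoxylin")
}

# markers profiled on every vessel object
vessel_profile_markers <- function() {
  c("AQP1", "CD34", "aSMA", "PDPN", "LYVE1", "MECA79", "panCK")
}

# markers measured on every cell
cell_profile_markers <- function() {
  c("CD45", "CD8", "CD20", "CD68", "S100")
}

#' Lymphovascular subtype levels
#'
#' The exhaustive, mutually exclusive subtype vocabulary used by
#' [classify_vessels()]: three blood subtypes (immature neovasculature
#' AQP1+CD34+aSMA+, activated capillaries/postcapillary venules
#' AQP1+CD34+aSMA-, arterioles AQP1+CD34-aSMA+), two lymphatic subtypes
#' (lymphatic capillaries PDPN+LYVE1+, inflamed lymphatic capillaries
#' PDPN+LYVE1-), the AQP1+CD34-aSMA- single-cell rejection class, and a
#' catch-all anomaly class.
#'
#' @return Character vector of subtype levels.
#' @export
vessel_subtypes <- function() {
  c("IMMATURE_NEOVASC", "ACTIVATED_CAP_PCV", "ARTERIOLE",
    "LYMPHATIC_CAP", "INFLAMED_LYMPHATIC_CAP",
    "REJECTED_SINGLE_CELL", "UNCLASSIFIED_ANOMALY")
}

blood_subtypes <- function() {
  c("IMMATURE_NEOVASC", "ACTIVATED_CAP_PCV", "ARTERIOLE")
}

lymphatic_subtypes <- function() {
  c("LYMPHATIC_CAP", "INFLAMED_LYMPHATIC_CAP")
}

#' Leukocyte class levels
#'
#' Mutually exclusive classes assigned by [gate_cells()]: CD8 T cells, CD20 B
#' cells, CD68 macrophages, other CD45+ leukocytes, and non-leukocytes.
#'
#' @return Character vector of class levels.
#' @export
cell_classes <- function() {
  c("CD8_T", "B_CELL", "MACROPHAGE", "OTHER_CD45", "NON_LEUKOCYTE")
}

# wall marker sets defining each plantable vessel subtype (truth-table of the
# hierarchical gate, used by the generator and by classification tests)
subtype_marker_sets <- function() {
  list(
    IMMATURE_NEOVASC       = c("AQP1", "CD34", "aSMA"),
    ACTIVATED_CAP_PCV      = c("AQP1", "CD34"),
    ARTERIOLE              = c("AQP1", "aSMA"),
    LYMPHATIC_CAP          = c("PDPN", "LYVE1"),
    INFLAMED_LYMPHATIC_CAP = c("PDPN")
  )
}

# marker sets for plantable cell classes; macrophages get deliberately weak
# CD45 (see gate_cells) encoded as "CD45lo"
class_marker_sets <- function() {
  list(
    CD8_T         = c("CD45", "CD8"),
    B_CELL        = c("CD45", "CD20"),
    MACROPHAGE    = c("CD68", "CD45lo"),
    OTHER_CD45    = c("CD45"),
    NON_LEUKOCYTE = c("S100")
  )
}
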