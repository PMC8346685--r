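#' ROI feature schemas
#'
#' A feature schema is an ordered table of atlas regions, one row per scalar
#' feature, that fixes the column order of every cohort matrix downstream.
#' Two families are provided: a structural schema (Desikan-Killiany cortical
#' thickness and surface area plus FreeSurfer subcortical volumes, 152
#' features) and a diffusion schema (JHU white-matter tract FA or RD, 41
#' features).
#'
#' @name roi_schema
NULL

# Desikan-Killiany cortical parcellation (34 regions per hemisphere)
DK_REGIONS <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

# FreeSurfer aseg subcortical grey-matter structures (8 per hemisphere)
ASEG_REGIONS <- c(
  "lateral_ventricle", "thalamus", "caudate", "putamen", "pallidum",
  "hippocampus", "amygdala", "accumbens")

# Bilateral JHU atlas white-matter tracts used by multi-site DTI protocols.
# The atlas midline corpus callosum segments (BCC, GCC, SCC) are added
# separately; 19 bilateral + 3 midline = 41 features.
JHU_BILATERAL_TRACTS <- c(
  "ACR", "ALIC", "CGC", "CGH", "CR", "CST", "EC", "FXST", "IC", "IFO",
  "PCR", "PLIC", "PTR", "RLIC", "SCR", "SFO", "SLF", "SS", "UNC")

JHU_MIDLINE_TRACTS <- c("BCC", "GCC", "SCC")

new_roi_schema <- function(features, modality, atlas) {
  stopifnot(is.data.frame(features),
            all(c("name", "roi_name", "measure", "hemisphere") %in%
                  names(features)))
  if (anyDuplicated(features$name))
    stopf("duplicate feature names in schema")
  structure(features, modality = modality, atlas = atlas,
            class = c("roi_schema", "data.frame"))
}

#' Build the structural ROI feature schema
#'
#' 34 Desikan-Killiany cortical regions per hemisphere, each contributing a
#' thickness and a surface-area feature, plus 8 subcortical volumes per
#' hemisphere: 68 + 68 + 16 = 152 features.
#'
#' @return A `roi_schema` data frame with columns `name`, `roi_name`,
#'   `measure` (`thickness`, `surface_area`, `subcortical_volume`) and
#'   `hemisphere` (`left`/`right`).
#' @examples
#' sch <- build_structural_schema()
#' nrow(sch)                      # 152
#' table(sch$measure)
#' @export
build_structural_schema <- function() {
  hemi <- c(left = "L", right = "R")
  blocks <- list()
  for (ms in c("thickness", "surface_area")) {
    suffix <- if (ms == "thickness") "thick" else "surf"
    for (h in names(hemi)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        name = sprintf("%s_%s_%s", hemi[[h]], DK_REGIONS, suffix),
        roi_name = DK_REGIONS, measure = ms, hemisphere = h,
        stringsAsFactors = FALSE)
    }
  }
  for (h in names(hemi)) {
    blocks[[length(blocks) + 1L]] <- data.frame(
      name = sprintf("%s_%s_vol", hemi[[h]], ASEG_REGIONS),
      roi_name = ASEG_REGIONS, measure = "subcortical_volume",
      hemisphere = h, stringsAsFactors = FALSE)
  }
  new_roi_schema(do.call(rbind, blocks), modality = "structural",
                 atlas = "Desikan-Killiany + FreeSurfer aseg")
}

#' Build the diffusion ROI feature schema
#'
#' JHU-atlas white-matter tract features: 19 bilateral tracts (left and
#' right entries each) plus the midline corpus callosum segments BCC, GCC
#' and SCC, for 41 features in total. The bilateral tract list is
#' configurable; the midline trio is fixed.
#'
#' @param measure `"FA"` (fractional anisotropy) or `"RD"` (radial
#'   diffusivity).
#' @param bilateral_tracts Character vector of bilateral tract
#'   abbreviations. Defaults to the standard multi-site DTI skeleton set.
#' @return A `roi_schema` data frame of 2 * length(bilateral_tracts) + 3
#'   rows.
#' @examples
#' sch <- build_diffusion_schema("FA")
#' nrow(sch)                                       # 41
#' sch$roi_name[sch$hemisphere == "midline"]       # BCC GCC SCC
#' @export
build_diffusion_schema <- function(measure = c("FA", "RD"),
                                   bilateral_tracts = JHU_BILATERAL_TRACTS) {
  measure <- match.arg(measure)
  if (anyDuplicated(bilateral_tracts))
    stopf("bilateral tract names must be unique")
  hemi <- c(left = "L", right = "R")
  blocks <- lapply(names(hemi), function(h) data.frame(
    name = sprintf("%s_%s_%s", bilateral_tracts, hemi[[h]], measure),
    roi_name = bilateral_tracts, measure = measure, hemisphere = h,
    stringsAsFactors = FALSE))
  blocks[[3L]] <- data.frame(
    name = sprintf("%s_%s", JHU_MIDLINE_TRACTS, measure),
    roi_name = JHU_MIDLINE_TRACTS, measure = measure,
    hemisphere = "midline", stringsAsFactors = FALSE)
  new_roi_schema(do.call(rbind, blocks),
                 modality = paste0("diffusion_", measure), atlas = "JHU")
}

#' @export
print.roi_schema <- function(x, ...) {
  cat(sprintf("<roi_schema> %s (%s): %d features\n",
              attr(x, "modality"), attr(x, "atlas"), nrow(x)))
  print(table(measure = x$measure, hemisphere = x$hemisphere))
  invisible(x)
}

schema_names <- function(schema) schema$name
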