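#' The 13 brain-region codes
#'
#' Returns the admissible region vocabulary in its fixed declaration order:
#' the four cortical lobes (FL frontal, TL temporal, PL parietal, OL
#' occipital), CB cerebellum, BS brainstem, THA_HT thalamus/hypothalamus,
#' OC optic chiasm, CC corpus callosum, VT ventricles, HIP hippocampus,
#' AN amygdaloid nucleus and OB_OT olfactory bulb/tract. Declaration order
#' is the documented tie-break order wherever region ties must be resolved.
#'
#' @return Character vector of 13 region codes.
#' @export
region_codes <- function() {
  c("FL", "TL", "PL", "OL", "CB", "BS", "THA_HT",
    "OC", "CC", "VT", "HIP", "AN", "OB_OT")
}

# Slash forms used in figures/tables map onto filesystem-safe tokens.
.region_aliases <- c("THA/HT" = "THA_HT", "OB/OT" = "OB_OT")

#' Parse region labels
#'
#' Accepts the safe tokens of [region_codes()] as well as the slash aliases
#' `"THA/HT"` and `"OB/OT"`.
#'
#' @param x Character vector of region labels.
#' @return Factor with levels `region_codes()`.
#' @export
parse_region <- function(x) {
  x <- as.character(x)
  hit <- x %in% names(.region_aliases)
  x[hit] <- .region_aliases[x[hit]]
  bad <- !x %in% region_codes() & !is.na(x)
  if (any(bad)) {
    stop("unknown region code(s): ", paste(unique(x[bad]), collapse = ", "),
         "; admissible codes are: ", paste(region_codes(), collapse = ", "),
         " (aliases THA/HT, OB/OT accepted)", call. = FALSE)
  }
  factor(x, levels = region_codes())
}

#' Display form of a region code
#'
#' Inverse of the alias mapping in [parse_region()]: `THA_HT` renders as
#' `"THA/HT"` and `OB_OT` as `"OB/OT"`.
#'
#' @param x Character vector or factor of safe region tokens.
#' @return Character vector with slash forms restored.
#' @export
format_region <- function(x) {
  x <- as.character(x)
  rev_map <- stats::setNames(names(.region_aliases), .region_aliases)
  hit <- x %in% names(rev_map)
  x[hit] <- rev_map[x[hit]]
  x
}

#' Expected region groupings from the observed clustering
#'
#' The three multi-region groups visible in the region-correlation heatmap:
#' the four cortical lobes, the hippocampus/amygdala pair, and the midline
#' group of thalamus-hypothalamus, corpus callosum and ventricles. These are
#' fixed constants against which a dendrogram cut is compared; they are not
#' derived from data.
#'
#' @return Named list of character vectors of region codes.
#' @export
framework_groups <- function() {
  list(
    lobes   = c("FL", "TL", "PL", "OL"),
    limbic  = c("HIP", "AN"),
    midline = c("THA_HT", "CC", "VT")
  )
}
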