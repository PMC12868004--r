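#' RNA region-specificity calls
#'
#' The HPA-style rule: nTPM values below `rna_lower` (default 1) are set to
#' missing, the rest log2-transformed; a gene is region-specific iff its
#' maximum log2 nTPM exists, at least one other region is non-missing, and
#' the maximum is at least `rna_ratio` (default 2) times the mean log2 nTPM
#' of the remaining non-missing regions. The comparison is a ratio of log2
#' values, as the rule is stated, not a fold change. When the rest mean is 0
#' the limit convention applies: specific iff the maximum log2 is > 0.
#'
#' @param rna An `rna_table` (see [read_rna_table()] / [rna_table()]).
#' @param config An [analysis_config()] (uses `rna_lower`, `rna_ratio`).
#' @return Data frame: gene_id, max_region, max_log2, mean_rest_log2,
#'   n_rest, specific.
#' @export
rna_specificity <- function(rna, config = analysis_config()) {
  stopifnot(inherits(rna, "rna_table"), length(rna$region_labels) >= 2)
  x <- rna$ntpm
  x[x < config$rna_lower] <- NA_real_
  lx <- log2(x)
  ng <- nrow(lx)
  max_region <- rep(NA_character_, ng)
  max_log2 <- mean_rest <- rep(NA_real_, ng)
  n_rest <- integer(ng)
  specific <- rep(FALSE, ng)
  for (i in seq_len(ng)) {
    row <- lx[i, ]
    if (all(is.na(row))) next
    j <- which.max(row)                       # first max, column order
    max_region[i] <- colnames(lx)[j]
    max_log2[i] <- row[j]
    rest <- row[-j]
    n_rest[i] <- sum(!is.na(rest))
    if (n_rest[i] == 0) next
    mean_rest[i] <- mean(rest, na.rm = TRUE)
    specific[i] <- if (mean_rest[i] == 0) max_log2[i] > 0 else
      max_log2[i] >= config$rna_ratio * mean_rest[i]
  }
  data.frame(gene_id = rownames(lx), max_region = max_region,
             max_log2 = max_log2, mean_rest_log2 = mean_rest,
             n_rest = n_rest, specific = specific,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map protein-side region calls into the RNA vocabulary
#'
#' @param spec A `specificity_table` from [call_region_specific()].
#' @param region_map Named character vector, region code -> RNA label, NA
#'   for unmappable regions (default [default_region_map()]).
#' @return Data frame: protein_id, called (protein-side specific flag),
#'   region (protein side), rna_region (mapped label or NA), mappable.
#' @export
map_protein_regions_to_rna <- function(spec, region_map = default_region_map()) {
  called <- spec$call
  reg <- spec$max_region
  enc <- unique(reg[called & !is.na(reg)])
  missing_map <- setdiff(enc, names(region_map))
  if (length(missing_map) > 0)
    stop("region map lacks entries for: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  rna_region <- rep(NA_character_, nrow(spec))
  rna_region[!is.na(reg)] <- region_map[reg[!is.na(reg)]]
  data.frame(protein_id = spec$protein_id, called = called, region = reg,
             rna_region = rna_region,
             mappable = !is.na(rna_region),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Proteome-transcriptome concordance classes
#'
#' Each protein in the specificity table is assigned exactly one class:
#' `unmapped` (no gene in the id map), `both` (protein- and RNA-specific),
#' `protein_only`, `rna_only`, or `background`. For class `both`,
#' `region_agreement` records whether the mapped protein region equals the
#' RNA-specific region; the class itself does not require agreement.
#'
#' @param protein_calls Output of [map_protein_regions_to_rna()].
#' @param rna_calls Output of [rna_specificity()].
#' @param idmap Data frame protein_id, gene_id (each protein maps to <= 1
#'   gene).
#' @return Data frame: protein_id, gene_id, class, region_agreement.
#' @export
concordance_classify <- function(protein_calls, rna_calls, idmap) {
  if (anyDuplicated(idmap$protein_id))
    stop("duplicate protein_id in id map", call. = FALSE)
  gene <- idmap$gene_id[match(protein_calls$protein_id, idmap$protein_id)]
  ri <- match(gene, rna_calls$gene_id)
  gene_specific <- !is.na(ri) & rna_calls$specific[ri]
  rna_region <- ifelse(is.na(ri), NA_character_, rna_calls$max_region[ri])

  cls <- rep("background", nrow(protein_calls))
  cls[protein_calls$called & gene_specific] <- "both"
  cls[protein_calls$called & !gene_specific] <- "protein_only"
  cls[!protein_calls$called & gene_specific] <- "rna_only"
  cls[is.na(gene)] <- "unmapped"

  agree <- rep(NA, nrow(protein_calls))
  b <- cls == "both"
  agree[b] <- !is.na(protein_calls$rna_region[b]) &
    protein_calls$rna_region[b] == rna_region[b]
  data.frame(protein_id = protein_calls$protein_id, gene_id = gene,
             class = factor(cls, levels = c("both", "protein_only",
                                            "rna_only", "unmapped",
                                            "background")),
             region_agreement = agree,
             stringsAsFactors = FALSE, row.names = NULL)
}
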