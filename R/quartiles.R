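#' Per-region relative protein abundance
#'
#' For each region: a protein's mean ppm over the region's observed samples,
#' divided by the region total, so fractions sum to 1. Proteins unobserved in
#' a region are excluded from that region's vector.
#'
#' @param matrix A ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @return Named list (region -> named fraction vector).
#' @export
region_relative_abundance <- function(matrix, annotations) {
  stopifnot(matrix_stage(matrix) == "ppm")
  ann <- .match_annotations(matrix, annotations)
  v <- .unwrap(matrix)
  regs <- region_codes()[region_codes() %in% as.character(ann$region)]
  out <- list()
  for (r in regs) {
    cols <- which(as.character(ann$region) == r)
    sub <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    obs <- n > 0
    if (!any(obs)) {
      warning("region ", r, " has no observed values; skipped")
      next
    }
    fr <- m[obs] / sum(m[obs])
    names(fr) <- rownames(v)[obs]
    out[[r]] <- fr
  }
  out
}

#' Cumulative-abundance quartile partition
#'
#' Proteins are ranked by relative abundance (descending, ties by protein
#' id). Each protein's cumulative start is the summed fraction of all more
#' abundant proteins; its quartile is the bin `[b_{k-1}, b_k)` containing
#' that start (Q1 holds the most abundant proteins making up the first 25%
#' of the region's total abundance).
#'
#' @param fractions Named nonnegative fraction vector summing to 1.
#' @param bounds Increasing cut points ending at 1 (default quartiles).
#' @return Data frame: protein_id, fraction, cum_start, quartile; attribute
#'   `counts` is the per-quartile protein count.
#' @export
cumulative_quartiles <- function(fractions, bounds = c(0.25, 0.5, 0.75, 1)) {
  if (any(fractions < 0)) stop("negative abundance fraction", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  ord <- order(-fractions, names(fractions))
  fr <- fractions[ord]
  start <- cumsum(c(0, fr[-length(fr)]))
  qi <- findInterval(start, c(0, bounds[-length(bounds)]))
  lab <- paste0("Q", seq_along(bounds))
  quart <- factor(lab[qi], levels = lab)
  out <- data.frame(protein_id = names(fr), fraction = unname(fr),
                    cum_start = unname(start), quartile = quart,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "counts") <- table(quart)
  out
}

#' Quartile partition for every region
#'
#' @param matrix A ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @param config An [analysis_config()] (uses `quartile_bounds`).
#' @return List with `table` (long data.frame: region, protein_id, fraction,
#'   cum_start, quartile) and `counts` (region x quartile).
#' @export
region_quartiles <- function(matrix, annotations, config = analysis_config()) {
  fr <- region_relative_abundance(matrix, annotations)
  tabs <- lapply(names(fr), function(r) {
    q <- cumulative_quartiles(fr[[r]], config$quartile_bounds)
    cbind(region = r, q, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  counts <- as.data.frame.matrix(
    table(tab$region, tab$quartile)[names(fr), , drop = FALSE])
  counts <- cbind(region = rownames(counts), counts, stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(table = tab, counts = counts)
}
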