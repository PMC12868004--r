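#' Marker-recovery metrics against planted ground truth
#'
#' Sensitivity (planted markers called), empirical FDR (calls that are not
#' planted markers, pooled across regions), region accuracy (true-positive
#' calls assigned to the planted region), and the consensus-correlation
#' error when the truth carries `rho_true` and the table a consensus fit.
#'
#' @param calls A `specificity_table` from [call_region_specific()].
#' @param truth Truth table from [generate_proteome_dataset()].
#' @return List of class `recovery_report`: sensitivity, empirical_fdr
#'   (NA when no calls), region_accuracy (NA when no true positives),
#'   rho_error (NA when not computable), n_calls, n_markers.
#' @export
recovery_metrics <- function(calls, truth) {
  if (!setequal(calls$protein_id, truth$protein_id))
    stop("call and truth protein universes differ", call. = FALSE)
  tr <- truth[match(calls$protein_id, truth$protein_id), , drop = FALSE]
  called <- calls$call
  tp <- called & tr$is_marker
  n_calls <- sum(called)
  n_markers <- sum(tr$is_marker)
  sens <- if (n_markers > 0) sum(tp) / n_markers else NA_real_
  fdr <- if (n_calls > 0) sum(called & !tr$is_marker) / n_calls else NA_real_
  reg_acc <- if (sum(tp) > 0)
    mean(calls$max_region[tp] == tr$marker_region[tp]) else NA_real_
  rho_err <- NA_real_
  cons <- attr(calls, "consensus")
  rho_true <- attr(truth, "rho_true")
  if (!is.null(cons) && !is.null(rho_true))
    rho_err <- abs(cons$rho_consensus - rho_true)
  structure(list(sensitivity = sens, empirical_fdr = fdr,
                 region_accuracy = reg_acc, rho_error = rho_err,
                 n_calls = n_calls, n_markers = n_markers),
            class = "recovery_report")
}

#' Called fraction under the global null
#'
#' Generates marker-free datasets and reports the fraction of proteins
#' called region-specific in each replicate — a calibration check that the
#' adjusted-p threshold controls false calls under the null. Replicate seeds
#' are `params$seed + rep`.
#'
#' @param params [generator_params()] with `markers_per_region = 0`.
#' @param config An [analysis_config()].
#' @param n_reps Number of replicates.
#' @return Data frame (rep, seed, n_proteins, called_fraction); attribute
#'   `mean_called_fraction`.
#' @export
null_calibration <- function(params, config = analysis_config(), n_reps = 5L) {
  stopifnot(inherits(params, "generator_params"),
            params$markers_per_region == 0)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- params$seed + r
    ds <- generate_proteome_dataset(p)
    lg <- log2_transform(to_ppm(ds$matrix))
    tab <- call_region_specific(lg, ds$annotations, config)
    rows[[r]] <- data.frame(rep = r, seed = p$seed,
                            n_proteins = nrow(tab),
                            called_fraction = mean(tab$call))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rep = integer(0), seed = integer(0),
                      n_proteins = integer(0), called_fraction = numeric(0))
  attr(out, "mean_called_fraction") <-
    if (nrow(out) > 0) mean(out$called_fraction) else NA_real_
  out
}

# Internal: a generator variant planting one shared marker set per expected
# region group, so regions inside a group share correlated profile structure.
.generate_grouped_dataset <- function(params, markers_per_group = 25L) {
  set.seed(params$seed)
  base <- params
  base$markers_per_region <- 0L
  ds <- generate_proteome_dataset(base)
  groups <- framework_groups()
  v <- .unwrap(ds$matrix)
  reg <- as.character(ds$annotations$region)
  np <- nrow(v)
  need <- markers_per_group * length(groups)
  stopifnot(need <= np)
  set.seed(params$seed + 10000L)
  idx <- sample(np, need)
  for (k in seq_along(groups)) {
    rows <- idx[seq((k - 1) * markers_per_group + 1, k * markers_per_group)]
    cols <- which(reg %in% groups[[k]])
    v[rows, cols] <- v[rows, cols] * 2^params$log2_effect
  }
  ds$matrix <- abundance_matrix(v, stage = "raw")
  ds$group_markers <- idx
  ds
}

#' Recovery probability of the expected region groups
#'
#' For each of `n_seeds` seeds: generate a dataset whose regions carry
#' shared elevated marker sets inside each expected group, cluster the
#' region-correlation matrix, cut at k = 4, and record whether each group is
#' co-clustered. Reports the per-group recovery fraction over seeds.
#'
#' @param params Base [generator_params()] (its `log2_effect` and noise
#'   fields set the planted structure; markers_per_region is ignored).
#' @param config An [analysis_config()].
#' @param n_seeds Number of independent seeds.
#' @param markers_per_group Shared markers planted per group.
#' @return Data frame (group, n_recovered, n_seeds, recovery_fraction);
#'   attribute `per_seed` has the full flag matrix.
#' @export
module_recovery <- function(params, config = analysis_config(),
                            n_seeds = 20L, markers_per_group = 25L) {
  groups <- framework_groups()
  flags <- matrix(NA, n_seeds, length(groups),
                  dimnames = list(NULL, names(groups)))
  for (s in seq_len(n_seeds)) {
    p <- params
    p$seed <- params$seed + s
    ds <- .generate_grouped_dataset(p, markers_per_group)
    lg <- log2_transform(to_ppm(ds$matrix))
    prof <- region_profile_matrix(lg, ds$annotations)
    dend <- hierarchical_cluster(region_correlation(prof), config)
    cmp <- compare_to_framework(dend, k = 4L)
    flags[s, ] <- cmp$co_clustered[match(names(groups), cmp$group)]
  }
  out <- data.frame(group = names(groups),
                    n_recovered = colSums(flags == TRUE, na.rm = TRUE),
                    n_seeds = n_seeds,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$recovery_fraction <- out$n_recovered / n_seeds
  attr(out, "per_seed") <- flags
  out
}
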