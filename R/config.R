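#' Analysis configuration
#'
#' All tunable thresholds of the pipeline in one place. Defaults are the
#' published calling rule: a protein is region-specific when its top region's
#' geometric-mean abundance is at least `fc_threshold` (1.5) times the pooled
#' mean of the remaining regions and the donor-blocked ANOVA BH-adjusted p
#' value is below `alpha` (0.01).
#'
#' @param fc_threshold Linear fold-change threshold vs the remaining regions.
#' @param alpha BH-adjusted p-value cutoff.
#' @param min_obs_max_region Minimum observed samples in the top region for a
#'   call.
#' @param min_testable_regions Minimum regions with >= 1 observation for a
#'   protein to enter testing.
#' @param blocking `"blocked"` (donor compound-symmetry correction) or
#'   `"oneway"` (plain one-way ANOVA).
#' @param trim Trim fraction (each tail) for the Fisher-z trimmed mean in the
#'   consensus-correlation estimator.
#' @param rho_clamp Length-2 interval to which per-protein correlation
#'   estimates are clamped.
#' @param fc_scale `"geometric"` (2^difference of mean log2, default) or
#'   `"linear"` (ratio of linear-ppm means) fold change.
#' @param rna_lower nTPM floor; values below it are treated as missing.
#' @param rna_ratio Required ratio of max log2 nTPM to mean log2 nTPM of the
#'   remaining regions.
#' @param distance Region-distance flavour for clustering (only `"pearson"`).
#' @param linkage Agglomeration rule (only `"complete"`).
#' @param quartile_bounds Strictly increasing cumulative-abundance cut points
#'   ending at 1.
#' @param seed Integer seed recorded in run manifests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold = 1.5,
                            alpha = 0.01,
                            min_obs_max_region = 2L,
                            min_testable_regions = 3L,
                            blocking = c("blocked", "oneway"),
                            trim = 0.15,
                            rho_clamp = c(-0.95, 0.95),
                            fc_scale = c("geometric", "linear"),
                            rna_lower = 1.0,
                            rna_ratio = 2.0,
                            distance = "pearson",
                            linkage = "complete",
                            quartile_bounds = c(0.25, 0.50, 0.75, 1.00),
                            seed = 1L) {
  blocking <- match.arg(blocking)
  fc_scale <- match.arg(fc_scale)
  distance <- match.arg(distance, "pearson")
  linkage <- match.arg(linkage, "complete")
  stopifnot(fc_threshold > 0, alpha > 0, alpha < 1,
            min_obs_max_region >= 1, min_testable_regions >= 2,
            trim >= 0, trim < 0.5,
            length(rho_clamp) == 2, rho_clamp[1] < rho_clamp[2],
            rho_clamp[1] > -1, rho_clamp[2] < 1,
            rna_lower > 0, rna_ratio > 0)
  qb <- quartile_bounds
  if (any(diff(qb) <= 0) || abs(qb[length(qb)] - 1) > 1e-12 || any(qb <= 0))
    stop("quartile_bounds must be strictly increasing and end at 1", call. = FALSE)
  structure(list(
    fc_threshold = fc_threshold, alpha = alpha,
    min_obs_max_region = as.integer(min_obs_max_region),
    min_testable_regions = as.integer(min_testable_regions),
    blocking = blocking, trim = trim, rho_clamp = rho_clamp,
    fc_scale = fc_scale, rna_lower = rna_lower, rna_ratio = rna_ratio,
    distance = distance, linkage = linkage, quartile_bounds = qb,
    seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Flat keys mirroring the arguments of [analysis_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(analysis_config, vals)
}
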