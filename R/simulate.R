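#' Parameters of the synthetic proteome generator
#'
#' The generator emulates the structure of a donor x region label-free DIA
#' study: per-protein log2 baselines spanning several orders of magnitude,
#' planted region markers, donor random effects inducing intra-donor
#' correlation, per-sample depth factors, and missingness as MCAR followed by
#' intensity-dependent (left-censoring) MNAR. Defaults emulate the mapped
#' study scale: 4,660 proteins, 13 regions, 8 donors, ~16% overall
#' missingness.
#'
#' @param n_proteins Number of proteins.
#' @param regions Character vector of region codes (default all 13).
#' @param n_donors Number of donors.
#' @param markers_per_region Planted markers per region.
#' @param log2_effect Marker elevation in its region, log2 units.
#' @param baseline_mean,baseline_sd Location/scale of protein baselines on
#'   the log2-ppm scale.
#' @param donor_sd Donor random-effect sd (log2 units).
#' @param resid_sd Residual sd (log2 units).
#' @param depth_spread Log-normal sd of the per-sample multiplicative depth
#'   factor (0 = equal depth).
#' @param mcar_rate Fraction of cells missing completely at random.
#' @param mnar_mid,mnar_scale Midpoint/steepness (log2 scale) of the logistic
#'   MNAR mechanism: a cell at log2 intensity x is additionally missing with
#'   probability `plogis((mnar_mid - x)/mnar_scale)`; `mnar_scale = 0`
#'   disables MNAR.
#' @param n_drop_cells Donor x region cells dropped at random from the full
#'   grid (emulates an unbalanced design, e.g. 99 of 104 samples).
#' @param rna_concordance Probability that a planted marker's gene is also
#'   RNA-specific in its mapped region.
#' @param rna_unmapped Probability that a protein has no gene in the id map.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_proteins = 4660L,
                             regions = region_codes(),
                             n_donors = 8L,
                             markers_per_region = 20L,
                             log2_effect = 2,
                             baseline_mean = 7,
                             baseline_sd = 2,
                             donor_sd = 0.3,
                             resid_sd = 0.5,
                             depth_spread = 0.25,
                             mcar_rate = 0.10,
                             mnar_mid = 2.9,
                             mnar_scale = 1.0,
                             n_drop_cells = 5L,
                             rna_concordance = 1.0,
                             rna_unmapped = 0.0,
                             seed = 1L) {
  regions <- as.character(parse_region(regions))
  p <- list(n_proteins = as.integer(n_proteins), regions = regions,
            n_donors = as.integer(n_donors),
            markers_per_region = as.integer(markers_per_region),
            log2_effect = log2_effect, baseline_mean = baseline_mean,
            baseline_sd = baseline_sd, donor_sd = donor_sd,
            resid_sd = resid_sd, depth_spread = depth_spread,
            mcar_rate = mcar_rate, mnar_mid = mnar_mid,
            mnar_scale = mnar_scale, n_drop_cells = as.integer(n_drop_cells),
            rna_concordance = rna_concordance, rna_unmapped = rna_unmapped,
            seed = as.integer(seed))
  stopifnot(p$n_proteins >= 1, length(p$regions) >= 2, p$n_donors >= 1,
            p$markers_per_region >= 0, p$baseline_sd >= 0, p$donor_sd >= 0,
            p$resid_sd >= 0, p$depth_spread >= 0,
            p$mcar_rate >= 0, p$mcar_rate <= 1, p$mnar_scale >= 0,
            p$rna_concordance >= 0, p$rna_concordance <= 1,
            p$rna_unmapped >= 0, p$rna_unmapped <= 1,
            p$n_drop_cells >= 0)
  if (p$markers_per_region * length(p$regions) > p$n_proteins)
    stop("infeasible marker allocation: markers_per_region x |regions| ",
         "exceeds n_proteins", call. = FALSE)
  if (p$n_drop_cells >= p$n_donors * length(p$regions))
    stop("n_drop_cells must leave at least one sample", call. = FALSE)
  structure(p, class = "generator_params")
}

#' Generate a synthetic proteome dataset with ground truth
#'
#' Model per protein g, sample i of donor j in region r:
#' `log2 x = mu_g + beta_g * [r == r_g] + d_gj + eps`, with
#' `d_gj ~ N(0, donor_sd^2)` drawn independently per protein and donor and
#' `eps ~ N(0, resid_sd^2)`. The raw linear value is `2^x` times the sample's
#' depth factor. Missingness is MCAR at `mcar_rate` followed by logistic MNAR
#' on the (pre-depth) log2 intensity. One sample per donor x region cell;
#' `n_drop_cells` cells are removed at random.
#'
#' @param params A [generator_params()].
#' @return List with `matrix` (raw [abundance_matrix()]), `annotations`
#'   (sample_id, donor_id, region), and `truth` (per-protein `is_marker`,
#'   `marker_region`, `log2_effect`; attribute `rho_true` =
#'   donor_sd^2 / (donor_sd^2 + resid_sd^2)).
#' @export
generate_proteome_dataset <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  nr <- length(params$regions)
  proteins <- sprintf("P%05d", seq_len(params$n_proteins))
  donors <- sprintf("d%d", seq_len(params$n_donors))

  grid <- expand.grid(donor_id = donors, region = params$regions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (params$n_drop_cells > 0) {
    drop <- sample(nrow(grid), params$n_drop_cells)
    grid <- grid[-drop, , drop = FALSE]
  }
  grid$sample_id <- paste(grid$donor_id, grid$region, sep = "_")
  ann <- data.frame(sample_id = grid$sample_id, donor_id = grid$donor_id,
                    region = parse_region(grid$region),
                    stringsAsFactors = FALSE)
  ns <- nrow(ann)

  # marker allocation: a random protein subset, region-by-region
  marker_region <- rep(NA_character_, params$n_proteins)
  n_mark <- params$markers_per_region * nr
  if (n_mark > 0) {
    idx <- sample(params$n_proteins, n_mark)
    marker_region[idx] <- rep(params$regions, each = params$markers_per_region)
  }
  is_marker <- !is.na(marker_region)

  mu <- stats::rnorm(params$n_proteins, params$baseline_mean, params$baseline_sd)
  donor_eff <- matrix(stats::rnorm(params$n_proteins * params$n_donors,
                                   0, params$donor_sd),
                      nrow = params$n_proteins,
                      dimnames = list(proteins, donors))
  eps <- matrix(stats::rnorm(params$n_proteins * ns, 0, params$resid_sd),
                nrow = params$n_proteins)

  x <- mu + eps + donor_eff[, ann$donor_id, drop = FALSE]
  reg_chr <- as.character(ann$region)
  for (j in seq_len(ns)) {
    hit <- which(marker_region == reg_chr[j])
    if (length(hit) > 0) x[hit, j] <- x[hit, j] + params$log2_effect
  }

  depth <- if (params$depth_spread > 0)
    stats::rlnorm(ns, 0, params$depth_spread) else rep(1, ns)
  raw <- 2^x * rep(depth, each = params$n_proteins)

  miss <- matrix(stats::runif(length(x)) < params$mcar_rate, nrow = nrow(x))
  if (params$mnar_scale > 0) {
    pm <- stats::plogis((params$mnar_mid - x) / params$mnar_scale)
    miss <- miss | (matrix(stats::runif(length(x)), nrow = nrow(x)) < pm)
  }
  raw[miss] <- NA_real_
  dimnames(raw) <- list(proteins, ann$sample_id)

  truth <- data.frame(protein_id = proteins, is_marker = is_marker,
                      marker_region = marker_region,
                      log2_effect = ifelse(is_marker, params$log2_effect, 0),
                      stringsAsFactors = FALSE)
  v <- params$donor_sd^2 + params$resid_sd^2
  attr(truth, "rho_true") <- if (v > 0) params$donor_sd^2 / v else 0

  list(matrix = abundance_matrix(raw, stage = "raw"),
       annotations = ann, truth = truth)
}

#' Default proteome-to-RNA region correspondence
#'
#' The five RNA-side territories used for cross-omics comparison: the four
#' cortical lobes plus olfactory bulb/tract collapse to cortex (`Cx`);
#' cerebellum, brainstem, hippocampus and thalamus/hypothalamus map onto
#' themselves. Remaining regions (OC, CC, VT, AN) have no RNA-side
#' counterpart and are `NA` (unmappable).
#'
#' @return Named character vector over [region_codes()].
#' @export
default_region_map <- function() {
  m <- stats::setNames(rep(NA_character_, 13), region_codes())
  m[c("FL", "TL", "PL", "OL", "OB_OT")] <- "Cx"
  m["CB"] <- "CB"; m["BS"] <- "BS"; m["HIP"] <- "HIP"; m["THA_HT"] <- "THA_HT"
  m
}

#' Generate a matched RNA table and identifier map
#'
#' Every protein gets gene `g_<protein_id>` unless sampled into the unmapped
#' fraction. A planted marker whose region maps into the RNA vocabulary is
#' made RNA-specific there with probability `rna_concordance` (its nTPM
#' pattern satisfies the log2-scale >= 2x rule); all other genes receive a
#' flat nTPM profile that fails the rule.
#'
#' @param truth Truth table from [generate_proteome_dataset()].
#' @param params The same [generator_params()].
#' @param region_labels RNA-side vocabulary (default the five territories of
#'   [default_region_map()]).
#' @return List with `rna` (an `rna_table`) and `idmap` (protein_id,
#'   gene_id).
#' @export
generate_rna_table <- function(truth, params,
                               region_labels = c("Cx", "CB", "BS", "HIP",
                                                 "THA_HT")) {
  stopifnot(inherits(params, "generator_params"),
            all(c("protein_id", "is_marker", "marker_region") %in% names(truth)))
  set.seed(params$seed + 1L)
  rmap <- default_region_map()
  mapped_lab <- rep(NA_character_, nrow(truth))
  mk <- which(truth$is_marker)
  mapped_lab[mk] <- rmap[truth$marker_region[mk]]
  known <- mapped_lab[!is.na(mapped_lab)]
  if (length(known) > 0 && !all(known %in% region_labels))
    stop("region label(s) not in RNA vocabulary: ",
         paste(setdiff(known, region_labels), collapse = ", "), call. = FALSE)

  genes <- paste0("g_", truth$protein_id)
  keep <- stats::runif(nrow(truth)) >= params$rna_unmapped
  idmap <- data.frame(protein_id = truth$protein_id[keep],
                      gene_id = genes[keep], stringsAsFactors = FALSE)

  # flat baseline nTPM = 4 (log2 = 2) fails the >=2x log2 rule everywhere;
  # a concordant marker gets nTPM 32 (log2 = 5 >= 2 * 2) in its mapped region
  ntpm <- matrix(4, nrow = nrow(truth), ncol = length(region_labels),
                 dimnames = list(genes, region_labels))
  conc <- stats::runif(nrow(truth)) < params$rna_concordance
  hit <- which(truth$is_marker & !is.na(mapped_lab) & conc)
  if (length(hit) > 0)
    ntpm[cbind(hit, match(mapped_lab[hit], region_labels))] <- 32
  list(rna = rna_table(ntpm), idmap = idmap)
}
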