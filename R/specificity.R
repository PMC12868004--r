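#' Per-protein region means and counts
#'
#' Mean log2 ppm and observation count per protein per region, over observed
#' values only, plus each protein's pooled mean.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @return List of class `region_stats`: `means` and `counts` (proteins x
#'   regions, regions in declaration order), `pooled_mean`, `regions`.
#' @export
region_stats <- function(matrix, annotations) {
  stopifnot(matrix_stage(matrix) == "log2ppm")
  ann <- .match_annotations(matrix, annotations)
  v <- .unwrap(matrix)
  regs <- region_codes()[region_codes() %in% as.character(ann$region)]
  means <- counts <- matrix(NA_real_, nrow(v), length(regs),
                            dimnames = list(rownames(v), regs))
  for (k in seq_along(regs)) {
    cols <- which(as.character(ann$region) == regs[k])
    sub <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    counts[, k] <- n
    means[, k] <- ifelse(n > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
  }
  structure(list(means = means, counts = counts,
                 pooled_mean = rowMeans(v, na.rm = TRUE), regions = regs),
            class = "region_stats")
}

#' Consensus intra-donor correlation
#'
#' A single correlation, pooled across proteins, describing how samples from
#' the same donor co-vary after region effects are removed. Per protein with
#' residual degrees of freedom >= 3: residuals are value minus region mean;
#' the per-protein estimate is a method-of-moments ratio of within-donor
#' cross-region residual products to the residual variance. Because a region
#' mean contains every donor's effect, the expected product of a within-donor
#' pair spanning regions r and r' is deflated by the finite-block factor
#' `kappa = 1 - 1/n_r - 1/n_r' + m/(n_r n_r')` (n = observations per region,
#' m = donors observed in both); the estimator divides by the summed kappa
#' rather than the pair count, which removes this small-sample attenuation.
#' Same-region within-donor pairs (absent from the default one-sample-per-
#' cell design) are excluded, as their deflation also involves the residual
#' variance. Estimates are clamped and pooled by a trimmed mean on the
#' Fisher-z scale.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @param config An [analysis_config()] (uses `trim`, `rho_clamp`).
#' @return List of class `consensus_correlation`: `rho_consensus`,
#'   `rho_per_protein` (named, NA where not estimable), `trim`, `n_used`.
#' @export
estimate_consensus_correlation <- function(matrix, annotations,
                                           config = analysis_config()) {
  stopifnot(matrix_stage(matrix) == "log2ppm")
  ann <- .match_annotations(matrix, annotations)
  v <- .unwrap(matrix)
  reg <- as.character(ann$region)
  donors <- unique(ann$donor_id)
  if (sum(table(ann$donor_id) >= 2) < 2)
    stop("need >= 2 donors with >= 2 samples each; ",
         "use blocking = 'oneway' otherwise", call. = FALSE)

  # residuals about region means, all proteins at once
  resid <- v
  regs <- unique(reg)
  n_reg_obs <- rep(0L, nrow(v))
  for (r in regs) {
    cols <- which(reg == r)
    sub <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- ifelse(n > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    resid[, cols] <- sub - m
    n_reg_obs <- n_reg_obs + (n > 0L)
  }
  n_obs <- rowSums(!is.na(v))
  df <- n_obs - n_reg_obs
  s2 <- rowSums(resid^2, na.rm = TRUE) / pmax(df, 1)

  np <- nrow(v)
  obs <- !is.na(resid)
  e0 <- resid; e0[!obs] <- 0
  # per-protein observation counts per region
  n_reg <- sapply(regs, function(r)
    rowSums(obs[, which(reg == r), drop = FALSE]))
  # accumulate, per region pair: within-donor residual products (P) and the
  # count of donors observed in both regions (M), per protein
  pairs_idx <- utils::combn(seq_along(regs), 2)
  P <- M <- matrix(0, np, ncol(pairs_idx))
  for (d in donors) {
    cols <- which(ann$donor_id == d)
    if (length(cols) < 2) next
    dreg <- match(reg[cols], regs)
    for (pi in seq_len(ncol(pairs_idx))) {
      a <- cols[dreg == pairs_idx[1, pi]]
      b <- cols[dreg == pairs_idx[2, pi]]
      if (length(a) == 0 || length(b) == 0) next
      for (ca in a) for (cb in b) {
        P[, pi] <- P[, pi] + e0[, ca] * e0[, cb]
        M[, pi] <- M[, pi] + (obs[, ca] & obs[, cb])
      }
    }
  }
  na_ <- n_reg[, pairs_idx[1, ], drop = FALSE]
  nb_ <- n_reg[, pairs_idx[2, ], drop = FALSE]
  kappa <- M * (1 - 1 / pmax(na_, 1) - 1 / pmax(nb_, 1)) + M^2 / pmax(na_ * nb_, 1)
  kappa[M == 0] <- 0
  pair_sum <- rowSums(P)
  kappa_sum <- rowSums(kappa)
  n_pairs <- rowSums(M)

  ok <- df >= 3 & n_pairs >= 1 & kappa_sum > 0 & s2 > 0
  rho <- rep(NA_real_, np)
  rho[ok] <- (pair_sum[ok] / kappa_sum[ok]) / s2[ok]
  rho[ok] <- pmin(pmax(rho[ok], config$rho_clamp[1]), config$rho_clamp[2])
  names(rho) <- rownames(v)
  if (!any(ok))
    stop("no protein has within-donor sample pairs; ",
         "use blocking = 'oneway'", call. = FALSE)
  consensus <- tanh(mean(atanh(rho[ok]), trim = config$trim))
  structure(list(rho_consensus = consensus, rho_per_protein = rho,
                 trim = config$trim, n_used = sum(ok)),
            class = "consensus_correlation")
}

#' Donor-blocked one-way region ANOVA for one protein
#'
#' Accounts for intra-donor correlation through a compound-symmetry
#' covariance: within each donor block of size m the values are whitened as
#' `y* = (y - c * mean(block)) / sqrt(1 - rho)` with
#' `c = 1 - sqrt((1 - rho) / (1 + (m - 1) rho))` (the inverse square root of
#' the compound-symmetry correlation), then an ordinary one-way ANOVA of
#' region on the whitened values is computed. With `rho = 0` this is exactly
#' the textbook one-way F test.
#'
#' @param values Numeric vector of one protein's observed log2 values.
#' @param annotations Annotations for those samples (same order).
#' @param rho Intra-donor correlation (scalar).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
blocked_anova_f <- function(values, annotations, rho = 0) {
  ann <- as_sample_annotation(annotations)
  stopifnot(length(values) == nrow(ann), !anyNA(values))
  reg <- as.character(ann$region)
  r <- length(unique(reg))
  n <- length(values)
  if (r < 2) stop("need >= 2 regions observed", call. = FALSE)
  df1 <- r - 1L
  df2 <- n - r
  if (df2 < 1) stop("no residual degrees of freedom (df2 < 1)", call. = FALSE)

  m_max <- max(table(ann$donor_id))
  if (rho >= 1 || (m_max > 1 && rho <= -1 / (m_max - 1)))
    stop(sprintf("rho = %g outside (-1/(m-1), 1) for max block size m = %d; ",
                 rho, m_max), call. = FALSE)

  y <- values
  if (rho != 0) {
    for (d in unique(ann$donor_id)) {
      i <- which(ann$donor_id == d)
      m <- length(i)
      cc <- 1 - sqrt((1 - rho) / (1 + (m - 1) * rho))
      y[i] <- (y[i] - cc * mean(y[i])) / sqrt(1 - rho)
    }
  }

  gm <- mean(y)
  ssb <- 0; ssw <- 0
  for (g in unique(reg)) {
    i <- which(reg == g)
    mg <- mean(y[i])
    ssb <- ssb + length(i) * (mg - gm)^2
    ssw <- ssw + sum((y[i] - mg)^2)
  }
  if (ssw <= 0) {
    if (ssb <= 1e-24) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up FDR adjustment over the non-missing entries only (m = count
#' present); missing entries stay missing and positions are preserved.
#'
#' @param pvals Numeric vector of p-values, NA allowed.
#' @return Adjusted vector, same length and order.
#' @export
benjamini_hochberg <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m > 0) {
    o <- order(p)
    vals <- p[o] * m / seq_len(m)
    adj <- pmin(rev(cummin(rev(vals))), 1)
    res <- numeric(m)
    res[o] <- adj
    out[ok] <- res
  }
  out
}

#' Top region and fold change versus the remaining regions
#'
#' The top region is the one with the highest mean log2 ppm (ties broken by
#' region declaration order and flagged). The fold change compares the top
#' region's mean against the pooled mean over all observed samples from the
#' remaining regions, as a linear ratio `2^(difference of log2 means)`.
#'
#' @param stats A [region_stats()] result.
#' @param matrix The log2ppm matrix the stats came from.
#' @param annotations Sample annotations.
#' @param fc_scale `"geometric"` (default; 2^difference of mean log2) or
#'   `"linear"` (ratio of arithmetic means of linear ppm).
#' @return Data frame: protein_id, max_region, tie_flag, fc_vs_rest,
#'   n_max_region, n_regions_observed. fc is NA for proteins observed in < 2
#'   regions.
#' @export
fold_change_vs_rest <- function(stats, matrix, annotations,
                                fc_scale = c("geometric", "linear")) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(inherits(stats, "region_stats"))
  ann <- .match_annotations(matrix, annotations)
  v <- .unwrap(matrix)
  means <- stats$means; counts <- stats$counts
  np <- nrow(means)
  n_reg_obs <- rowSums(counts > 0, na.rm = TRUE)

  max_region <- rep(NA_character_, np)
  tie_flag <- rep(FALSE, np)
  fc <- rep(NA_real_, np)
  n_max <- rep(0L, np)

  reg_of_col <- as.character(ann$region)
  has <- n_reg_obs >= 1
  # top region: first column (declaration order) attaining the row max
  mm <- means
  mm[is.na(mm)] <- -Inf
  top <- max.col(mm, ties.method = "first")
  rowmax <- mm[cbind(seq_len(np), top)]
  n_at_max <- rowSums(mm == rowmax & is.finite(mm))
  max_region[has] <- stats$regions[top[has]]
  tie_flag[has] <- n_at_max[has] > 1
  n_max[has] <- counts[cbind(which(has), top[has])]

  comp <- which(n_reg_obs >= 2)
  for (i in comp) {
    max_cols <- which(reg_of_col == max_region[i])
    rest_vals <- v[i, -max_cols]
    if (fc_scale == "geometric") {
      fc[i] <- 2^(means[i, top[i]] - mean(rest_vals, na.rm = TRUE))
    } else {
      fc[i] <- mean(2^v[i, max_cols], na.rm = TRUE) /
        mean(2^rest_vals, na.rm = TRUE)
    }
  }
  data.frame(protein_id = rownames(v), max_region = max_region,
             tie_flag = tie_flag, fc_vs_rest = fc, n_max_region = n_max,
             n_regions_observed = n_reg_obs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call region-specific proteins
#'
#' The full calling pipeline: region stats, consensus intra-donor correlation
#' (when `blocking = "blocked"`), per-protein donor-blocked F test, BH
#' adjustment over testable proteins, fold change versus the remaining
#' regions. A protein is testable when at least `min_testable_regions`
#' regions have an observation and residual df >= 1; it is called
#' region-specific when additionally the BH-adjusted p is below `alpha`, the
#' fold change is at least `fc_threshold`, and its top region has at least
#' `min_obs_max_region` observations.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @param config An [analysis_config()].
#' @return Data frame of class `specificity_table` (one row per protein:
#'   protein_id, max_region, tie_flag, fc_vs_rest, F, df1, df2, p, p_adj,
#'   testable, call, plus region-mean columns `mean_<region>`); attribute
#'   `consensus` holds the `consensus_correlation` when blocking was used.
#' @export
call_region_specific <- function(matrix, annotations,
                                 config = analysis_config()) {
  stopifnot(matrix_stage(matrix) == "log2ppm")
  ann <- .match_annotations(matrix, annotations)
  v <- .unwrap(matrix)
  st <- region_stats(matrix, annotations)

  consensus <- NULL
  rho <- 0
  if (config$blocking == "blocked") {
    consensus <- estimate_consensus_correlation(matrix, annotations, config)
    rho <- consensus$rho_consensus
  }

  np <- nrow(v)
  Fv <- df1 <- df2 <- pv <- rep(NA_real_, np)
  n_reg_obs <- rowSums(st$counts > 0, na.rm = TRUE)
  testable <- n_reg_obs >= config$min_testable_regions
  for (i in which(testable)) {
    obs <- which(!is.na(v[i, ]))
    if (length(obs) - n_reg_obs[i] < 1) { testable[i] <- FALSE; next }
    res <- blocked_anova_f(v[i, obs], ann[obs, , drop = FALSE], rho)
    Fv[i] <- res$F; df1[i] <- res$df1; df2[i] <- res$df2; pv[i] <- res$p
  }
  p_adj <- benjamini_hochberg(ifelse(testable, pv, NA_real_))

  fc <- fold_change_vs_rest(st, matrix, annotations, config$fc_scale)
  call <- testable & !is.na(p_adj) & p_adj < config$alpha &
    !is.na(fc$fc_vs_rest) & fc$fc_vs_rest >= config$fc_threshold &
    fc$n_max_region >= config$min_obs_max_region

  out <- data.frame(protein_id = fc$protein_id, max_region = fc$max_region,
                    tie_flag = fc$tie_flag, fc_vs_rest = fc$fc_vs_rest,
                    F = Fv, df1 = df1, df2 = df2, p = pv, p_adj = p_adj,
                    testable = testable, call = call,
                    stringsAsFactors = FALSE, row.names = NULL)
  mcols <- as.data.frame(st$means)
  names(mcols) <- paste0("mean_", st$regions)
  out <- cbind(out, mcols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "consensus") <- consensus
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' Top-k called proteins per region
#'
#' Called proteins of each region ranked by fold change (descending, ties by
#' protein id), truncated to `k` — the per-region signature lists.
#'
#' @param table A `specificity_table` from [call_region_specific()].
#' @param k Maximum proteins per region.
#' @return Data frame: region, rank, protein_id, fc_vs_rest, p_adj.
#' @export
top_k_per_region <- function(table, k = 13L) {
  called <- table[table$call, , drop = FALSE]
  out <- lapply(intersect(region_codes(), unique(called$max_region)),
                function(r) {
    sub <- called[called$max_region == r, , drop = FALSE]
    sub <- sub[order(-sub$fc_vs_rest, sub$protein_id), , drop = FALSE]
    sub <- utils::head(sub, k)
    data.frame(region = r, rank = seq_len(nrow(sub)),
               protein_id = sub$protein_id, fc_vs_rest = sub$fc_vs_rest,
               p_adj = sub$p_adj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(region = character(0), rank = integer(0),
                      protein_id = character(0), fc_vs_rest = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Proteins elevated in all four cortical lobes
#'
#' A protein belongs to the shared cortical signature when, for each of FL,
#' TL, PL and OL separately, its lobe mean exceeds the pooled mean over the
#' nine noncortical regions by at least `fc_threshold` (as a linear ratio on
#' geometric means), and its overall region ANOVA BH-adjusted p is below
#' `alpha`.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @param config An [analysis_config()].
#' @param spec_table Optional precomputed [call_region_specific()] table
#'   (avoids refitting).
#' @return Data frame: protein_id, fc_FL, fc_TL, fc_PL, fc_OL, p_adj,
#'   in_signature.
#' @export
lobe_shared_signature <- function(matrix, annotations,
                                  config = analysis_config(),
                                  spec_table = NULL) {
  lobes <- framework_groups()$lobes
  ann <- .match_annotations(matrix, annotations)
  present <- unique(as.character(ann$region))
  if (!all(lobes %in% present))
    stop("design lacks lobe(s): ",
         paste(setdiff(lobes, present), collapse = ", "), call. = FALSE)
  noncortical <- setdiff(region_codes(), lobes)
  if (!any(present %in% noncortical))
    stop("design has no noncortical region", call. = FALSE)
  if (is.null(spec_table))
    spec_table <- call_region_specific(matrix, annotations, config)

  v <- .unwrap(matrix)
  st <- region_stats(matrix, annotations)
  nc_cols <- which(as.character(ann$region) %in% noncortical)
  nc_mean <- rowMeans(v[, nc_cols, drop = FALSE], na.rm = TRUE)

  fcs <- sapply(lobes, function(L) 2^(st$means[, L] - nc_mean))
  colnames(fcs) <- paste0("fc_", lobes)
  ok <- rowSums(fcs >= config$fc_threshold, na.rm = TRUE) == length(lobes) &
    rowSums(is.na(fcs)) == 0
  p_adj <- spec_table$p_adj[match(rownames(v), spec_table$protein_id)]
  sig <- ok & !is.na(p_adj) & p_adj < config$alpha
  out <- data.frame(protein_id = rownames(v), fcs, p_adj = p_adj,
                    in_signature = sig, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}
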