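test_that("region stats match a per-cell loop oracle", {
  set.seed(15)
  regions <- c("FL", "TL", "CB", "HIP")
  ann <- make_annotations(regions, 5)
  v <- matrix(rnorm(50 * nrow(ann), 10, 2), 50, nrow(ann),
              dimnames = list(paste0("p", 1:50), ann$sample_id))
  v[sample(length(v), 200)] <- NA
  m <- abundance_matrix(v, "log2ppm")
  st <- region_stats(m, ann)
  for (r in regions) {
    cols <- ann$sample_id[ann$region == r]
    for (i in c(1, 17, 50)) {
      x <- v[i, cols]
      expect_equal(unname(st$counts[i, r]), sum(!is.na(x)))
      if (any(!is.na(x)))
        expect_equal(unname(st$means[i, r]), mean(x, na.rm = TRUE))
      else expect_true(is.na(st$means[i, r]))
    }
  }
  # simple forced case: region with samples {2, 4}
  ann2 <- make_annotations(c("FL", "TL"), 2)
  m2 <- make_log2_matrix(c(2, 4, 1, 3), "p1"[1], ann2$sample_id)
  # sample order: d1_FL d2_FL d1_TL d2_TL
  st2 <- region_stats(m2, ann2)
  expect_equal(unname(st2$means["p1", "FL"]), 3)
  expect_equal(unname(st2$counts["p1", "FL"]), 2)
})

test_that("blocked ANOVA with rho 0 reproduces the textbook one-way F", {
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    donor_id = paste0("d", 1:4),
                    region = c("FL", "FL", "TL", "TL"))
  res <- blocked_anova_f(c(1, 2, 3, 4), ann, rho = 0)
  expect_equal(res$F, 8)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 2L)
  expect_equal(res$p, 0.1056, tolerance = 1e-3)

  set.seed(33)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    n_per <- sample(2:4, k, replace = TRUE)
    reg <- rep(region_codes()[seq_len(k)], n_per)
    n <- length(reg)
    ann <- data.frame(sample_id = paste0("s", 1:n),
                      donor_id = paste0("d", 1:n), region = reg)
    y <- rnorm(n)
    got <- blocked_anova_f(y, ann, rho = 0)
    want <- oneway_f_oracle(y, reg)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df1, want$df1)
    expect_equal(got$df2, want$df2)
  }
})

test_that("blocked ANOVA handles degenerate and invalid inputs", {
  ann <- data.frame(sample_id = paste0("s", 1:4),
                    donor_id = c("d1", "d1", "d2", "d2"),
                    region = c("FL", "TL", "FL", "TL"))
  res <- blocked_anova_f(rep(3, 4), ann, rho = 0.4)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(blocked_anova_f(1:4, ann, rho = 1.2), "outside")
  expect_error(blocked_anova_f(1:4, ann, rho = -1), "outside")
})

test_that("blocked F is affine invariant on the log2 scale", {
  set.seed(44)
  ann <- make_annotations(c("FL", "TL", "CB"), 4)
  y <- rnorm(nrow(ann))
  base <- blocked_anova_f(y, ann, rho = 0.3)
  shifted <- blocked_anova_f(y + 5, ann, rho = 0.3)
  scaled <- blocked_anova_f(y * 3, ann, rho = 0.3)
  expect_equal(shifted$F, base$F, tolerance = 1e-10)
  expect_equal(scaled$F, base$F, tolerance = 1e-10)
})

test_that("whitening makes the F test exact under donor correlation", {
  # analytic check: at rho > 0 the whitened one-way F of compound-symmetric
  # data is F-distributed; empirical null rejection near nominal level
  set.seed(55)
  ann <- make_annotations(c("FL", "TL", "CB", "HIP"), 6)
  rho <- 0.5
  nd <- length(unique(ann$donor_id))
  rej <- 0; n_rep <- 400
  for (i in seq_len(n_rep)) {
    d <- rnorm(nd, 0, sqrt(rho))
    y <- d[match(ann$donor_id, unique(ann$donor_id))] +
      rnorm(nrow(ann), 0, sqrt(1 - rho))
    res <- blocked_anova_f(y, ann, rho = rho)
    if (res$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.03)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.1, 1.4)), "0, 1")

  set.seed(66)
  for (i in 1:250) {
    p <- runif(sample(1:30, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-14)
    # independent cross-check against the stock implementation
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # missing entries are preserved and excluded from m
  p <- c(0.01, NA, 0.02, 0.03, NA)
  got <- benjamini_hochberg(p)
  expect_true(all(is.na(got[c(2, 5)])))
  expect_equal(got[!is.na(p)], bh_oracle(p[!is.na(p)]))
})

test_that("BH output bounds and monotonicity hold", {
  set.seed(77)
  for (i in 1:50) {
    p <- runif(20)
    a <- benjamini_hochberg(p)
    expect_true(all(a >= p - 1e-15) && all(a <= 1))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-15))
  }
})

test_that("consensus correlation recovers the planted intra-donor rho", {
  for (sds in list(c(0, 0.5, 0), c(0.5, 0.5, 0.5))) {
    p <- generator_params(n_proteins = 2000, markers_per_region = 0,
                          donor_sd = sds[1], resid_sd = sds[2], seed = 11)
    ds <- generate_proteome_dataset(p)
    lg <- log2_transform(to_ppm(ds$matrix))
    cc <- estimate_consensus_correlation(lg, ds$annotations)
    expect_lt(abs(cc$rho_consensus - sds[3]), 0.05)
    expect_lte(cc$n_used, 2000)
  }
})

test_that("consensus correlation agrees with an independent REML fit", {
  skip_if_not_installed("limma")
  skip_if_not_installed("statmod")
  p <- generator_params(n_proteins = 1500, markers_per_region = 0,
                        donor_sd = 0.4, resid_sd = 0.4, mcar_rate = 0,
                        mnar_scale = 0, n_drop_cells = 0, seed = 23)
  ds <- generate_proteome_dataset(p)
  lg <- log2_transform(to_ppm(ds$matrix))
  cc <- estimate_consensus_correlation(lg, ds$annotations)
  v <- unclass(lg); attr(v, "stage") <- NULL
  design <- stats::model.matrix(~ 0 + region, data = ds$annotations)
  dc <- limma::duplicateCorrelation(v, design, block = ds$annotations$donor_id)
  expect_lt(abs(cc$rho_consensus - dc$consensus.correlation), 0.05)
})

test_that("a zero-residual protein is excluded from the consensus pool", {
  p <- generator_params(n_proteins = 200, markers_per_region = 0,
                        donor_sd = 0.3, resid_sd = 0.4, mcar_rate = 0,
                        mnar_scale = 0, n_drop_cells = 0, seed = 3)
  ds <- generate_proteome_dataset(p)
  lg <- log2_transform(to_ppm(ds$matrix))
  v <- unclass(lg); attr(v, "stage") <- NULL
  v[1, ] <- 10  # constant protein: zero residuals everywhere
  lg <- abundance_matrix(v, "log2ppm")
  cc <- estimate_consensus_correlation(lg, ds$annotations)
  expect_true(is.na(cc$rho_per_protein[1]))
  expect_equal(cc$n_used, 199L)
})

test_that("fold change picks the top region with the documented tie rule", {
  ann <- make_annotations(c("FL", "TL", "CB"), 2)
  # protein 1: FL mean 4, rest pooled mean 3 -> fc 2
  # protein 2: FL and TL tie at 5, CB lower -> tie flag, FL chosen
  v <- rbind(p1 = c(4, 4, 3.5, 2.5, 3.5, 2.5),
             p2 = c(5, 5, 5, 5, 1, 1))
  # sample order is d1_FL d2_FL d1_TL d2_TL d1_CB d2_CB
  ann <- ann[order(match(ann$region, c("FL", "TL", "CB")), ann$donor_id), ]
  colnames(v) <- ann$sample_id
  m <- abundance_matrix(v, "log2ppm")
  st <- region_stats(m, ann)
  fc <- fold_change_vs_rest(st, m, ann)
  expect_equal(fc$max_region, c("FL", "FL"))
  expect_equal(fc$tie_flag, c(FALSE, TRUE))
  expect_equal(fc$fc_vs_rest[1], 2)

  # a protein observed in one region only is not computable
  v2 <- rbind(p1 = c(1, 2, NA, NA, NA, NA))
  colnames(v2) <- ann$sample_id
  st2 <- region_stats(abundance_matrix(v2, "log2ppm"), ann)
  fc2 <- fold_change_vs_rest(st2, abundance_matrix(v2, "log2ppm"), ann)
  expect_true(is.na(fc2$fc_vs_rest[1]))
})

test_that("noise-free planted markers are called exactly, each in its region", {
  p <- noise_free_params(n_proteins = 120, markers_per_region = 2,
                         log2_effect = 2, seed = 12)
  ds <- generate_proteome_dataset(p)
  # depth is flat, so the raw values are exact powers of the log2 signal;
  # log2(raw) is the per-sample-comparable scale without the compositional
  # shift a marker imposes on its own region's ppm denominator
  lg <- abundance_matrix(log2(unclass(ds$matrix)), "log2ppm")
  cfg <- analysis_config(blocking = "oneway")
  tab <- call_region_specific(lg, ds$annotations, cfg)
  called <- tab$protein_id[tab$call]
  planted <- ds$truth$protein_id[ds$truth$is_marker]
  expect_setequal(called, planted)
  idx <- match(planted, tab$protein_id)
  expect_equal(tab$max_region[idx],
               ds$truth$marker_region[ds$truth$is_marker])
  expect_equal(tab$fc_vs_rest[idx], rep(4, length(idx)), tolerance = 1e-9)
})

test_that("calls are anti-monotone in the fold-change and alpha thresholds", {
  p <- generator_params(n_proteins = 600, markers_per_region = 5,
                        log2_effect = 1, seed = 14)
  ds <- generate_proteome_dataset(p)
  lg <- log2_transform(to_ppm(ds$matrix))
  base <- call_region_specific(lg, ds$annotations, analysis_config())
  tighter_fc <- call_region_specific(lg, ds$annotations,
                                     analysis_config(fc_threshold = 2.5))
  tighter_a <- call_region_specific(lg, ds$annotations,
                                    analysis_config(alpha = 0.001))
  expect_true(all(tighter_fc$call <= base$call))
  expect_true(all(tighter_a$call <= base$call))
})

test_that("top-k per region ranks by fold change with id tie-break", {
  tab <- data.frame(protein_id = c("pB", "pA", "pC", "pD"),
                    max_region = c("FL", "FL", "FL", "TL"),
                    fc_vs_rest = c(3, 3, 5, 2),
                    p_adj = c(0.001, 0.001, 0.001, 0.001),
                    call = c(TRUE, TRUE, TRUE, TRUE))
  top <- top_k_per_region(tab, k = 13)
  fl <- top[top$region == "FL", ]
  expect_equal(fl$protein_id, c("pC", "pA", "pB"))
  expect_equal(nrow(top[top$region == "TL", ]), 1L)
  top2 <- top_k_per_region(tab, k = 2)
  expect_equal(nrow(top2[top2$region == "FL", ]), 2L)
})

test_that("planted fold-change ordering is reproduced in the signatures", {
  p <- noise_free_params(n_proteins = 60, markers_per_region = 0, seed = 2)
  ds <- generate_proteome_dataset(p)
  v <- unclass(ds$matrix); attr(v, "stage") <- NULL
  fl <- as.character(ds$annotations$region) == "FL"
  v["P00010", fl] <- v["P00010", fl] * 2^3
  v["P00020", fl] <- v["P00020", fl] * 2^2
  v["P00030", fl] <- v["P00030", fl] * 2^1
  lg <- log2_transform(to_ppm(abundance_matrix(v, "raw")))
  tab <- call_region_specific(lg, ds$annotations,
                              analysis_config(blocking = "oneway"))
  top <- top_k_per_region(tab, k = 13)
  fl_top <- top[top$region == "FL", ]
  expect_equal(fl_top$protein_id, c("P00010", "P00020", "P00030"))
})

test_that("four-lobe shared signature requires elevation in every lobe", {
  p <- noise_free_params(n_proteins = 80, markers_per_region = 0, seed = 9)
  ds <- generate_proteome_dataset(p)
  v <- unclass(ds$matrix); attr(v, "stage") <- NULL
  reg <- as.character(ds$annotations$region)
  lobes <- framework_groups()$lobes
  v[1, reg %in% lobes] <- v[1, reg %in% lobes] * 2^2          # all four
  v[2, reg %in% lobes[1:3]] <- v[2, reg %in% lobes[1:3]] * 2^2 # three only
  lg <- log2_transform(to_ppm(abundance_matrix(v, "raw")))
  sig <- lobe_shared_signature(lg, ds$annotations,
                               analysis_config(blocking = "oneway"))
  expect_true(sig$in_signature[1])
  expect_false(sig$in_signature[2])
})

test_that("four-lobe signature recovery on a planted simulation", {
  p <- generator_params(n_proteins = 2000, markers_per_region = 0,
                        resid_sd = 0.4, donor_sd = 0.3, seed = 28)
  ds <- generate_proteome_dataset(p)
  v <- unclass(ds$matrix); attr(v, "stage") <- NULL
  reg <- as.character(ds$annotations$region)
  lobes <- framework_groups()$lobes
  # plant into well-observed proteins: elevating a value post hoc cannot
  # rescue cells the left-censoring mechanism already removed, whereas a
  # genuinely abundant protein would not have been censored
  planted <- which(rowMeans(is.na(v)) < 0.2)[1:20]
  v[planted, reg %in% lobes] <- v[planted, reg %in% lobes] * 2^2
  lg <- log2_transform(to_ppm(abundance_matrix(v, "raw")))
  sig <- lobe_shared_signature(lg, ds$annotations)
  hits <- which(sig$in_signature)
  expect_true(all(planted %in% hits))
  expect_lte(length(setdiff(hits, planted)), 1L)
})
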