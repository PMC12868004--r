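# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (loops, direct definitions) and
# share no code with the implementation they check.

# step-up FDR by the raw definition: adj_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# textbook one-way ANOVA F
oneway_f_oracle <- function(values, groups) {
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    y <- values[groups == g]
    ssb <- ssb + length(y) * (mean(y) - gm)^2
    ssw <- ssw + sum((y - mean(y))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

# a small annotation frame: one sample per donor x region
make_annotations <- function(regions, n_donors) {
  g <- expand.grid(donor_id = paste0("d", seq_len(n_donors)),
                   region = regions, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(g$donor_id, g$region, sep = "_"),
             donor_id = g$donor_id, region = g$region,
             stringsAsFactors = FALSE)
}

# a log2ppm-stage matrix straight from numbers (bypasses normalization)
make_log2_matrix <- function(values, proteins, samples) {
  m <- matrix(values, nrow = length(proteins),
              dimnames = list(proteins, samples))
  abundance_matrix(m, stage = "log2ppm")
}

# noise-free generator settings: exact arithmetic downstream
noise_free_params <- function(...) {
  generator_params(donor_sd = 0, resid_sd = 0, depth_spread = 0,
                   mcar_rate = 0, mnar_scale = 0, n_drop_cells = 0, ...)
}
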