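#' Normalize a raw matrix to parts per million
#'
#' Each sample's observed values are divided by that sample's observed total
#' and multiplied by 10^6, making samples of different total signal
#' comparable. Missing values are preserved; the denominator sums observed
#' proteins only.
#'
#' @param matrix A raw [abundance_matrix()].
#' @return A ppm-stage `abundance_matrix`.
#' @export
to_ppm <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix_stage(matrix) != "raw")
    stop("to_ppm expects a raw-stage matrix", call. = FALSE)
  v <- .unwrap(matrix)
  totals <- colSums(v, na.rm = TRUE)
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[empty], collapse = ", "), call. = FALSE)
  out <- sweep(v, 2, totals, "/") * 1e6
  abundance_matrix(out, stage = "ppm")
}

#' Log2-transform a ppm matrix
#'
#' @param matrix A ppm-stage [abundance_matrix()].
#' @return A log2ppm-stage `abundance_matrix`.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix_stage(matrix) != "ppm")
    stop("log2_transform expects a ppm-stage matrix", call. = FALSE)
  v <- .unwrap(matrix)
  if (any(v <= 0, na.rm = TRUE))
    stop("nonpositive value in ppm matrix", call. = FALSE)
  out <- log2(v)
  structure(out, stage = "log2ppm",
            class = c("abundance_matrix", "matrix", "array"))
}

#' Quality-control summaries
#'
#' Per-sample raw totals and observed-protein counts, per-protein missing
#' fractions, per-protein-per-region coefficients of variation on the linear
#' ppm scale, per-region identified-protein counts and log10 dynamic range,
#' and the global median protein missing fraction.
#'
#' @param raw Raw-stage [abundance_matrix()].
#' @param ppm Matching ppm-stage matrix (from [to_ppm()]).
#' @param annotations Sample annotations.
#' @return List of class `qc_report` with elements `samples`, `proteins`,
#'   `cv` (long data.frame protein x region), `regions`,
#'   `median_missing_fraction`.
#' @export
qc_report <- function(raw, ppm, annotations) {
  stopifnot(matrix_stage(raw) == "raw", matrix_stage(ppm) == "ppm",
            identical(dimnames(raw), dimnames(ppm)))
  ann <- .match_annotations(raw, annotations)
  rawv <- .unwrap(raw); ppmv <- .unwrap(ppm)

  samples <- data.frame(
    sample_id = colnames(rawv),
    raw_total = colSums(rawv, na.rm = TRUE),
    n_observed = colSums(!is.na(rawv)),
    stringsAsFactors = FALSE, row.names = NULL)

  prot_miss <- rowMeans(is.na(rawv))
  proteins <- data.frame(protein_id = rownames(rawv),
                         missing_fraction = prot_miss,
                         stringsAsFactors = FALSE, row.names = NULL)

  regs <- levels(droplevels(ann$region))
  cv_list <- vector("list", length(regs))
  region_rows <- vector("list", length(regs))
  for (k in seq_along(regs)) {
    cols <- which(as.character(ann$region) == regs[k])
    sub <- ppmv[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    sq <- rowSums(sub^2, na.rm = TRUE)
    s2 <- (sq - n * m^2) / pmax(n - 1, 1)
    cv <- ifelse(n >= 2, sqrt(pmax(s2, 0)) / m, NA_real_)
    cv_list[[k]] <- data.frame(protein_id = rownames(ppmv), region = regs[k],
                               n_obs = n, cv = cv, stringsAsFactors = FALSE)
    obs <- sub[!is.na(sub)]
    region_rows[[k]] <- data.frame(
      region = regs[k],
      n_identified = sum(rowSums(!is.na(sub)) > 0),
      dynamic_range_log10 = if (length(obs) > 0)
        log10(max(obs) / min(obs)) else NA_real_,
      stringsAsFactors = FALSE)
  }

  structure(list(samples = samples, proteins = proteins,
                 cv = do.call(rbind, cv_list),
                 regions = do.call(rbind, region_rows),
                 median_missing_fraction = stats::median(prot_miss)),
            class = "qc_report")
}

#' Complete-case PCA of samples
#'
#' Restricts to proteins observed in every sample, centers each protein
#' across samples, and projects samples onto the top right-singular
#' directions. No imputation is performed.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param n_components Number of axes to return.
#' @return List of class `pca_result` with `scores` (samples x components)
#'   and `explained_variance` (fractions, nonincreasing).
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  stopifnot(matrix_stage(matrix) == "log2ppm", ncol(matrix) >= 2)
  v <- .unwrap(matrix)
  complete <- rowSums(is.na(v)) == 0
  if (sum(complete) < 2)
    stop("fewer than 2 proteins observed in all samples; ",
         "imputation is out of scope, filter samples instead", call. = FALSE)
  x <- v[complete, , drop = FALSE]
  x <- x - rowMeans(x)                    # center each protein
  n_components <- min(n_components, nrow(x), ncol(x))
  sv <- svd(t(x), nu = n_components, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- colnames(v)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(n_components)]),
            class = "pca_result")
}
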