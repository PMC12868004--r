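#' Region x protein mean-profile matrix
#'
#' Per-region mean log2 ppm per protein over observed samples; cells with no
#' observation are missing.
#'
#' @param matrix A log2ppm-stage [abundance_matrix()].
#' @param annotations Sample annotations.
#' @return Numeric matrix, regions (declaration order) x proteins.
#' @export
region_profile_matrix <- function(matrix, annotations) {
  st <- region_stats(matrix, annotations)
  if (length(st$regions) < 2) stop("need >= 2 regions", call. = FALSE)
  t(st$means)
}

#' Region-region Pearson correlation
#'
#' Pairwise-complete Pearson correlation between region mean profiles; the
#' number of proteins shared by each pair is recorded so the
#' pairwise-complete choice is auditable.
#'
#' @param profiles Region x protein matrix from [region_profile_matrix()].
#' @param min_shared Minimum proteins with both means present per pair.
#' @return List of class `region_correlation`: `r` (symmetric, unit
#'   diagonal), `n_pairs`, `regions`.
#' @export
region_correlation <- function(profiles, min_shared = 3L) {
  obs <- !is.na(profiles)
  n_pairs <- obs %*% t(obs)
  off <- n_pairs; diag(off) <- Inf
  if (any(off < min_shared)) {
    bad <- which(off < min_shared, arr.ind = TRUE)[1, ]
    stop(sprintf("region pair (%s, %s) shares only %d proteins (min %d)",
                 rownames(profiles)[bad[1]], rownames(profiles)[bad[2]],
                 n_pairs[bad[1], bad[2]], min_shared), call. = FALSE)
  }
  r <- stats::cor(t(profiles), use = "pairwise.complete.obs")
  diag(r) <- 1
  structure(list(r = r, n_pairs = n_pairs, regions = rownames(profiles)),
            class = "region_correlation")
}

#' Complete-linkage clustering on correlation distance
#'
#' Agglomerates regions on distance `d = 1 - r` with complete linkage. At
#' each step the pair with the smallest inter-cluster distance is merged;
#' ties are broken deterministically by the smallest leaf index (then the
#' smallest partner index). Merge heights are nondecreasing.
#'
#' @param corr A [region_correlation()] result (or a symmetric correlation
#'   matrix).
#' @param config An [analysis_config()] (distance/linkage flavour check).
#' @return List of class `region_dendrogram`: `merges` (data.frame node_a,
#'   node_b, height; negative entries are leaf indices, positive entries
#'   earlier merges, hclust convention) and `leaves` (region labels).
#' @export
hierarchical_cluster <- function(corr, config = analysis_config()) {
  r <- if (inherits(corr, "region_correlation")) corr$r else corr
  stopifnot(isSymmetric(unname(r)), config$distance == "pearson",
            config$linkage == "complete")
  d <- 1 - r
  n <- nrow(d)
  leaves <- rownames(d)
  active <- seq_len(n)                 # indices into cluster list
  members <- as.list(seq_len(n))       # leaf sets
  node_id <- -seq_len(n)               # hclust convention
  merges <- data.frame(node_a = integer(n - 1), node_b = integer(n - 1),
                       height = numeric(n - 1))
  # inter-cluster distance matrix (complete linkage), grows by merging
  D <- d
  diag(D) <- Inf
  min_leaf <- seq_len(n)               # smallest leaf index per cluster
  for (step in seq_len(n - 1)) {
    live <- which(!is.na(min_leaf))
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    best_lo <- Inf; best_hi <- Inf
    for (ai in seq_along(live)) {
      for (bi in seq_along(live)) {
        if (bi <= ai) next
        a <- live[ai]; b <- live[bi]
        dv <- D[a, b]
        lo <- min(min_leaf[a], min_leaf[b]); hi <- max(min_leaf[a], min_leaf[b])
        take <- dv < best_d - 1e-12 ||
          (abs(dv - best_d) <= 1e-12 &&
           (lo < best_lo || (lo == best_lo && hi < best_hi)))
        if (take) {
          best <- c(a, b); best_d <- dv; best_lo <- lo; best_hi <- hi
        }
      }
    }
    a <- best[1]; b <- best[2]
    merges$node_a[step] <- node_id[a]; merges$node_b[step] <- node_id[b]
    merges$height[step] <- best_d
    # complete linkage update: new cluster lives in slot a
    D[a, ] <- pmax(D[a, ], D[b, ]); D[, a] <- D[a, ]
    D[a, a] <- Inf
    D[b, ] <- Inf; D[, b] <- Inf
    members[[a]] <- c(members[[a]], members[[b]])
    min_leaf[a] <- min(min_leaf[a], min_leaf[b])
    min_leaf[b] <- NA_integer_
    node_id[a] <- step; node_id[b] <- NA_integer_
  }
  structure(list(merges = merges, leaves = leaves),
            class = "region_dendrogram")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; since complete-linkage heights are
#' nondecreasing this keeps the first n-k merges.
#'
#' @param dend A [hierarchical_cluster()] result.
#' @param k Number of flat clusters.
#' @return Named integer vector, leaf -> cluster id.
#' @export
cut_dendrogram <- function(dend, k) {
  n <- length(dend$leaves)
  stopifnot(k >= 1, k <= n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- seq_len(n - k)
  merge_rep <- integer(nrow(dend$merges))  # leaf representative per merge
  for (s in keep) {
    a <- dend$merges$node_a[s]; b <- dend$merges$node_b[s]
    ra <- if (a < 0) find(-a) else find(merge_rep[a])
    rb <- if (b < 0) find(-b) else find(merge_rep[b])
    parent[rb] <- ra
    merge_rep[s] <- ra
  }
  # also record representatives of unmerged nodes for completeness
  if (n - k < nrow(dend$merges)) {
    for (s in seq(n - k + 1, nrow(dend$merges))) {
      a <- dend$merges$node_a[s]
      merge_rep[s] <- if (a < 0) -a else merge_rep[a]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- as.integer(factor(roots, levels = unique(roots)))
  stats::setNames(cl, dend$leaves)
}

#' Compare a dendrogram cut with the expected region groups
#'
#' Cuts the dendrogram into `k` clusters and flags each expected group
#' ([framework_groups()]) as co-clustered iff all its members share one
#' cluster.
#'
#' @param dend A [hierarchical_cluster()] result.
#' @param k Cut count (default 4).
#' @return Data frame: group, members, evaluable, co_clustered; attribute
#'   `n_recovered`.
#' @export
compare_to_framework <- function(dend, k = 4L) {
  cl <- cut_dendrogram(dend, k)
  groups <- framework_groups()
  rows <- lapply(names(groups), function(g) {
    mem <- groups[[g]]
    evaluable <- all(mem %in% names(cl))
    co <- if (evaluable) length(unique(cl[mem])) == 1 else NA
    data.frame(group = g, members = paste(mem, collapse = ","),
               evaluable = evaluable, co_clustered = co,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_recovered") <- sum(out$co_clustered %in% TRUE)
  out
}
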