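#' Read a wide protein-abundance table
#'
#' Tab-separated UTF-8 with header; first column `protein_id`, remaining
#' columns one per sample. Empty cells or literal `NA` are missing. In a raw
#' matrix, zeros are the non-detection convention of label-free DIA output
#' and are coerced to missing (a message reports the count).
#'
#' @param path TSV file path.
#' @param stage Declared processing stage of the values.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, stage = c("raw", "ppm", "log2ppm")) {
  stage <- match.arg(stage)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = c("", "NA"), colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || names(tab)[1] != "protein_id")
    stop("abundance table must start with a 'protein_id' column", call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate protein_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  samples <- names(tab)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample column: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- tab[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad) > 0)
      stop(sprintf("non-numeric cell '%s' at row %d (protein %s), column '%s'",
                   cell[bad[1]], bad[1], ids[bad[1]], samples[j]), call. = FALSE)
    vals[, j] <- num
  }
  if (stage == "raw") {
    zeros <- which(vals == 0)
    if (length(zeros) > 0) {
      vals[zeros] <- NA_real_
      message(length(zeros), " zero value(s) in raw matrix coerced to missing",
              " (below-detection convention)")
    }
  }
  abundance_matrix(vals, stage = stage)
}

#' Read sample annotations
#'
#' Tab-separated with header `sample_id`, `donor_id`, `region`; region labels
#' may use the slash aliases (`THA/HT`, `OB/OT`).
#'
#' @param path TSV file path.
#' @return Data frame of validated annotations.
#' @export
read_sample_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_sample_annotation(tab)
}

#' Read a gene x region nTPM table
#'
#' Tab-separated; first column `gene_id`, remaining columns RNA-side region
#' labels (e.g. Cx, CB, BS, HIP, THA_HT). Cells are nonnegative nTPM values;
#' empty cells are missing.
#'
#' @param path TSV file path.
#' @return List with `gene_ids`, `region_labels` and numeric matrix `ntpm`.
#' @export
read_rna_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("RNA table must start with a 'gene_id' column", call. = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene_id", call. = FALSE)
  labs <- names(tab)[-1]
  if (anyDuplicated(labs)) stop("duplicate region label", call. = FALSE)
  ntpm <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(ntpm) <- "double"
  rownames(ntpm) <- ids
  if (any(ntpm < 0, na.rm = TRUE))
    stop("negative nTPM value(s); nTPM must be >= 0", call. = FALSE)
  rna_table(ntpm)
}

#' Construct an RNA table from an nTPM matrix
#'
#' @param ntpm Nonnegative numeric matrix, genes x RNA-side regions.
#' @return List of class `rna_table`.
#' @export
rna_table <- function(ntpm) {
  stopifnot(is.matrix(ntpm), !is.null(rownames(ntpm)), !is.null(colnames(ntpm)))
  if (any(ntpm < 0, na.rm = TRUE)) stop("nTPM must be >= 0", call. = FALSE)
  structure(list(gene_ids = rownames(ntpm),
                 region_labels = colnames(ntpm),
                 ntpm = ntpm),
            class = "rna_table")
}

#' Read a protein-to-gene identifier map
#'
#' Tab-separated with header `protein_id`, `gene_id`; each protein maps to at
#' most one gene.
#'
#' @param path TSV file path.
#' @return Data frame with columns `protein_id`, `gene_id`.
#' @export
read_id_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("protein_id", "gene_id") %in% names(tab)))
    stop("id map needs columns protein_id, gene_id", call. = FALSE)
  if (anyDuplicated(tab$protein_id))
    stop("duplicate protein_id in id map", call. = FALSE)
  tab[c("protein_id", "gene_id")]
}

# Internal: render a data.frame to TSV text with numbers at 15 significant
# digits so a read-back round-trips to >= 12 significant digits.
.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.15g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    } else if (is.factor(out[[j]])) {
      out[[j]] <- as.character(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

#' Write result tables and a run manifest
#'
#' Each named data.frame is written as `<name>.tsv` under `out_dir` with a
#' stable column order; numbers carry 15 significant digits so values
#' round-trip. A `manifest.txt` lists every file with its MD5, the config
#' hash and the seed. Reruns on identical inputs produce byte-identical TSVs
#' (the manifest's timestamp line is the only varying output).
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config An [analysis_config()] (hashed into the manifest).
#' @return Invisibly, a data.frame manifest (file, md5).
#' @export
write_results <- function(tables, out_dir, config = analysis_config()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(as.data.frame(tables[[nm]]), f)
    files <- c(files, f)
  }
  hashes <- unname(tools::md5sum(files))
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file), add = TRUE)
  writeLines(paste(names(config),
                   vapply(config, function(v) paste(format(v, digits = 15),
                                                    collapse = ","),
                          character(1)), sep = "="), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  manifest <- data.frame(file = basename(files), md5 = hashes,
                         stringsAsFactors = FALSE)
  man_path <- file.path(out_dir, "manifest.txt")
  lines <- c(paste0("# run manifest (", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ")"),
             paste0("config_hash\t", cfg_hash),
             paste0("seed\t", config$seed),
             paste(manifest$file, manifest$md5, sep = "\t"))
  writeLines(lines, man_path)
  invisible(manifest)
}
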