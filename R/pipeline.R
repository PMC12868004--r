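# Orchestration shared by the CLI script and programmatic runs. The CLI at
# inst/cli/brainprot.R is a thin wrapper around run_pipeline().

# Internal: wide data.frame form of an abundance matrix for writing.
.matrix_to_df <- function(m) {
  df <- as.data.frame(.unwrap(m))
  cbind(protein_id = rownames(m), df, stringsAsFactors = FALSE)
}

# Internal: tiny long-option parser: --flag value or bare switches.
.parse_argv <- function(argv, switches = c("--verbose")) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("usage: unexpected argument '", a, "'", call. = FALSE)
    key <- sub("^--", "", a)
    if (a %in% switches) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      if (i == length(argv))
        stop("usage: flag ", a, " needs a value", call. = FALSE)
      out[[key]] <- argv[i + 1]
      i <- i + 2
    }
  }
  out
}

.need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0)
    stop("usage: missing required flag(s): ",
         paste0("--", miss, collapse = ", "), call. = FALSE)
}

.log_line <- function(verbose, ...) {
  if (isTRUE(verbose)) message("[brainprotmap] ", ...)
}

# Internal: load matrix + annotations named by opts.
.load_inputs <- function(opts) {
  .need(opts, c("matrix", "samples"))
  list(matrix = read_abundance_matrix(opts$matrix, stage = "raw"),
       annotations = read_sample_annotations(opts$samples))
}

#' Run a pipeline stage from parsed command-line style arguments
#'
#' Subcommands: `simulate`, `normalize`, `qc`, `specificity`, `quartiles`,
#' `modules`, `crossomics`, `evaluate`, `run-all`. Common flags: `--matrix`,
#' `--samples`, `--out` (required), `--config` (YAML, optional), `--seed`,
#' `--verbose`; `crossomics`/`run-all` accept `--rna` and `--idmap`,
#' `evaluate` requires `--truth`. All outputs are TSVs under `--out` plus a
#' run manifest; reruns with identical inputs and seed are byte-identical.
#'
#' @param argv Character vector: subcommand followed by flags, as from
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, a list with `status` (0 ok, 1 run error, 2 usage
#'   error) and `manifest` (data.frame of written files, NULL on error).
#' @export
run_pipeline <- function(argv) {
  res <- tryCatch({
    if (length(argv) < 1)
      stop("usage: brainprot <subcommand> [--flags]; subcommands: ",
           "simulate normalize qc specificity quartiles modules ",
           "crossomics evaluate run-all", call. = FALSE)
    sub <- argv[1]
    known <- c("simulate", "normalize", "qc", "specificity", "quartiles",
               "modules", "crossomics", "evaluate", "run-all")
    if (!sub %in% known)
      stop("usage: unknown subcommand '", sub, "'", call. = FALSE)
    opts <- .parse_argv(argv[-1])
    .need(opts, "out")
    config <- if (!is.null(opts$config)) read_config(opts$config)
              else analysis_config()
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    verbose <- isTRUE(opts$verbose)
    tables <- .run_stage(sub, opts, config, verbose)
    manifest <- write_results(tables, opts$out, config)
    .log_line(verbose, "wrote ", nrow(manifest), " table(s) to ", opts$out)
    list(status = 0L, manifest = manifest)
  }, error = function(e) {
    status <- if (grepl("^usage:", conditionMessage(e))) 2L else 1L
    message("error: ", conditionMessage(e))
    list(status = status, manifest = NULL)
  })
  invisible(res)
}

# Internal: compute the named result tables for one subcommand.
.run_stage <- function(sub, opts, config, verbose) {
  if (sub == "simulate") {
    pars <- generator_params(seed = config$seed)
    if (!is.null(opts$`n-proteins`))
      pars$n_proteins <- as.integer(opts$`n-proteins`)
    if (!is.null(opts$`markers-per-region`))
      pars$markers_per_region <- as.integer(opts$`markers-per-region`)
    ds <- generate_proteome_dataset(pars)
    rna <- generate_rna_table(ds$truth, pars)
    .log_line(verbose, "simulated ", nrow(ds$matrix), " proteins x ",
              ncol(ds$matrix), " samples")
    rnadf <- cbind(gene_id = rna$rna$gene_ids,
                   as.data.frame(rna$rna$ntpm), stringsAsFactors = FALSE)
    return(list(matrix = .matrix_to_df(ds$matrix), samples = ds$annotations,
                truth = ds$truth, rna = rnadf, idmap = rna$idmap))
  }

  inp <- .load_inputs(opts)
  ppm <- to_ppm(inp$matrix)
  lg <- log2_transform(ppm)
  .log_line(verbose, "loaded ", nrow(inp$matrix), " proteins x ",
            ncol(inp$matrix), " samples; normalized to ppm/log2")

  stage_tables <- function(which) {
    switch(which,
      normalize = list(ppm = .matrix_to_df(ppm), log2ppm = .matrix_to_df(lg)),
      qc = {
        qc <- qc_report(inp$matrix, ppm, inp$annotations)
        list(qc_samples = qc$samples, qc_proteins = qc$proteins,
             qc_cv = qc$cv, qc_regions = qc$regions,
             qc_global = data.frame(
               median_missing_fraction = qc$median_missing_fraction))
      },
      specificity = {
        tab <- call_region_specific(lg, inp$annotations, config)
        cons <- attr(tab, "consensus")
        out <- list(specificity = tab,
                    top_per_region = top_k_per_region(tab))
        if (!is.null(cons))
          out$consensus_correlation <- data.frame(
            rho_consensus = cons$rho_consensus, trim = cons$trim,
            n_used = cons$n_used)
        lobes_ok <- all(framework_groups()$lobes %in%
                          as.character(inp$annotations$region))
        if (lobes_ok)
          out$lobe_signature <- lobe_shared_signature(
            lg, inp$annotations, config, spec_table = tab)
        out
      },
      quartiles = {
        q <- region_quartiles(ppm, inp$annotations, config)
        list(quartiles = q$table, quartile_counts = q$counts)
      },
      modules = {
        prof <- region_profile_matrix(lg, inp$annotations)
        corr <- region_correlation(prof)
        dend <- hierarchical_cluster(corr, config)
        cmp <- compare_to_framework(dend, k = 4L)
        rdf <- cbind(region = rownames(corr$r), as.data.frame(corr$r),
                     stringsAsFactors = FALSE)
        list(region_correlation = rdf, dendrogram = dend$merges,
             framework_comparison = cmp)
      },
      crossomics = {
        .need(opts, c("rna", "idmap"))
        tab <- call_region_specific(lg, inp$annotations, config)
        rna <- read_rna_table(opts$rna)
        idmap <- read_id_map(opts$idmap)
        rcalls <- rna_specificity(rna, config)
        pcalls <- map_protein_regions_to_rna(tab)
        conc <- concordance_classify(pcalls, rcalls, idmap)
        counts <- as.data.frame(table(class = conc$class),
                                stringsAsFactors = FALSE)
        list(rna_specificity = rcalls, concordance = conc,
             concordance_counts = counts)
      },
      evaluate = {
        .need(opts, "truth")
        truth <- utils::read.delim(opts$truth, sep = "\t",
                                   stringsAsFactors = FALSE)
        truth$is_marker <- as.logical(truth$is_marker)
        tab <- call_region_specific(lg, inp$annotations, config)
        rec <- recovery_metrics(tab, truth)
        list(recovery = data.frame(
          sensitivity = rec$sensitivity, empirical_fdr = rec$empirical_fdr,
          region_accuracy = rec$region_accuracy, rho_error = rec$rho_error,
          n_calls = rec$n_calls, n_markers = rec$n_markers))
      },
      stop("internal: unknown stage ", which, call. = FALSE))
  }

  if (sub != "run-all") return(stage_tables(sub))
  tables <- c(stage_tables("normalize"), stage_tables("qc"),
              stage_tables("specificity"), stage_tables("quartiles"),
              stage_tables("modules"))
  if (!is.null(opts$rna) && !is.null(opts$idmap))
    tables <- c(tables, stage_tables("crossomics"))
  tables
}
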