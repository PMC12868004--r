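#' Construct an abundance matrix
#'
#' The central container: a numeric proteins x samples matrix with explicit
#' missingness (`NA`) and a processing-stage tag. Stage `"raw"` holds
#' quantified linear intensities, `"ppm"` per-sample normalized parts per
#' million, `"log2ppm"` the log2 of ppm.
#'
#' @param values Numeric matrix; rownames are protein ids, colnames sample ids.
#' @param stage One of `"raw"`, `"ppm"`, `"log2ppm"`.
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, stage = c("raw", "ppm", "log2ppm")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have protein ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (stage %in% c("raw", "ppm") && any(values <= 0, na.rm = TRUE))
    stop("stage '", stage, "' requires all present values > 0", call. = FALSE)
  structure(values, stage = stage, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s]: %d proteins x %d samples, %.1f%% missing\n",
              attr(x, "stage"), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Processing stage of an abundance matrix
#' @param x An `abundance_matrix`.
#' @return Stage string.
#' @export
matrix_stage <- function(x) attr(x, "stage")

# Internal: strip class to plain matrix for arithmetic.
.unwrap <- function(x) {
  attr(x, "stage") <- NULL
  class(x) <- c("matrix", "array")
  x
}

#' Validate sample annotations
#'
#' Annotations are a data.frame with columns `sample_id`, `donor_id`,
#' `region` (a factor over [region_codes()]).
#'
#' @param ann Data frame to validate.
#' @return The validated data frame (region coerced via [parse_region()]).
#' @export
as_sample_annotation <- function(ann) {
  need <- c("sample_id", "donor_id", "region")
  if (!all(need %in% names(ann)))
    stop("annotations need columns: ", paste(need, collapse = ", "), call. = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  ann$donor_id <- as.character(ann$donor_id)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotations: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "),
         call. = FALSE)
  ann$region <- parse_region(ann$region)
  ann[c("sample_id", "donor_id", "region")]
}

# Internal: check matrix columns are annotated, return annotations in
# matrix column order.
.match_annotations <- function(matrix, annotations) {
  annotations <- as_sample_annotation(annotations)
  miss <- setdiff(colnames(matrix), annotations$sample_id)
  if (length(miss) > 0)
    stop("samples missing from annotations: ", paste(miss, collapse = ", "),
         call. = FALSE)
  annotations[match(colnames(matrix), annotations$sample_id), , drop = FALSE]
}
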