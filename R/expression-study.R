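#' Construct an ExpressionStudy
#'
#' An `ExpressionStudy` bundles one study's probe-level expression matrix with
#' its discordant-twin design: which samples form a pair, which twin of each
#' pair is affected, optional pair-level sex labels, and the probe-to-gene
#' annotation. It is the unit of input for the per-study stages of the
#' pipeline.
#'
#' @param study_id Single string identifying the study.
#' @param phenotype Single string, the phenotype label (e.g. `"CFS"`).
#' @param values Numeric matrix, probes x samples, with unique rownames
#'   (probe IDs) and colnames (sample IDs). `NA` marks missing measurements.
#' @param pairs Data frame with columns `pair_id`, `affected`, `unaffected`;
#'   the latter two are sample IDs present in `colnames(values)`.
#' @param sex Optional named character vector mapping `pair_id` to `"male"`
#'   or `"female"`; `NULL` when the study carries no sex labels.
#' @param annotation Data frame with columns `probe_id`, `gene_symbol`, one
#'   row per probe-gene link (a probe annotated to several genes appears on
#'   several rows). Rows for probes absent from `values` are dropped.
#' @param validate Run invariant checks (default `TRUE`).
#'
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `study_id`, `phenotype`, `values`, `pairs`, `sex`, `annotation`, and
#'   `unmapped` (probe IDs with no gene annotation).
#' @export
expression_study <- function(study_id, phenotype, values, pairs, sex = NULL,
                             annotation, validate = TRUE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  keep <- annotation$probe_id %in% rownames(values) &
    !is.na(annotation$gene_symbol) & nzchar(annotation$gene_symbol)
  annotation <- annotation[keep, c("probe_id", "gene_symbol"), drop = FALSE]
  annotation <- unique(annotation)
  rownames(annotation) <- NULL
  obj <- structure(
    list(study_id = as.character(study_id),
         phenotype = as.character(phenotype),
         values = values,
         pairs = pairs,
         sex = sex,
         annotation = annotation,
         unmapped = setdiff(rownames(values), annotation$probe_id)),
    class = "ExpressionStudy")
  if (validate) validate_expression_study(obj)
  obj
}

#' Validate ExpressionStudy invariants
#'
#' Checks that probe IDs are unique, every pair references existing samples,
#' no sample occurs in more than one pair slot, pair IDs are unique, at least
#' one pair is present, and sex labels (when given) cover only known pairs
#' with values in `male`/`female`.
#'
#' @param x An `ExpressionStudy`.
#' @return `x`, invisibly; errors on the first violated invariant.
#' @export
validate_expression_study <- function(x) {
  stopifnot(inherits(x, "ExpressionStudy"))
  v <- x$values
  if (!is.matrix(v) || !is.numeric(v))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    stop("probe IDs (rownames of values) must be present and unique",
         call. = FALSE)
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    stop("sample IDs (colnames of values) must be present and unique",
         call. = FALSE)
  p <- x$pairs
  if (nrow(p) < 1L) stop("at least one twin pair is required", call. = FALSE)
  if (anyDuplicated(p$pair_id))
    stop("duplicated pair_id in pairs", call. = FALSE)
  used <- c(p$affected, p$unaffected)
  if (anyDuplicated(used))
    stop("a sample ID occurs in more than one pair slot", call. = FALSE)
  if (!all(used %in% colnames(v)))
    stop("pair references a sample ID absent from the expression matrix",
         call. = FALSE)
  if (!is.null(x$sex)) {
    if (!all(names(x$sex) %in% p$pair_id))
      stop("sex labels refer to unknown pair IDs", call. = FALSE)
    if (!all(x$sex %in% c("male", "female")))
      stop("sex labels must be 'male' or 'female'", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat(sprintf("ExpressionStudy '%s' (%s): %d probes x %d samples, %d pairs%s\n",
              x$study_id, x$phenotype, nrow(x$values), ncol(x$values),
              nrow(x$pairs),
              if (is.null(x$sex)) "" else ", sex-labelled"))
  cat(sprintf("  annotation: %d probe-gene links, %d unmapped probes\n",
              nrow(x$annotation), length(x$unmapped)))
  invisible(x)
}

#' Restrict a study to a subset of twin pairs
#'
#' Keeps only the named pairs (and their samples); used by the sex-stratified
#' analysis. Probe data and annotation are untouched.
#'
#' @param study An `ExpressionStudy`.
#' @param pair_ids Character vector of pair IDs to retain.
#' @return A new `ExpressionStudy` restricted to those pairs.
#' @export
subset_pairs <- function(study, pair_ids) {
  keep <- study$pairs$pair_id %in% pair_ids
  if (!any(keep)) stop("no pairs left after subsetting", call. = FALSE)
  pairs <- study$pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  samples <- c(rbind(pairs$affected, pairs$unaffected))
  sex <- study$sex
  if (!is.null(sex)) sex <- sex[names(sex) %in% pairs$pair_id]
  expression_study(study$study_id, study$phenotype,
                   study$values[, samples, drop = FALSE],
                   pairs, sex = sex, annotation = study$annotation)
}
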