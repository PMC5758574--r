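# TSV input/output. One dialect only: tab-delimited, UTF-8, "." decimal,
# missing values as "" or "NA" on read and "NA" on write.

#' Read one study from its TSV triple
#'
#' Loads a probe-level expression matrix, the twin-pair metadata and the
#' probe-to-gene annotation, validates them, and assembles an
#' [expression_study()]. Pairs with a missing member are dropped with a
#' warning; probes without annotation are retained and flagged unmapped.
#'
#' @param matrix_path TSV with a header row of sample IDs; first column holds
#'   probe IDs, remaining columns expression intensities (platform-native
#'   units; empty field or `NA` for missing).
#' @param metadata_path TSV with columns `sample_id`, `pair_id`, `status`
#'   (`affected`/`unaffected`) and optionally `sex` (`male`/`female`,
#'   constant within a pair).
#' @param annotation_path TSV with columns `probe_id`, `gene_symbol`;
#'   multi-gene cells use the GPL convention `"A /// B"`.
#' @param study_id,phenotype Labels for the study; default to the matrix
#'   file name stem.
#'
#' @return An `ExpressionStudy`. The attribute `"load_report"` holds
#'   `n_pairs`, `n_unmapped` and the IDs of any dropped pairs.
#' @export
read_expression <- function(matrix_path, metadata_path, annotation_path,
                            study_id = NULL, phenotype = NULL) {
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  if (is.null(phenotype)) phenotype <- study_id

  mat <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2L)
    stop(sprintf("%s: malformed header, need probe column plus >=1 sample",
                 matrix_path), call. = FALSE)
  probe_ids <- as.character(mat[[1L]])
  dup <- which(duplicated(probe_ids))
  if (length(dup))
    stop(sprintf("%s: duplicate probe ID '%s' at data line %d",
                 matrix_path, probe_ids[dup[1L]], dup[1L]), call. = FALSE)
  values <- as.matrix(mat[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop(sprintf("%s: non-numeric expression values", matrix_path),
         call. = FALSE)
  rownames(values) <- probe_ids

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            colClasses = "character")
  need <- c("sample_id", "pair_id", "status")
  if (!all(need %in% names(meta)))
    stop(sprintf("%s: metadata must have columns %s", metadata_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  bad <- which(!meta$status %in% c("affected", "unaffected"))
  if (length(bad))
    stop(sprintf("%s: invalid status '%s' at data line %d", metadata_path,
                 meta$status[bad[1L]], bad[1L]), call. = FALSE)
  meta <- meta[meta$sample_id %in% colnames(values), , drop = FALSE]
  parsed <- build_pairs(meta, metadata_path)

  ann <- read_annotation(annotation_path)

  study <- expression_study(study_id, phenotype, values, parsed$pairs,
                            sex = parsed$sex, annotation = ann)
  attr(study, "load_report") <- list(
    n_pairs = nrow(parsed$pairs),
    n_unmapped = length(study$unmapped),
    dropped_pairs = parsed$dropped)
  study
}

# Turn sample-level metadata rows into a validated pair table plus optional
# per-pair sex map. Incomplete pairs are dropped (warning); two affected or
# two unaffected members, or conflicting sex within a pair, are errors.
build_pairs <- function(meta, path = "<metadata>") {
  ids <- sort(unique(meta$pair_id))
  has_sex <- "sex" %in% names(meta) && any(nzchar(meta$sex) & !is.na(meta$sex))
  pairs <- list(); sex <- character(); dropped <- character()
  for (pid in ids) {
    rows <- meta[meta$pair_id == pid, , drop = FALSE]
    aff <- rows$sample_id[rows$status == "affected"]
    una <- rows$sample_id[rows$status == "unaffected"]
    if (length(aff) > 1L || length(una) > 1L)
      stop(sprintf("%s: pair '%s' has %d affected / %d unaffected members",
                   path, pid, length(aff), length(una)), call. = FALSE)
    if (length(aff) != 1L || length(una) != 1L) {
      dropped <- c(dropped, pid)
      next
    }
    pairs[[pid]] <- data.frame(pair_id = pid, affected = aff,
                               unaffected = una, stringsAsFactors = FALSE)
    if (has_sex) {
      s <- unique(rows$sex[!is.na(rows$sex) & nzchar(rows$sex)])
      if (length(s) > 1L)
        stop(sprintf("%s: conflicting sex labels for pair '%s'", path, pid),
             call. = FALSE)
      if (length(s) == 1L) sex[pid] <- s
    }
  }
  if (length(dropped))
    warning(sprintf("%s: dropped incomplete pair(s): %s", path,
                    paste(dropped, collapse = ", ")), call. = FALSE)
  if (!length(pairs))
    stop(sprintf("%s: zero valid twin pairs", path), call. = FALSE)
  list(pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
       sex = if (length(sex)) sex else NULL,
       dropped = dropped)
}

# Annotation TSV -> long data.frame(probe_id, gene_symbol); " /// " cells are
# split, surrounding whitespace stripped, empty symbols discarded.
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(ann)))
    stop(sprintf("%s: annotation must have columns probe_id, gene_symbol",
                 path), call. = FALSE)
  genes <- strsplit(ann$gene_symbol, "///", fixed = TRUE)
  out <- data.frame(
    probe_id = rep(ann$probe_id, lengths(genes)),
    gene_symbol = trimws(unlist(genes, use.names = FALSE)),
    stringsAsFactors = FALSE)
  out <- out[!is.na(out$gene_symbol) & nzchar(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  unique(out)
}

#' Write a result table as deterministic TSV
#'
#' Writes any of the pipeline's result tables with a fixed column order,
#' floating-point numbers rendered to 6 significant digits, and a
#' deterministic row order (sorted by `gene`, then `study_id`, when those
#' columns exist). Re-reading reproduces the values to the rendered
#' precision.
#'
#' @param records Non-empty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    stop("refusing to write an empty result table", call. = FALSE)
  keys <- intersect(c("gene", "study_id"), names(records))
  if (length(keys)) {
    ord <- do.call(order, unname(records[keys]))
    records <- records[ord, , drop = FALSE]
  }
  for (j in seq_along(records)) {
    if (is.double(records[[j]]))
      records[[j]] <- ifelse(is.na(records[[j]]), NA,
                             formatC(records[[j]], digits = 6, format = "g"))
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
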