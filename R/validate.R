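# Internal validation helpers shared by the readers and the analysis entry
# points. All failures are rlang::abort() with the offending names in the
# message so a pipeline run never dies silently.

#' Validate a gene-by-sample count table
#'
#' Checks the count-matrix contract: a `gene_id` character column without
#' duplicates, all remaining columns numeric, non-negative and integral.
#'
#' @param counts A data frame: `gene_id` plus one numeric column per sample.
#' @param design Optional design table (`sample`, `condition`, `replicate`);
#'   when supplied, samples must match the count columns and both conditions
#'   must be non-empty.
#' @return `counts`, invisibly, after validation.
#' @export
validate_count_matrix <- function(counts, design = NULL) {
  if (!is.data.frame(counts)) abort("`counts` must be a data frame.")
  if (!"gene_id" %in% names(counts)) {
    abort("`counts` must have a `gene_id` column.")
  }
  dup <- unique(counts$gene_id[duplicated(counts$gene_id)])
  if (length(dup) > 0) {
    abort(paste0(
      "Duplicate gene ids in count matrix: ",
      paste(head(dup, 5), collapse = ", "),
      if (length(dup) > 5) ", ..." else ""
    ))
  }
  samp <- setdiff(names(counts), "gene_id")
  if (length(samp) == 0) abort("Count matrix has no sample columns.")
  m <- as.matrix(counts[samp])
  if (!is.numeric(m)) abort("Count columns must be numeric.")
  if (anyNA(m)) abort("Count matrix contains NA values.")
  if (any(m < 0)) abort("Counts must be non-negative.")
  if (any(m != round(m))) abort("Counts must be integral.")
  if (!is.null(design)) {
    validate_design(design, samp)
  }
  invisible(counts)
}

validate_design <- function(design, samples,
                            conditions = c("input", "IP")) {
  if (!is.data.frame(design) ||
      !all(c("sample", "condition") %in% names(design))) {
    abort("`design` must be a data frame with columns `sample`, `condition`.")
  }
  missing <- setdiff(samples, design$sample)
  extra <- setdiff(design$sample, samples)
  if (length(missing) || length(extra)) {
    abort(paste0(
      "Design/sample mismatch.",
      if (length(missing)) paste0(" Missing from design: ",
                                  paste(missing, collapse = ", "), ".") else "",
      if (length(extra)) paste0(" Not in table: ",
                                paste(extra, collapse = ", "), ".") else ""
    ))
  }
  bad <- setdiff(unique(design$condition), conditions)
  if (length(bad)) {
    abort(paste0("Unknown condition label(s): ", paste(bad, collapse = ", "),
                 "; expected ", paste(conditions, collapse = "/"), "."))
  }
  for (cond in conditions) {
    if (!any(design$condition == cond)) {
      abort(paste0("Design has no `", cond, "` samples."))
    }
  }
  invisible(design)
}

# counts tibble -> integer matrix with gene_id rownames, columns ordered as
# in the design (if given) else as in the table.
count_matrix_as_matrix <- function(counts, design = NULL) {
  samp <- setdiff(names(counts), "gene_id")
  if (!is.null(design)) samp <- design$sample
  m <- as.matrix(counts[samp])
  rownames(m) <- counts$gene_id
  m
}
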