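# broom-style tidiers for the result classes.

#' @export
tidy.rip_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "rip_result")
  out
}

#' @export
glance.rip_result <- function(x, ...) {
  params <- attr(x, "params")
  tibble(
    n_genes = nrow(x),
    n_selected = sum(x$selected, na.rm = TRUE),
    vfactor_threshold = params$vfactor_threshold,
    p_source = if (isTRUE(params$use_padj)) "padj" else "p",
    median_dispersion = median(x$dispersion, na.rm = TRUE),
    n_unconverged = sum(!x$converged),
    n_degenerate = sum(x$degenerate)
  )
}

#' @export
tidy.volcano_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "volcano_result")
  out
}

#' @export
glance.volcano_result <- function(x, ...) {
  params <- attr(x, "params")
  tibble(
    n_groups = nrow(x),
    n_enriched = sum(x$class == "enriched"),
    n_depleted = sum(x$class == "depleted"),
    cutoff = attr(x, "cutoff"),
    fdr = params$fdr,
    s0 = params$s0,
    n_perm_used = attr(x, "n_perm_used")
  )
}

#' @export
tidy.enrich_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "enrich_result")
  out
}

#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$padj < 0.05, na.rm = TRUE),
    top_category = x$category[which.min(x$p)],
    min_p = min(x$p, na.rm = TRUE)
  )
}

#' @export
tidy.densitometry_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "densitometry_result")
  out
}

#' @export
glance.densitometry_result <- function(x, ...) {
  tibble(
    n_replicates = nrow(x),
    mean_fold_change = attr(x, "mean_fold_change"),
    t = attr(x, "t"),
    df = attr(x, "df"),
    p = attr(x, "p")
  )
}
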