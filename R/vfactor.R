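#' Composite enrichment score (Vfactor)
#'
#' The Vfactor combines effect size and significance into a single ranking
#' score: `log2fc * (-log10(p))`. The sign follows the fold change, so
#' depleted genes get negative scores. To keep the score finite when p
#' underflows, p is floored at `p_floor` (default `1e-300`) before taking
#' the log; set `p_floor = NULL` to disable flooring, in which case p <= 0
#' is an error.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values (same length or length 1).
#' @param p_floor Lower bound applied to `p`, or `NULL` to disable.
#' @return Numeric vector of Vfactors (`NA` where inputs are `NA`).
#' @examples
#' vfactor(2, 1e-30) # 60
#' vfactor(-3, 1e-20) # -60
#' @export
vfactor <- function(log2fc, p, p_floor = 1e-300) {
  if (!is.null(p_floor)) {
    p <- pmax(p, p_floor)
  } else if (any(p <= 0, na.rm = TRUE)) {
    abort("p <= 0 encountered with flooring disabled (`p_floor = NULL`).")
  }
  if (any(p > 1, na.rm = TRUE)) abort("p-values must be <= 1.")
  log2fc * (-log10(p))
}

#' Select targets by a strict Vfactor threshold
#'
#' Keeps records with `vfactor` strictly greater than `threshold` (a record
#' at exactly the threshold is excluded), preserving the input row order.
#'
#' @param records Data frame with at least `gene_id` and `vfactor` columns
#'   (e.g. a [rip_enrichment()] result).
#' @param threshold Selection threshold (default 50).
#' @param name,provenance Metadata stored on the result.
#' @return A `target_set`: tibble of the selected rows with attributes
#'   `set_name`, `provenance` and `threshold`.
#' @export
select_targets <- function(records, threshold = 50, name = "targets",
                           provenance = NULL) {
  if (!all(c("gene_id", "vfactor") %in% names(records))) {
    abort("`records` must have `gene_id` and `vfactor` columns.")
  }
  out <- as_tibble(records[!is.na(records$vfactor) &
                             records$vfactor > threshold, ])
  attr(out, "set_name") <- name
  attr(out, "threshold") <- threshold
  attr(out, "provenance") <- provenance %||%
    paste0("vfactor > ", threshold)
  class(out) <- c("target_set", class(out))
  out
}

#' RIP-seq enrichment analysis
#'
#' End-to-end IP-versus-input enrichment: median-of-ratios size factors,
#' method-of-moments dispersions moderated toward a common center, the
#' two-group negative-binomial Wald test, Benjamini-Hochberg adjustment,
#' the Vfactor score and strict-threshold target selection.
#'
#' @param counts Count table: `gene_id` column plus one column per sample.
#' @param design Design table: `sample`, `condition` (`input`/`IP`),
#'   optionally `replicate`.
#' @param vfactor_threshold Strict selection threshold (default 50).
#' @param use_padj Score on the BH-adjusted p instead of the raw p
#'   (default `FALSE`: raw p, the literal reading of the score definition).
#' @param p_floor Floor applied to p before `-log10` (default `1e-300`).
#' @param moderate Moderate dispersions before testing (default `TRUE`).
#' @param prior_df Prior weight of the dispersion center when moderating.
#' @return A `rip_result` tibble: `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `p`, `padj`, `vfactor`, `selected`, `dispersion`, `converged`,
#'   `degenerate`; attributes carry the size factors and parameters.
#'   Works with [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_ripseq(n_genes = 200, seed = 1)
#' res <- rip_enrichment(sim$counts, sim$design)
#' glance(res)
#' @export
rip_enrichment <- function(counts, design, vfactor_threshold = 50,
                           use_padj = FALSE, p_floor = 1e-300,
                           moderate = TRUE, prior_df = 10) {
  validate_count_matrix(counts, design)
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, design, sf)
  if (moderate) {
    disp <- moderate_dispersions(disp, n_samples = nrow(design),
                                 n_conditions = 2, prior_df = prior_df)
  }
  res <- nb_wald_test(counts, design, sf, disp)
  res$padj <- bh_adjust(res$p)
  p_score <- if (use_padj) res$padj else res$p
  res$vfactor <- vfactor(res$log2fc, p_score, p_floor = p_floor)
  res$selected <- !is.na(res$vfactor) & res$vfactor > vfactor_threshold
  res <- res[, c("gene_id", "base_mean", "log2fc", "se", "p", "padj",
                 "vfactor", "selected", "dispersion", "converged",
                 "degenerate")]
  attr(res, "size_factors") <- sf
  attr(res, "params") <- list(
    vfactor_threshold = vfactor_threshold, use_padj = use_padj,
    p_floor = p_floor, moderate = moderate, prior_df = prior_df
  )
  class(res) <- c("rip_result", class(res))
  res
}
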