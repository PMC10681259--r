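# Set overlap and category over-representation statistics.

#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` category members when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are in the
#' category. Evaluated on the log scale (via `phyper(log.p = TRUE)`) so
#' tail probabilities far below 1e-100 are exact to machine precision.
#'
#' @param N Universe size.
#' @param K Category size (`0 <= K <= N`).
#' @param n Draw (query) size (`0 <= n <= N`).
#' @param k Observed overlap (`0 <= k <= min(n, K)`); vectorized.
#' @param log_p Return the natural log of the tail probability.
#' @return The tail probability (or its log).
#' @examples
#' hypergeometric_tail(10, 4, 5, 3) # 66/252
#' @export
hypergeometric_tail <- function(N, K, n, k, log_p = FALSE) {
  if (any(N < 0) || any(K < 0) || any(K > N)) {
    abort("Need 0 <= K <= N.")
  }
  if (any(n < 0) || any(n > N)) abort("Need 0 <= n <= N.")
  if (any(k < 0) || any(k > pmin(n, K))) {
    abort("Need 0 <= k <= min(n, K).")
  }
  lp <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Category over-representation for a query gene set
#'
#' One upper-tail hypergeometric test per category of an annotation table,
#' with BH adjustment across categories. Query genes outside the universe
#' are dropped with a warning.
#'
#' @param annotation Tibble with columns `gene_id`, `category`.
#' @param query Character vector of query gene ids.
#' @param universe Character vector of universe gene ids; defaults to all
#'   genes in `annotation`.
#' @return An `enrich_result` tibble, one row per category: `category`,
#'   `k` (overlap), `n` (query size in universe), `K` (category size),
#'   `N` (universe size), `expected` (`n*K/N`), `fraction` (`k/n`), `p`,
#'   `padj`; ordered by `p`.
#' @export
category_enrichment <- function(annotation, query, universe = NULL) {
  if (!all(c("gene_id", "category") %in% names(annotation))) {
    abort("`annotation` must have `gene_id` and `category` columns.")
  }
  universe <- unique(universe %||% annotation$gene_id)
  if (length(universe) == 0) abort("Empty universe.")
  outside <- setdiff(annotation$gene_id, universe)
  if (length(outside)) {
    abort(paste0(length(outside),
                 " annotated gene(s) are not in the universe."))
  }
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warn(paste0(length(dropped),
                " query gene(s) outside the universe were dropped."))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  ann <- distinct(annotation, .data$gene_id, .data$category)
  res <- ann |>
    group_by(.data$category) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = length(intersect(.data$gene_id, query)),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      expected = n * .data$K / N,
      fraction = ifelse(n > 0, .data$k / n, NA_real_),
      p = hypergeometric_tail(N, .data$K, n, .data$k)
    ) |>
    arrange(.data$p)
  res$padj <- bh_adjust(res$p)
  res <- res[, c("category", "k", "n", "K", "N", "expected", "fraction",
                 "p", "padj")]
  class(res) <- c("enrich_result", class(res))
  res
}

#' Intersection of gene sets
#'
#' Exact intersection of one or more gene-id vectors, returned sorted for
#' deterministic output.
#'
#' @param sets A list of character vectors (at least one).
#' @return Sorted character vector of ids present in every set.
#' @export
core_intersection <- function(sets) {
  if (!is.list(sets) || length(sets) == 0) {
    abort("`sets` must be a non-empty list of character vectors.")
  }
  out <- Reduce(intersect, lapply(sets, unique))
  sort(out)
}

#' Overlap of two gene sets
#'
#' Counts `k = |a intersect b|`; when a universe is supplied, also reports
#' the expected overlap and the upper-tail hypergeometric p-value of
#' drawing `k` or more of `b`'s members in a draw of size `|a|`.
#'
#' @param a,b Character vectors of gene ids.
#' @param universe Optional universe; both sets must be subsets of it.
#' @return One-row tibble: `k`, `n_a`, `n_b`, and with a universe `N`,
#'   `expected`, `p`.
#' @export
overlap_count <- function(a, b, universe = NULL) {
  a <- unique(a)
  b <- unique(b)
  k <- length(intersect(a, b))
  out <- tibble(k = k, n_a = length(a), n_b = length(b))
  if (!is.null(universe)) {
    universe <- unique(universe)
    if (length(setdiff(a, universe)) || length(setdiff(b, universe))) {
      abort("Both sets must be subsets of the universe.")
    }
    N <- length(universe)
    out$N <- N
    out$expected <- length(a) * length(b) / N
    out$p <- hypergeometric_tail(N, length(b), length(a), k)
  }
  out
}

#' Densitometry fold change with a t-test
#'
#' For western-blot quantification: each lane's relative abundance is the
#' target-band signal divided by the loading-control (reference) signal.
#' The per-replicate fold change is the overexpression lane's relative
#' abundance divided by the mean relative abundance of the control lanes,
#' and a two-sided one-sample t-test of the log fold changes against 0
#' tests for a change.
#'
#' @param tbl Tibble with columns `condition` (values
#'   `"overexpression"` / `"control"`), `replicate`, `target`, `reference`
#'   (positive band signals).
#' @return A `densitometry_result` tibble of the overexpression
#'   replicates: `replicate`, `relative_abundance`, `fold_change`;
#'   attributes `mean_fold_change`, `t`, `df`, `p`.
#' @export
densitometry_fold_change <- function(tbl) {
  need <- c("condition", "replicate", "target", "reference")
  if (!all(need %in% names(tbl))) {
    abort(paste0("`tbl` must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(tbl$reference <= 0)) abort("Reference signals must be > 0.")
  if (any(tbl$target <= 0)) abort("Target signals must be > 0.")
  bad <- setdiff(unique(tbl$condition), c("overexpression", "control"))
  if (length(bad)) {
    abort(paste0("Unknown condition(s): ", paste(bad, collapse = ", ")))
  }
  for (cond in c("overexpression", "control")) {
    if (sum(tbl$condition == cond) < 3) {
      abort(paste0("At least 3 `", cond, "` replicates are required."))
    }
  }
  rel <- tbl$target / tbl$reference
  ctrl_mean <- mean(rel[tbl$condition == "control"])
  oe <- tbl$condition == "overexpression"
  fc <- rel[oe] / ctrl_mean
  lf <- log(fc)
  se <- sd(lf) / sqrt(length(lf))
  if (se == 0) {
    # constant fold changes: no change gives t = 0 / p = 1, a constant
    # non-unit fold change is infinitely significant under this model
    t_stat <- if (mean(lf) == 0) 0 else sign(mean(lf)) * Inf
    p <- if (mean(lf) == 0) 1 else 0
  } else {
    t_stat <- mean(lf) / se
    p <- 2 * stats::pt(-abs(t_stat), length(lf) - 1)
  }
  out <- tibble(
    replicate = tbl$replicate[oe],
    relative_abundance = rel[oe],
    fold_change = fc
  )
  attr(out, "mean_fold_change") <- mean(fc)
  attr(out, "t") <- t_stat
  attr(out, "df") <- length(lf) - 1
  attr(out, "p") <- p
  class(out) <- c("densitometry_result", class(out))
  out
}

#' Consensus Ssd1 target fixture
#'
#' The eleven mRNAs consistently recovered as Ssd1 targets across the
#' published RIP and CRAC datasets, with a flag marking which of them were
#' also called as eIF2A RIP-seq targets. Shipped as a plain-text table in
#' `inst/extdata/ssd1_core_targets.tsv`.
#'
#' @return Tibble: `gene` (standard name), `eif2a_target` (logical),
#'   `description`.
#' @export
ssd1_core_targets <- function() {
  path <- system.file("extdata", "ssd1_core_targets.tsv",
                      package = "ripscore", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    eif2a_target = readr::col_logical(),
                    description = readr::col_character()
                  ))
}
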