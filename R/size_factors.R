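#' Median-of-ratios size factors
#'
#' Computes per-sample scaling factors by the median-of-ratios scheme used
#' for count normalization in differential-expression workflows: each count
#' is divided by the per-gene geometric mean across samples (genes with any
#' zero count are excluded from the reference), the per-sample factor is the
#' median of those ratios, and the factors are rescaled so that their
#' geometric mean is exactly 1.
#'
#' @param counts Count table: `gene_id` column plus one numeric column per
#'   sample (see [validate_count_matrix()]).
#' @return A tibble with columns `sample` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), a = c(10, 20), b = c(20, 40))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  validate_count_matrix(counts)
  m <- count_matrix_as_matrix(counts)
  sf <- size_factors_matrix(m)
  tibble(sample = colnames(m), size_factor = unname(sf))
}

# matrix backend, shared with the pipeline
size_factors_matrix <- function(m) {
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    abort(paste0(
      "Cannot compute median-of-ratios size factors: no gene has ",
      "all-positive counts across samples."
    ))
  }
  ref <- m[allpos, , drop = FALSE]
  log_geo <- rowMeans(log(ref))
  sf <- apply(ref, 2, function(col) median(exp(log(col) - log_geo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Per-gene negative-binomial dispersion by method of moments
#'
#' For each gene, counts are divided by the size factors and, within each
#' condition separately, the moment estimator
#' \eqn{\hat\alpha = (s^2 - \bar q) / \bar q^2} is formed from the normalized
#' counts (variance = \eqn{\mu + \alpha \mu^2} parameterization). The
#' per-condition estimates are averaged and floored at `floor`. Genes with
#' all-zero counts get the floor and are flagged.
#'
#' These raw estimates are very noisy with few replicates; the enrichment
#' pipeline moderates them with [moderate_dispersions()] before testing.
#'
#' @param counts Count table (`gene_id` + sample columns).
#' @param design Design table (`sample`, `condition`, `replicate`).
#' @param sf Optional size-factor tibble from [size_factors()]; computed if
#'   omitted.
#' @param floor Lower bound for the estimate (default `1e-8`).
#' @return Tibble: `gene_id`, `dispersion` (floored), `dispersion_raw`
#'   (unfloored average, may be negative or NA), `all_zero` flag.
#' @export
estimate_dispersions <- function(counts, design, sf = NULL, floor = 1e-8) {
  validate_count_matrix(counts, design)
  if (nrow(design) < 2) abort("At least 2 samples are required.")
  if (is.null(sf)) sf <- size_factors(counts)
  m <- count_matrix_as_matrix(counts, design)
  sfv <- sf$size_factor[match(colnames(m), sf$sample)]
  q <- sweep(m, 2, sfv, "/")
  conds <- unique(design$condition)
  per_cond <- vapply(conds, function(cond) {
    qc <- q[, design$sample[design$condition == cond], drop = FALSE]
    if (ncol(qc) < 2) return(rep(NA_real_, nrow(q)))
    mu <- rowMeans(qc)
    s2 <- rowSums((qc - mu)^2) / (ncol(qc) - 1)
    ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  }, numeric(nrow(q)))
  raw <- rowMeans(per_cond, na.rm = TRUE)
  raw[is.nan(raw)] <- NA_real_
  all_zero <- rowSums(m) == 0
  tibble(
    gene_id = rownames(m),
    dispersion = pmax(floor, ifelse(is.na(raw), floor, raw)),
    dispersion_raw = raw,
    all_zero = unname(all_zero)
  )
}

#' Moderate per-gene dispersions toward a common center
#'
#' Shrinks the raw moment estimates toward a robust center (trimmed mean of
#' the floored raw estimates) with weight `prior_df` against the per-gene
#' residual degrees of freedom. With 3 replicates per condition the raw
#' estimator has only 4 residual df and moderation is essential for
#' calibrated Wald p-values; see the methods vignette.
#'
#' @param disp Tibble from [estimate_dispersions()].
#' @param n_samples,n_conditions Sample and condition counts, used for the
#'   per-gene degrees of freedom (`n_samples - n_conditions`).
#' @param prior_df Prior weight of the common center (default 10).
#' @param trim Trim fraction for the center (default 0.05).
#' @param floor Lower bound (default `1e-8`).
#' @return `disp` with the `dispersion` column replaced by the moderated
#'   estimate and a `dispersion_center` attribute.
#' @export
moderate_dispersions <- function(disp, n_samples, n_conditions = 2,
                                 prior_df = 10, trim = 0.05, floor = 1e-8) {
  df_gene <- max(n_samples - n_conditions, 1)
  raw <- disp$dispersion_raw
  center <- mean(pmax(raw, 0), trim = trim, na.rm = TRUE)
  if (!is.finite(center)) center <- floor
  mod <- (df_gene * raw + prior_df * center) / (df_gene + prior_df)
  mod[is.na(mod)] <- center
  out <- mutate(disp, dispersion = pmax(floor, mod))
  attr(out, "dispersion_center") <- center
  out
}
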