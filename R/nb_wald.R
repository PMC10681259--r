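#' Two-group negative-binomial Wald test
#'
#' Fits, for every gene, the two-group NB generalized linear model with log
#' link and log size-factor offsets,
#' \deqn{y_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \quad
#'       \log \mu_{gj} = \log s_j + \beta_{0g} + x_j \beta_{1g},}
#' where \eqn{x_j} indicates the IP condition, by iteratively reweighted
#' least squares (one shared 2-column design, per-gene weights, closed-form
#' 2x2 solve vectorized across genes). The reported `log2fc` is
#' \eqn{\beta_1/\ln 2}, its standard error comes from the inverse Fisher
#' information, and `p` is the two-sided normal tail of `log2fc / se`.
#'
#' Zeros enter the GLM as ordinary observations (no pseudocounts). When one
#' condition is all zeros the GLM is degenerate; the gene is flagged
#' (`degenerate = TRUE`), `log2fc` is reported from a half-count fallback on
#' the normalized condition means, and `se`/`p` are `NA`. Genes whose IRLS
#' does not converge within `max_iter` are flagged `converged = FALSE` with
#' `p = NA`.
#'
#' @param counts Count table (`gene_id` + sample columns).
#' @param design Design table (`sample`, `condition` in `input`/`IP`).
#' @param sf Size-factor tibble ([size_factors()]); computed if `NULL`.
#' @param dispersions Tibble with `gene_id`, `dispersion` (e.g. from
#'   [estimate_dispersions()], optionally moderated); computed (moderated)
#'   if `NULL`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   max absolute coefficient change.
#' @return Tibble: `gene_id`, `base_mean` (mean normalized count), `log2fc`,
#'   `se`, `stat`, `p`, `dispersion`, `converged`, `degenerate`.
#' @export
nb_wald_test <- function(counts, design, sf = NULL, dispersions = NULL,
                         max_iter = 100, tol = 1e-8) {
  validate_count_matrix(counts, design)
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, design, sf)
    dispersions <- moderate_dispersions(dispersions, n_samples = nrow(design))
  }
  m <- count_matrix_as_matrix(counts, design)
  sfv <- sf$size_factor[match(colnames(m), sf$sample)]
  if (anyNA(sfv)) abort("Size factors missing for some samples.")
  disp <- dispersions$dispersion[match(rownames(m), dispersions$gene_id)]
  if (anyNA(disp)) abort("Dispersions missing for some genes.")
  x <- as.numeric(design$condition == "IP")
  fit <- nb_wald_fit(m, x, sfv, disp, max_iter = max_iter, tol = tol)
  tibble(
    gene_id = rownames(m),
    base_mean = unname(rowMeans(sweep(m, 2, sfv, "/"))),
    log2fc = fit$log2fc, se = fit$se, stat = fit$stat, p = fit$p,
    dispersion = disp,
    converged = fit$converged, degenerate = fit$degenerate
  )
}

# Vectorized IRLS over genes for the shared 2-column design [1, x].
nb_wald_fit <- function(y, x, sf, disp, max_iter = 100, tol = 1e-8) {
  n_g <- nrow(y)
  n_s <- ncol(y)
  off <- matrix(log(sf), n_g, n_s, byrow = TRUE)
  q <- sweep(y, 2, sf, "/")
  mean0 <- rowMeans(q[, x == 0, drop = FALSE])
  mean1 <- rowMeans(q[, x == 1, drop = FALSE])
  degenerate <- mean0 == 0 | mean1 == 0

  b0 <- log(pmax(rowMeans(q), 1e-8))
  b1 <- rep(0, n_g)
  active <- !degenerate
  converged <- rep(FALSE, n_g)
  S0 <- S1 <- det <- rep(NA_real_, n_g)
  xm <- matrix(x, n_g, n_s, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- b0 + xm * b1 + off
    mu <- exp(eta)
    w <- mu / (1 + disp * mu)
    z <- eta - off + (y - mu) / mu
    S0 <- rowSums(w)
    S1 <- rowSums(w * xm)
    T0 <- rowSums(w * z)
    T1 <- rowSums(w * z * xm)
    det <- S1 * (S0 - S1)
    b1n <- ifelse(det > 0, (S0 * T1 - S1 * T0) / det, b1)
    b0n <- (T0 - S1 * b1n) / S0
    delta <- pmax(abs(b1n - b1), abs(b0n - b0))
    b0 <- ifelse(active, b0n, b0)
    b1 <- ifelse(active, b1n, b1)
    newly <- active & delta < tol
    converged[newly] <- TRUE
    active <- active & !newly
  }
  se_b1 <- sqrt(S0 / det)
  log2fc <- b1 / log(2)
  se <- se_b1 / log(2)
  stat <- log2fc / se
  p <- 2 * pnorm(-abs(stat))
  # unconverged genes report NA p with the flag, never silently
  bad <- !converged & !degenerate
  p[bad] <- NA_real_
  # degenerate genes: half-count fallback for log2fc only
  if (any(degenerate)) {
    fb <- log2((mean1 + 0.5) / (mean0 + 0.5))
    log2fc[degenerate] <- fb[degenerate]
    se[degenerate] <- NA_real_
    stat[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
  }
  list(log2fc = unname(log2fc), se = unname(se), stat = unname(stat),
       p = unname(p), converged = unname(converged | degenerate),
       degenerate = unname(degenerate))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`:
#' step-up adjustment with monotonicity enforcement, order-preserving,
#' `NA` propagated.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(paste0("p-values outside [0, 1] at positions: ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  p.adjust(p, method = "BH")
}
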