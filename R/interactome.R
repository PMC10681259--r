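# Label-free AP-MS interactor calling: filter -> log2 -> valid-value ->
# impute -> permutation-FDR volcano. The stage order is part of the
# contract: each step records the stage it produces on the table and
# refuses input from the wrong stage.

lfq_stage <- function(tbl) attr(tbl, "lfq_stage") %||% "raw"

set_stage <- function(tbl, stage) {
  attr(tbl, "lfq_stage") <- stage
  tbl
}

require_stage <- function(tbl, expected, fn) {
  got <- lfq_stage(tbl)
  if (!got %in% expected) {
    abort(paste0(
      fn, "() expects a table at stage ",
      paste(sQuote(expected), collapse = " or "),
      " but got ", sQuote(got),
      ". The pipeline order is filter_protein_groups -> log2_lfq -> ",
      "valid_value_filter -> impute_downshift -> call_interactors."
    ))
  }
  invisible(tbl)
}

meta_cols <- c("group_id", "member_ids", "razor_unique_peptides",
               "reverse", "contaminant")

intensity_cols <- function(tbl, design) {
  missing <- setdiff(design$sample, names(tbl))
  if (length(missing)) {
    abort(paste0("Samples missing from table: ",
                 paste(missing, collapse = ", ")))
  }
  design$sample
}

validate_protein_design <- function(design) {
  if (!is.data.frame(design) ||
      !all(c("sample", "group") %in% names(design))) {
    abort("`design` must have columns `sample` and `group`.")
  }
  bad <- setdiff(unique(design$group), c("bait", "control"))
  if (length(bad)) {
    abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", "),
                 "; expected bait/control."))
  }
  for (g in c("bait", "control")) {
    if (sum(design$group == g) < 2) {
      abort(paste0("At least 2 `", g, "` samples are required."))
    }
  }
  invisible(design)
}

#' Filter protein groups on peptide evidence and decoy flags
#'
#' Removes protein groups supported by a single razor+unique peptide
#' (`razor_unique_peptides <= min_razor_unique - 1`), reverse-database hits
#' and potential contaminants. The removal bookkeeping is stored as the
#' `filter_log` attribute.
#'
#' @param tbl Protein-group table: `group_id`, `razor_unique_peptides`,
#'   logical `reverse` and `contaminant`, plus one intensity column per
#'   sample.
#' @param min_razor_unique Minimum peptide evidence to keep (default 2,
#'   i.e. single-peptide groups are dropped).
#' @return Filtered tibble at stage `"filtered"`.
#' @export
filter_protein_groups <- function(tbl, min_razor_unique = 2) {
  require_stage(tbl, "raw", "filter_protein_groups")
  need <- c("group_id", "razor_unique_peptides", "reverse", "contaminant")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  n0 <- nrow(tbl)
  drop_rev <- tbl$reverse
  drop_con <- tbl$contaminant & !drop_rev
  drop_pep <- tbl$razor_unique_peptides < min_razor_unique &
    !drop_rev & !drop_con
  out <- as_tibble(tbl[!(drop_rev | drop_con | drop_pep), ])
  if (nrow(out) == 0) {
    warn("All protein groups were removed by the evidence/flag filter.")
  }
  attr(out, "filter_log") <- tibble(
    step = c("input", "reverse", "contaminant", "single_peptide", "kept"),
    n = c(n0, sum(drop_rev), sum(drop_con), sum(drop_pep), nrow(out))
  )
  set_stage(out, "filtered")
}

#' Log2-transform LFQ intensities
#'
#' Positive intensities become log2 intensities; zeros (the MaxQuant
#' "not quantified" convention) and `NA`/`NaN` become explicit missing
#' values. An intensity of exactly 1 maps to 0 and stays valid.
#'
#' @param tbl Protein-group table at stage `"filtered"` (or `"raw"`, for
#'   ad-hoc use on already-clean tables).
#' @param design Design table (`sample`, `group`).
#' @return Tibble at stage `"log2"`; attribute `missing_per_sample` counts
#'   missing values per sample.
#' @export
log2_lfq <- function(tbl, design) {
  require_stage(tbl, c("raw", "filtered"), "log2_lfq")
  validate_protein_design(design)
  cols <- intensity_cols(tbl, design)
  out <- tbl
  for (cl in cols) {
    v <- out[[cl]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("Negative LFQ intensity in sample ", cl, "."))
    }
    v[!is.finite(v) | v == 0] <- NA_real_
    out[[cl]] <- log2(v)
  }
  attr(out, "missing_per_sample") <- tibble(
    sample = cols,
    n_missing = unname(vapply(cols, function(cl) sum(is.na(out[[cl]])),
                              integer(1)))
  )
  set_stage(out, "log2")
}

#' Valid-value filter
#'
#' Keeps a protein group when the fraction of valid (non-missing) log2
#' intensities is at least `min_frac` in the bait group or in the control
#' group. The comparison uses `>=` on the exact fraction.
#'
#' @param tbl Table at stage `"log2"`.
#' @param design Design table (`sample`, `group`).
#' @param min_frac Minimum valid fraction required in at least one group
#'   (default 0.6).
#' @return Tibble at stage `"valid"`; `n_valid_bait` / `n_valid_control`
#'   columns record the pre-imputation counts.
#' @export
valid_value_filter <- function(tbl, design, min_frac = 0.6) {
  require_stage(tbl, "log2", "valid_value_filter")
  validate_protein_design(design)
  bait <- design$sample[design$group == "bait"]
  ctrl <- design$sample[design$group == "control"]
  vb <- rowSums(!is.na(as.matrix(tbl[bait])))
  vc <- rowSums(!is.na(as.matrix(tbl[ctrl])))
  keep <- vb / length(bait) >= min_frac | vc / length(ctrl) >= min_frac
  out <- as_tibble(tbl[keep, ])
  out$n_valid_bait <- vb[keep]
  out$n_valid_control <- vc[keep]
  attr(out, "filter_log") <- tibble(
    step = c("input", "below_valid_fraction", "kept"),
    n = c(nrow(tbl), sum(!keep), nrow(out))
  )
  set_stage(out, "valid")
}

#' Down-shifted Gaussian imputation of missing values
#'
#' Replaces, separately for each sample, every missing log2 intensity by a
#' draw from `Normal(m_j - downshift * s_j, (width * s_j)^2)`, where `m_j`
#' and `s_j` are the mean and SD of that sample's observed values (computed
#' after the valid-value filter). This emulates values below the MS
#' detection limit, the standard treatment of missing-not-at-random LFQ
#' data.
#'
#' @param tbl Table at stage `"valid"`.
#' @param design Design table (`sample`, `group`).
#' @param width,downshift Distribution parameters in units of the
#'   per-sample observed SD (defaults 0.3 and 1.8).
#' @param seed Integer seed; required for reproducibility.
#' @return Tibble at stage `"imputed"`; attribute `imputation_mask` is a
#'   logical matrix (groups x samples) marking imputed cells.
#' @export
impute_downshift <- function(tbl, design, width = 0.3, downshift = 1.8,
                             seed = 1L) {
  require_stage(tbl, "valid", "impute_downshift")
  validate_protein_design(design)
  if (width <= 0) abort("`width` must be > 0.")
  if (downshift < 0) abort("`downshift` must be >= 0.")
  cols <- intensity_cols(tbl, design)
  out <- tbl
  mask <- matrix(FALSE, nrow(tbl), length(cols),
                 dimnames = list(tbl$group_id, cols))
  rng <- local_rng(seed)
  for (cl in cols) {
    v <- out[[cl]]
    obs <- v[!is.na(v)]
    if (length(obs) < 2) {
      abort(paste0("Sample ", cl, " has fewer than 2 observed values; ",
                   "cannot estimate its imputation distribution."))
    }
    miss <- is.na(v)
    if (any(miss)) {
      m <- mean(obs)
      s <- sd(obs)
      v[miss] <- rng(function() {
        rnorm(sum(miss), mean = m - downshift * s, sd = width * s)
      })
      out[[cl]] <- v
      mask[, cl] <- miss
    }
  }
  attr(out, "imputation_mask") <- mask
  attr(out, "imputation_params") <- list(width = width,
                                         downshift = downshift, seed = seed)
  set_stage(out, "imputed")
}

# Run `f` under a private RNG state seeded with `seed`, restoring the
# caller's state afterwards. Returns a function so callers can draw several
# times from the same stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  function(f) {
    outer_state <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    assign(".Random.seed", state, globalenv())
    on.exit({
      state <<- get(".Random.seed", globalenv())
      if (is.null(outer_state)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", outer_state, globalenv())
      }
    })
    f()
  }
}

#' Two-sample t-test
#'
#' Two-sided pooled-variance (Student) t-test by default; Welch by flag.
#' Degenerate inputs follow the convention: zero pooled variance with equal
#' means gives `t = 0, p = 1`; zero variance with unequal means gives
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param bait,control Numeric vectors (>= 2 values each).
#' @param kind `"student"` (pooled variance) or `"welch"`.
#' @return A one-row tibble: `mean_diff`, `se`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
two_sample_t <- function(bait, control, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  if (length(bait) < 2 || length(control) < 2) {
    abort("Both groups need at least 2 values.")
  }
  nb <- length(bait)
  nc <- length(control)
  md <- mean(bait) - mean(control)
  vb <- var(bait)
  vc <- var(control)
  if (kind == "student") {
    sp2 <- ((nb - 1) * vb + (nc - 1) * vc) / (nb + nc - 2)
    se <- sqrt(sp2 * (1 / nb + 1 / nc))
    df <- nb + nc - 2
  } else {
    se <- sqrt(vb / nb + vc / nc)
    df <- (vb / nb + vc / nc)^2 /
      ((vb / nb)^2 / (nb - 1) + (vc / nc)^2 / (nc - 1))
  }
  degenerate <- FALSE
  if (se == 0) {
    if (md == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(md) * Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    t <- md / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble(mean_diff = md, se = se, t = t, df = df, p = p,
         degenerate = degenerate)
}

#' s0-moderated test statistic
#'
#' `d = mean_diff / (se + s0)`. With `s0 = 0` this is the plain t
#' statistic; a positive `s0` damps the statistic of small, precisely
#' measured differences and produces the curved volcano significance
#' boundary.
#'
#' @param mean_diff,se,s0 Numerics (vectors recycled); `se > 0`, `s0 >= 0`.
#' @return Numeric vector `d`.
#' @export
s0_statistic <- function(mean_diff, se, s0 = 0.1) {
  if (any(se <= 0, na.rm = TRUE)) abort("`se` must be > 0.")
  if (any(s0 < 0)) abort("`s0` must be >= 0.")
  mean_diff / (se + s0)
}

# Row-wise pooled t pieces for a matrix split by bait columns.
row_t_stats <- function(m, bait_idx, s0) {
  nb <- length(bait_idx)
  nc <- ncol(m) - nb
  B <- m[, bait_idx, drop = FALSE]
  C <- m[, -bait_idx, drop = FALSE]
  mb <- rowMeans(B)
  mc <- rowMeans(C)
  sp2 <- (rowSums((B - mb)^2) + rowSums((C - mc)^2)) / (nb + nc - 2)
  se <- sqrt(sp2 * (1 / nb + 1 / nc))
  md <- mb - mc
  t <- ifelse(se > 0, md / se, ifelse(md == 0, 0, sign(md) * Inf))
  p <- 2 * stats::pt(-abs(t), nb + nc - 2)
  d <- md / (se + s0)
  list(mean_diff = md, se = se, t = t, p = p, d = d)
}

# All distinct bait/control label assignments other than the observed one.
# For equal group sizes an assignment and its complement give the same |d|,
# so only one of each pair is kept.
perm_assignments <- function(n_bait, n_control) {
  n <- n_bait + n_control
  cmb <- combn(n, n_bait)
  obs <- seq_len(n_bait)
  keep <- list()
  for (i in seq_len(ncol(cmb))) {
    s <- cmb[, i]
    if (identical(s, obs)) next
    if (n_bait == n_control && s[1] != 1) next
    keep[[length(keep) + 1]] <- s
  }
  keep
}

#' Permutation-FDR volcano: call significant interactors
#'
#' Computes the s0-moderated statistic `d` for every protein group, builds
#' a null distribution of `|d|` from random bait/control label
#' permutations (all distinct non-identity assignments enumerated when
#' there are no more than `n_perm`, a seeded subsample otherwise), and
#' finds the smallest cutoff `c` whose estimated FDR
#' `(average permutation count of |d| >= c) / (observed count of |d| >= c)`
#' is at most `fdr`, after enforcing monotonicity of the FDR curve.
#' Enrichment calls (`significant`) are groups with `|d| >= c` and a
#' positive difference; the depleted side is classed separately.
#'
#' @param tbl Completed (imputed) table at stage `"imputed"`, or a fully
#'   observed table at stage `"valid"` with no missing values.
#' @param design Design table (`sample`, `group`).
#' @param s0 Moderation constant (default 0.1).
#' @param fdr Target false discovery rate (default 0.01).
#' @param n_perm Maximum number of label permutations (default 250).
#' @param seed Seed for the permutation subsample.
#' @param count_stat Aggregate the per-permutation exceedance counts with
#'   the `"mean"` (default) or `"median"`.
#' @return A `volcano_result` tibble: `group_id`, `log2_enrichment`, `se`,
#'   `t_stat`, `p`, `d_stat`, `n_valid_bait`, `n_valid_control`, `class`
#'   (`enriched` / `depleted` / `ns`), `significant`; attributes `cutoff`,
#'   `n_perm_used`, `fdr`, `s0`.
#' @export
call_interactors <- function(tbl, design, s0 = 0.1, fdr = 0.01,
                             n_perm = 250, seed = 1L,
                             count_stat = c("mean", "median")) {
  count_stat <- match.arg(count_stat)
  require_stage(tbl, c("imputed", "valid"), "call_interactors")
  validate_protein_design(design)
  cols <- c(design$sample[design$group == "bait"],
            design$sample[design$group == "control"])
  m <- as.matrix(tbl[cols])
  if (anyNA(m)) {
    abort("Table still contains missing values; run impute_downshift() first.")
  }
  n_bait <- sum(design$group == "bait")
  n_control <- sum(design$group == "control")
  perms <- perm_assignments(n_bait, n_control)
  if (length(perms) < 2) {
    abort("Fewer than 2 distinct label permutations exist for this design.")
  }
  if (length(perms) > n_perm) {
    rng <- local_rng(seed)
    perms <- perms[rng(function() sample(length(perms), n_perm))]
  }
  obs <- row_t_stats(m, seq_len(n_bait), s0)
  null_abs <- vapply(perms, function(b) abs(row_t_stats(m, b, s0)$d),
                     numeric(nrow(m)))
  cand <- sort(abs(obs$d), decreasing = TRUE)
  if (count_stat == "mean") {
    # mean over permutations of #(|d| >= c) = pooled count / n_perm
    pooled <- sort(as.numeric(null_abs))
    cnt_ge <- length(pooled) - findInterval(cand, pooled, left.open = TRUE)
    perm_cnt <- cnt_ge / length(perms)
  } else {
    perm_cnt <- vapply(cand,
                       function(cc) median(colSums(null_abs >= cc)),
                       numeric(1))
  }
  fdr_curve <- perm_cnt / seq_along(cand)
  fdr_curve <- rev(cummin(rev(fdr_curve))) # monotone non-increasing in c
  ok <- which(fdr_curve <= fdr)
  cutoff <- if (length(ok) == 0) Inf else cand[max(ok)]
  cls <- ifelse(abs(obs$d) >= cutoff,
                ifelse(obs$d > 0, "enriched", "depleted"), "ns")
  out <- tibble(
    group_id = tbl$group_id,
    log2_enrichment = unname(obs$mean_diff),
    se = unname(obs$se),
    t_stat = unname(obs$t),
    p = unname(obs$p),
    d_stat = unname(obs$d),
    n_valid_bait = tbl[["n_valid_bait"]] %||% rep(NA_integer_, nrow(tbl)),
    n_valid_control = tbl[["n_valid_control"]] %||%
      rep(NA_integer_, nrow(tbl)),
    class = cls,
    significant = cls == "enriched"
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_perm_used") <- length(perms)
  attr(out, "params") <- list(s0 = s0, fdr = fdr, n_perm = n_perm,
                              seed = seed, count_stat = count_stat)
  class(out) <- c("volcano_result", class(out))
  out
}

#' Run the full interactome pipeline
#'
#' Chains [filter_protein_groups()], [log2_lfq()], [valid_value_filter()],
#' [impute_downshift()] and [call_interactors()] with the stated defaults.
#'
#' @inheritParams call_interactors
#' @inheritParams impute_downshift
#' @inheritParams valid_value_filter
#' @param tbl Raw protein-group table (stage `"raw"`).
#' @return A `volcano_result` (see [call_interactors()]).
#' @export
interactome_pipeline <- function(tbl, design, s0 = 0.1, fdr = 0.01,
                                 width = 0.3, downshift = 1.8,
                                 min_frac = 0.6, n_perm = 250, seed = 1L) {
  tbl |>
    filter_protein_groups() |>
    log2_lfq(design) |>
    valid_value_filter(design, min_frac = min_frac) |>
    impute_downshift(design, width = width, downshift = downshift,
                     seed = seed) |>
    call_interactors(design, s0 = s0, fdr = fdr, n_perm = n_perm,
                     seed = seed)
}

#' Identification/quantification bookkeeping
#'
#' Counts protein groups identified (non-zero intensity) in at least one
#' sample of either group, and groups quantified in both groups — the
#' usual "identified in either / quantified in both" summary reported for
#' AP-MS experiments.
#'
#' @param tbl Raw protein-group table (intensity scale, 0 = not
#'   quantified).
#' @param design Design table (`sample`, `group`).
#' @return One-row tibble: `n_groups`, `n_identified_either`,
#'   `n_quantified_both`.
#' @export
quantification_summary <- function(tbl, design) {
  validate_protein_design(design)
  bait <- design$sample[design$group == "bait"]
  ctrl <- design$sample[design$group == "control"]
  qb <- rowSums(as.matrix(tbl[bait]) > 0, na.rm = TRUE) > 0
  qc <- rowSums(as.matrix(tbl[ctrl]) > 0, na.rm = TRUE) > 0
  tibble(
    n_groups = nrow(tbl),
    n_identified_either = sum(qb | qc),
    n_quantified_both = sum(qb & qc)
  )
}

#' Volcano report table
#'
#' Flattens a [call_interactors()] result into a plain report tibble with
#' `-log10(p)` and optional user-supplied category tags for plot coloring.
#'
#' @param records A `volcano_result`.
#' @param annotations Optional tibble `group_id`, `category`.
#' @return Tibble: `group_id`, `log2_enrichment`, `neg_log10_p`, `d_stat`,
#'   `class`, `significant`, and `category` when annotations are given.
#' @export
enrichment_report <- function(records, annotations = NULL) {
  out <- tibble(
    group_id = records$group_id,
    log2_enrichment = records$log2_enrichment,
    neg_log10_p = -log10(records$p),
    d_stat = records$d_stat,
    class = records$class,
    significant = records$significant
  )
  if (!is.null(annotations)) {
    out <- left_join(out, annotations, by = "group_id")
  }
  out
}
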