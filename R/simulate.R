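# Seeded generators with planted ground truth. These define the study
# conditions under which the analysis modules are validated; every
# generator is a pure function of its arguments including `seed`.

#' Simulate a RIP-seq IP/input count matrix with planted enrichment
#'
#' Per-gene baseline means are log-normal; input counts are negative
#' binomial `NB(mean = mu_g * s_j, dispersion = alpha)`
#' (variance `mu + alpha mu^2`) and IP counts get the planted log2 fold
#' change: `NB(mean = mu_g * s_j * 2^delta_g)` with `delta_g = log2fc` for
#' the enriched fraction and 0 otherwise. Library-size factors are drawn
#' uniformly from `sf_range`.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_rep Replicates per condition (default 3, the usual RIP-seq
#'   design).
#' @param enriched_frac Fraction of genes with planted enrichment
#'   (default 0.05).
#' @param log2fc Planted log2 fold change: a single value (point mass) or
#'   `c(mu, sigma)` for a Normal effect distribution (default 3).
#' @param dispersion NB dispersion alpha (default 0.05).
#' @param mean_log,mean_sdlog Log-normal parameters of the baseline mean
#'   (defaults `log(200)` and 1).
#' @param sf_range Range of the uniform library-size factors
#'   (default `c(0.7, 1.4)`).
#' @param seed Integer seed (required).
#' @return List: `counts` (tibble, `gene_id` + samples), `design`
#'   (`sample`, `condition`, `replicate`), `truth` (`gene_id`, `enriched`,
#'   `true_log2fc`), `config`.
#' @export
simulate_ripseq <- function(n_genes = 2000, n_rep = 3, enriched_frac = 0.05,
                            log2fc = 3, dispersion = 0.05,
                            mean_log = log(200), mean_sdlog = 1,
                            sf_range = c(0.7, 1.4), seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (enriched_frac < 0 || enriched_frac > 1) {
    abort("`enriched_frac` must be in [0, 1].")
  }
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (n_rep < 1) abort("`n_rep` must be >= 1.")
  rng <- local_rng(seed)
  rng(function() {
    samples <- c(paste0("input_", seq_len(n_rep)),
                 paste0("IP_", seq_len(n_rep)))
    design <- tibble(
      sample = samples,
      condition = rep(c("input", "IP"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2)
    )
    sf <- runif(2 * n_rep, sf_range[1], sf_range[2])
    mu0 <- rlnorm(n_genes, mean_log, mean_sdlog)
    n_enr <- round(enriched_frac * n_genes)
    enriched <- sample(n_genes, n_enr)
    delta <- rep(0, n_genes)
    if (n_enr > 0) {
      delta[enriched] <- if (length(log2fc) == 2) {
        rnorm(n_enr, log2fc[1], log2fc[2])
      } else {
        log2fc
      }
    }
    x <- as.numeric(design$condition == "IP")
    mu <- outer(mu0, sf) * 2^outer(delta, x)
    y <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes)
    } else {
      matrix(stats::rpois(length(mu), mu), n_genes)
    }
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    counts <- as_tibble(as.data.frame(y))
    names(counts) <- samples
    counts <- dplyr::bind_cols(tibble(gene_id = gene_ids), counts)
    truth <- tibble(
      gene_id = gene_ids,
      enriched = seq_len(n_genes) %in% enriched,
      true_log2fc = delta
    )
    list(counts = counts, design = design, truth = truth,
         config = list(n_genes = n_genes, n_rep = n_rep,
                       enriched_frac = enriched_frac, log2fc = log2fc,
                       dispersion = dispersion, mean_log = mean_log,
                       mean_sdlog = mean_sdlog, sf_range = sf_range,
                       seed = seed))
  })
}

#' Simulate a label-free AP-MS protein-group table with planted interactors
#'
#' Latent log2 intensities are Normal with a per-group baseline
#' `Normal(base_mean, base_sd)` and within-group SD `within_sd`; planted
#' interactors get a bait-side shift of `effect` log2 units. Each latent
#' value is observed with logistic detection probability
#' `plogis(slope * (value - midpoint))` — missing-not-at-random, lower
#' intensity more often missing — and unobserved values are written as LFQ
#' intensity 0. A configurable fraction of groups carries exactly one
#' razor+unique peptide and a small fraction is flagged
#' reverse/contaminant, to exercise the evidence filter.
#'
#' @param n_groups Number of protein groups (default 1000).
#' @param n_bait,n_control Replicates per group (defaults 6 and 3).
#' @param interactor_frac Fraction of planted interactors (default 0.05).
#' @param effect Planted bait shift in log2 units (default 3).
#' @param within_sd Within-group SD in log2 units (default 0.5).
#' @param base_mean,base_sd Baseline intensity distribution on the log2
#'   scale (defaults 26 and 3, the typical LFQ range).
#' @param detect_mid,detect_slope Logistic detection midpoint and slope
#'   (defaults 21.5 — 1.5 SD below the mean intensity — and 1).
#' @param frac_single_peptide Fraction of groups with exactly one
#'   razor+unique peptide (default 0.05).
#' @param frac_flagged Fraction flagged reverse or contaminant
#'   (default 0.02).
#' @param seed Integer seed (required).
#' @return List: `table` (raw-stage protein-group tibble), `design`,
#'   `truth` (`group_id`, `interactor`, `true_effect`), `config`.
#' @export
simulate_proteome <- function(n_groups = 1000, n_bait = 6, n_control = 3,
                              interactor_frac = 0.05, effect = 3,
                              within_sd = 0.5, base_mean = 26, base_sd = 3,
                              detect_mid = 21.5, detect_slope = 1,
                              frac_single_peptide = 0.05,
                              frac_flagged = 0.02, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_bait < 2 || n_control < 2) abort("Group sizes must be >= 2.")
  if (interactor_frac < 0 || interactor_frac > 1) {
    abort("`interactor_frac` must be in [0, 1].")
  }
  rng <- local_rng(seed)
  rng(function() {
    samples <- c(paste0("bait_", seq_len(n_bait)),
                 paste0("control_", seq_len(n_control)))
    design <- tibble(
      sample = samples,
      group = rep(c("bait", "control"), c(n_bait, n_control))
    )
    base <- rnorm(n_groups, base_mean, base_sd)
    n_int <- round(interactor_frac * n_groups)
    planted <- sample(n_groups, n_int)
    shift <- rep(0, n_groups)
    shift[planted] <- effect
    lat <- cbind(
      matrix(rnorm(n_groups * n_bait, base + shift, within_sd), n_groups),
      matrix(rnorm(n_groups * n_control, base, within_sd), n_groups)
    )
    p_det <- stats::plogis(detect_slope * (lat - detect_mid))
    observed <- matrix(rbinom(length(lat), 1, p_det) == 1, n_groups)
    lfq <- ifelse(observed, 2^lat, 0)
    group_ids <- sprintf("grp_%04d", seq_len(n_groups))
    razor <- 2L + stats::rpois(n_groups, 4)
    razor[sample(n_groups, round(frac_single_peptide * n_groups))] <- 1L
    flags <- rep(FALSE, n_groups)
    flags[sample(n_groups, round(frac_flagged * n_groups))] <- TRUE
    rev_flag <- flags & runif(n_groups) < 0.5
    con_flag <- flags & !rev_flag
    tbl <- dplyr::bind_cols(
      tibble(group_id = group_ids,
             razor_unique_peptides = razor,
             reverse = rev_flag,
             contaminant = con_flag),
      as_tibble(as.data.frame(lfq, col.names = samples))
    )
    names(tbl)[-(1:4)] <- samples
    truth <- tibble(
      group_id = group_ids,
      interactor = seq_len(n_groups) %in% planted,
      true_effect = shift
    )
    list(table = set_stage(tbl, "raw"), design = design, truth = truth,
         config = list(n_groups = n_groups, n_bait = n_bait,
                       n_control = n_control,
                       interactor_frac = interactor_frac, effect = effect,
                       within_sd = within_sd, base_mean = base_mean,
                       base_sd = base_sd, detect_mid = detect_mid,
                       detect_slope = detect_slope,
                       frac_single_peptide = frac_single_peptide,
                       frac_flagged = frac_flagged, seed = seed))
  })
}

#' Simulate a gene-category annotation with an over-represented category
#'
#' Builds an annotation universe in which each category covers a stated
#' background fraction of genes, and the focal (first) category is
#' over-represented within a supplied target set by `enrichment_factor`.
#' With the defaults (3% background, factor 8) about 24% of the targets
#' fall in the focal category.
#'
#' @param n_genes Universe size (default 6000, a yeast-scale
#'   transcriptome).
#' @param category_fracs Named numeric vector of background fractions per
#'   category, summing to at most 1 (default
#'   `c(cell_wall = 0.03, other = 0.20)`); the first is the focal
#'   category.
#' @param target_ids Character vector of target gene ids (subset of the
#'   generated universe `gene_0001...`); may be `NULL` for no planting.
#' @param enrichment_factor Multiplier of the focal background fraction
#'   within the target set (default 8).
#' @param seed Integer seed (required).
#' @return List: `annotation` (tibble `gene_id`, `category`), `universe`
#'   (character), `config`.
#' @export
simulate_annotation <- function(n_genes = 6000,
                                category_fracs = c(cell_wall = 0.03,
                                                   other = 0.20),
                                target_ids = NULL, enrichment_factor = 8,
                                seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (sum(category_fracs) > 1) {
    abort("Category fractions must sum to at most 1.")
  }
  focal_frac <- category_fracs[1]
  if (focal_frac * enrichment_factor > 1) {
    abort("Infeasible inflation: focal fraction times factor exceeds 1.")
  }
  rng <- local_rng(seed)
  rng(function() {
    universe <- sprintf("gene_%04d", seq_len(n_genes))
    target_ids <- unique(target_ids)
    if (length(setdiff(target_ids, universe))) {
      abort("`target_ids` must be drawn from the generated universe.")
    }
    rows <- list()
    for (i in seq_along(category_fracs)) {
      cat_name <- names(category_fracs)[i]
      frac <- category_fracs[i]
      p <- rep(frac, n_genes)
      if (i == 1 && length(target_ids)) {
        p[universe %in% target_ids] <- frac * enrichment_factor
      }
      member <- runif(n_genes) < p
      rows[[i]] <- tibble(gene_id = universe[member], category = cat_name)
    }
    list(annotation = bind_rows(rows), universe = universe,
         config = list(n_genes = n_genes, category_fracs = category_fracs,
                       enrichment_factor = enrichment_factor, seed = seed))
  })
}
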