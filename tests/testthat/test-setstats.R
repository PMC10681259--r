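test_that("hypergeometric tail reproduces exact small cases", {
  expect_equal(hypergeometric_tail(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_tail(50, 50, 10, 4), 1) # K = N: certain
  # N=10, K=4, n=5, k=3: exhaustive enumeration over C(10,5) draws
  draws <- combn(10, 5)
  hits <- sum(apply(draws, 2, function(d) sum(d <= 4) >= 3))
  expect_equal(hypergeometric_tail(10, 4, 5, 3), hits / ncol(draws))
  expect_equal(hits / ncol(draws), 66 / 252)
})

test_that("hypergeometric tail matches the log-gamma summation oracle", {
  set.seed(110)
  for (rep in 1:25) {
    N <- sample(20:2000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    got <- hypergeometric_tail(N, K, n, k)
    want <- oracle_hyper_tail(N, K, n, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # deep tail: log-space result stays finite and matches the oracle
  lp <- hypergeometric_tail(6000, 180, 146, 100, log_p = TRUE)
  expect_true(is.finite(lp))
  expect_equal(lp, log(oracle_hyper_tail(6000, 180, 146, 100)),
               tolerance = 1e-9)
})

test_that("upper and lower tails are complementary", {
  # P[X >= k] + P[X <= k] = 1 + P[X = k]
  for (k in 0:4) {
    up <- hypergeometric_tail(10, 4, 5, k)
    lo <- phyper(k, 4, 6, 5)
    pk <- dhyper(k, 4, 6, 5)
    expect_equal(up + lo, 1 + pk, tolerance = 1e-14)
  }
})

test_that("the tail is non-increasing in k", {
  p <- vapply(0:20, function(k) hypergeometric_tail(100, 30, 20, k),
              numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("parameter violations are rejected", {
  expect_error(hypergeometric_tail(10, 11, 5, 3), "K <= N")
  expect_error(hypergeometric_tail(10, 4, 11, 3), "n <= N")
  expect_error(hypergeometric_tail(10, 4, 5, 5), "min\\(n, K\\)")
})

test_that("category enrichment reproduces a constructed composition", {
  # universe 6000, one 180-gene category (3%), query of 146 with 35 inside
  universe <- sprintf("g%04d", 1:6000)
  category <- universe[1:180]
  query <- c(universe[1:35], universe[1000:1110])
  ann <- tibble::tibble(gene_id = category, category = "cw")
  res <- category_enrichment(ann, query, universe = universe)
  expect_equal(res$k, 35)
  expect_equal(res$n, 146)
  expect_equal(res$fraction, 35 / 146)
  expect_equal(round(res$fraction, 4), 0.2397)
  expect_equal(res$p, oracle_hyper_tail(6000, 180, 146, 35),
               tolerance = 1e-12)

  # query identical to the category: k = n, minimal p for the geometry
  res2 <- category_enrichment(ann, category, universe = universe)
  expect_equal(res2$k, res2$n)
  expect_equal(res2$p, oracle_hyper_tail(6000, 180, 180, 180),
               tolerance = 1e-12)

  # disjoint query: k = 0, p = 1
  res3 <- category_enrichment(ann, universe[3000:3050],
                              universe = universe)
  expect_equal(res3$k, 0)
  expect_equal(res3$p, 1)
})

test_that("enrichment p-values are invariant under gene-id relabeling", {
  set.seed(111)
  universe <- sprintf("g%03d", 1:300)
  ann <- tibble::tibble(
    gene_id = sample(universe, 120, replace = FALSE),
    category = rep(c("a", "b"), each = 60)
  )
  query <- sample(universe, 40)
  res <- category_enrichment(ann, query, universe = universe)
  # bijective relabeling
  map <- setNames(sprintf("x%03d", sample(300)), universe)
  res2 <- category_enrichment(
    dplyr::mutate(ann, gene_id = unname(map[gene_id])),
    unname(map[query]),
    universe = unname(map[universe])
  )
  expect_equal(res2$p, res$p)
  expect_equal(res2$k, res$k)
})

test_that("query genes outside the universe are dropped with a warning", {
  ann <- tibble::tibble(gene_id = c("a", "b"), category = "c1")
  expect_warning(
    res <- category_enrichment(ann, c("a", "zzz"),
                               universe = c("a", "b", "d")),
    "dropped"
  )
  expect_equal(res$n, 1)
  expect_error(category_enrichment(ann, "a", universe = character()),
               "Empty universe")
})

test_that("set intersection and overlap behave as set algebra requires", {
  expect_equal(core_intersection(list(c("b", "a"))), c("a", "b"))
  expect_equal(core_intersection(list(c("a", "b"), c("c"))), character(0))
  expect_equal(
    core_intersection(list(c("a", "b", "c"), c("b", "c", "d"),
                           c("c", "b"))),
    c("b", "c")
  )
  expect_equal(overlap_count(c("a", "b"), c("a", "b"))$k, 2)
  # symmetry
  set.seed(112)
  u <- sprintf("g%03d", 1:100)
  a <- sample(u, 20)
  b <- sample(u, 20)
  expect_equal(overlap_count(a, b, u)$k, overlap_count(b, a, u)$k)
  got <- overlap_count(a, b, u)
  expect_equal(got$p, oracle_hyper_tail(100, 20, 20, got$k),
               tolerance = 1e-12)
})

test_that("the consensus Ssd1 target fixture gives the 8-of-11 overlap", {
  core <- ssd1_core_targets()
  expect_equal(nrow(core), 11)
  ov <- overlap_count(core$gene, core$gene[core$eif2a_target])
  expect_equal(ov$k, 8)
})

test_that("densitometry fold changes and t-test match a hand computation", {
  # identical conditions: fold change 1, p near 1
  same <- tibble::tibble(
    condition = rep(c("overexpression", "control"), each = 3),
    replicate = rep(1:3, 2),
    target = rep(4, 6), reference = rep(8, 6)
  )
  r0 <- densitometry_fold_change(same)
  expect_equal(r0$fold_change, rep(1, 3))
  expect_equal(attr(r0, "p"), 1, tolerance = 1e-9)

  # OE relative abundances (0.5, 0.45, 0.55) vs control (1, 1, 1)
  tbl <- tibble::tibble(
    condition = rep(c("overexpression", "control"), each = 3),
    replicate = rep(1:3, 2),
    target = c(5, 4.5, 5.5, 10, 10, 10),
    reference = rep(10, 6)
  )
  res <- densitometry_fold_change(tbl)
  expect_equal(res$fold_change, c(0.5, 0.45, 0.55))
  # hand oracle: one-sample t of log fold changes against 0
  lf <- log(c(0.5, 0.45, 0.55))
  t_hand <- mean(lf) / (sd(lf) / sqrt(3))
  expect_equal(attr(res, "t"), t_hand, tolerance = 1e-12)
  expect_equal(attr(res, "p"), 2 * pt(-abs(t_hand), 2), tolerance = 1e-12)
  expect_equal(attr(res, "mean_fold_change"), 0.5)

  # doubling one condition's reference halves its relative abundances
  tbl2 <- tbl
  tbl2$reference[tbl2$condition == "overexpression"] <- 20
  res2 <- densitometry_fold_change(tbl2)
  expect_equal(res2$fold_change, res$fold_change / 2)

  # zero reference is an error
  bad <- tbl
  bad$reference[1] <- 0
  expect_error(densitometry_fold_change(bad), "> 0")
})
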