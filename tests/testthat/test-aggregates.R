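test_that("quantile normalization reproduces the worked example and invariants", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qn <- quantile_normalize(matrix_as_omics(m))
  expect_equal(qn$s1, c(2.5, 3.5, 4.5))
  expect_equal(qn$s2, c(2.5, 3.5, 4.5))

  # identical columns unchanged; idempotence; equal column means
  m2 <- matrix(rep(c(2, 7, 4, 9), 2), 4, 2,
               dimnames = list(letters[1:4], c("s1", "s2")))
  qn2 <- quantile_normalize(matrix_as_omics(m2))
  expect_equal(omics_as_matrix(qn2), m2)

  set.seed(14)
  m3 <- matrix(rnorm(200 * 5, 20, 3), 200, 5,
               dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:5)))
  qn3 <- quantile_normalize(matrix_as_omics(m3))
  cm <- colMeans(omics_as_matrix(qn3))
  expect_lt(diff(range(cm)), 1e-9)
  expect_equal(quantile_normalize(qn3), qn3, tolerance = 1e-12)
  # columns share the sorted multiset
  sm <- apply(omics_as_matrix(qn3), 2, sort)
  expect_lt(max(abs(sm - sm[, 1])), 1e-12)
})

test_that("quantile normalization matches limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(25)
  m <- matrix(rnorm(150 * 4, 22, 2), 150, 4,
              dimnames = list(sprintf("p%03d", 1:150), sprintf("s%d", 1:4)))
  mine <- omics_as_matrix(quantile_normalize(matrix_as_omics(m)))
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9)
})

agg_samples <- function(n = 3) {
  tibble::tibble(sample_id = c(sprintf("TH_%d", 1:n), sprintf("Pellet_%d", 1:n)),
                 label = rep(c("TH", "Pellet"), each = n))
}

test_that("aggregate enrichment calls injected shifts and respects filters", {
  # identical pellet and homogenate: fc ~ 0, nothing enriched
  set.seed(5)
  base <- matrix(rnorm(100 * 3, 25, 2), 100, 3)
  m <- cbind(base, base)
  dimnames(m) <- list(sprintf("p%03d", 1:100),
                      c(sprintf("TH_%d", 1:3), sprintf("Pellet_%d", 1:3)))
  enr <- aggregate_enrichment(matrix_as_omics(m), agg_samples())
  expect_true(all(abs(enr$log2fc) < 1e-9))
  expect_false(any(enr$enriched))

  # a protein quantified in < 2 replicates of one label is dropped
  m2 <- m + matrix(rnorm(length(m), 0, 0.1), nrow(m))
  m2["p001", c("Pellet_1", "Pellet_2")] <- NA
  enr2 <- aggregate_enrichment(matrix_as_omics(m2), agg_samples())
  expect_false("p001" %in% enr2$feature_id)
})

test_that("a +2 log2 pellet shift is recovered in nearly all seeds", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(s, {
      base <- rnorm(200, 25, 2)
      m <- cbind(matrix(rnorm(200 * 3, base, 0.2), 200),
                 matrix(rnorm(200 * 3, base + c(2, rep(0, 199)), 0.2), 200))
      dimnames(m) <- list(sprintf("p%03d", 1:200),
                          c(sprintf("TH_%d", 1:3), sprintf("Pellet_%d", 1:3)))
      enr <- aggregate_enrichment(matrix_as_omics(m), agg_samples())
      enr$enriched[enr$feature_id == "p001"]
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null aggregate data pass the cutoffs at the nominal rate", {
  agg <- generate_aggregate_experiment(2000, enriched_set = character(), seed = 8)
  enr <- aggregate_enrichment(agg$data, agg$samples)
  frac_p <- mean(enr$p < 0.05)
  expect_gte(frac_p, 0.03)
  expect_lte(frac_p, 0.07)
  # enrichment additionally needs the fold-change cutoff
  expect_lte(mean(enr$enriched), frac_p)
})

test_that("biophysical scores follow their closed forms", {
  expect_equal(clever_score("negative", 0.8), -0.8)
  expect_equal(clever_score("indeterminate", NA), 0)
  expect_equal(clever_score("positive", 0.55), 0.55)
  # odd under label swap at equal probability
  expect_equal(clever_score("positive", 0.9), -clever_score("negative", 0.9))
  expect_error(clever_score("positive", 0.3), "0.5")
  expect_equal(s2d_score(40, 100), 0.4)
  expect_equal(s2d_score(0, 50), 0)
  expect_equal(s2d_score(77, 77), 1)
  expect_error(s2d_score(5, 0), "n_residues")
  expect_error(s2d_score(10, 5), "n_coil")
})

test_that("extreme-tail comparison: degenerate, null and linked cases", {
  set.seed(9)
  dat <- tibble::tibble(feature_id = sprintf("p%04d", 1:1000),
                        log2fc = rnorm(1000), score = 1)
  res <- compare_extremes(dat)
  expect_equal(res$d, 0)
  expect_equal(res$p, 1)

  # scores equal to enrichment separate the tails decisively
  dat2 <- dat
  dat2$score <- dat2$log2fc
  expect_lt(compare_extremes(dat2)$p, 1e-6)

  # independence: p uniform over seeds (tails large enough for a smooth
  # p-value grid)
  ps <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      d <- tibble::tibble(feature_id = sprintf("p%03d", 1:600),
                          log2fc = rnorm(600), score = rnorm(600))
      compare_extremes(d)$p
    })
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(compare_extremes(dat[1:20, ]), "min_tail")
})

test_that("score_link = 0 leaves scores independent of enrichment", {
  agg <- generate_aggregate_experiment(2000, sprintf("prot_%04d", 1:200),
                                       score_link = 0, seed = 12)
  joined <- dplyr::inner_join(
    tibble::tibble(feature_id = names(agg$truth$shift), shift = agg$truth$shift),
    agg$scores, by = "feature_id")
  expect_lt(abs(cor(joined$shift, joined$s2d_score)), 0.1)
  expect_lt(abs(cor(joined$shift, joined$clever_score)), 0.1)
})

test_that("Fisher set enrichment matches enumeration and ranks complexes", {
  # [[3,1],[1,3]] two-sided p ~ 0.486: set of 4 with 3 enriched,
  # universe 8 with 4 enriched
  universe <- sprintf("p%d", 1:8)
  catalog <- list(s = universe[1:4])
  enriched <- universe[c(1, 2, 3, 5)]
  res <- set_enrichment_in_aggregates(enriched, universe, catalog)
  expect_equal(res$tests$p, 0.4857143, tolerance = 1e-6)
  expect_equal(res$tests$p, fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               tolerance = 1e-12)

  # enumeration over all 2x2 tables with the same margins, N <= 30
  set.seed(33)
  for (i in 1:10) {
    N <- sample(10:30, 1)
    uni <- sprintf("q%02d", seq_len(N))
    inset <- sample(uni, sample(3:6, 1))
    enr <- sample(uni, sample(3:10, 1))
    a <- length(intersect(inset, enr))
    K <- length(inset); n <- length(enr)
    pmf <- vapply(max(0, n + K - N):min(K, n), function(k) {
      choose(K, k) * choose(N - K, n - k) / choose(N, n)
    }, numeric(1))
    p_exp <- sum(pmf[pmf <= pmf[a - max(0, n + K - N) + 1] * (1 + 1e-7)])
    got <- set_enrichment_in_aggregates(enr, uni, list(s = inset))$tests$p
    expect_equal(got, p_exp, tolerance = 1e-9)
  }

  # ranking needs >= 3 quantified members
  enrichment <- tibble::tibble(feature_id = universe, log2fc = c(3, 2, 1, 0, -1, -2, 1, 2))
  res2 <- set_enrichment_in_aggregates(enriched, universe,
                                       list(big = universe[1:4], small = universe[1:2]),
                                       enrichment = enrichment)
  expect_equal(res2$ranking$complex_id, "big")
  expect_equal(res2$ranking$median_log2fc, 1.5)
})

test_that("evidence filter keeps proteins with enough peptides and replicates", {
  ev <- tibble::tibble(
    feature_id = c("a", "a", "b", "b", "c"),
    replicate = c(1, 2, 1, 2, 1),
    n_unique_peptides = c(3, 2, 1, 5, 2)
  )
  expect_setequal(evidence_filter(ev, min_replicates = 2), "a")
  expect_setequal(evidence_filter(ev, min_replicates = 1), c("a", "b", "c"))
})
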