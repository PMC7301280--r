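test_that("PSM filtering applies the score, flag and reporter-floor rules", {
  rep10 <- function(v) matrix(v, 1, 10)
  base <- make_psms(matrix(2000, 6, 10))
  base$search_score <- c(14.9, 15, 100, 50, 50, 50)
  base$is_reverse[5] <- TRUE
  base$is_contaminant[6] <- TRUE
  out <- filter_psms(base)
  expect_equal(out$psm_id, c("psm002", "psm003", "psm004"))
  rep_report <- attr(out, "filter_report")
  expect_equal(rep_report$n[rep_report$criterion == "reverse_or_contaminant"], 2)
  expect_equal(rep_report$n[rep_report$criterion == "low_search_score"], 1)

  # all reporters at 999 -> discarded; one channel at the floor -> retained
  low <- make_psms(rbind(rep(999, 10), c(rep(999, 9), 1000)))
  out2 <- filter_psms(low)
  expect_equal(out2$psm_id, "psm002")

  # a reverse hit is discarded regardless of its score
  rev_hit <- make_psms(matrix(2000, 2, 10), score = 100)
  rev_hit$is_reverse[1] <- TRUE
  expect_equal(filter_psms(rev_hit)$psm_id, "psm002")

  # idempotence (filtered rows pass unchanged through a second filter)
  expect_equal(filter_psms(out), out, ignore_attr = TRUE)
  expect_error(filter_psms(make_psms(matrix(1, 1, 10), score = 1)), "no PSMs")
})

test_that("protein-group summarization takes medians of complete unique peptides", {
  v <- 2^(1:10 / 2) * 1000
  reps <- rbind(v, v, v)
  psms <- make_psms(reps, peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"))
  pg <- summarize_protein_groups(psms, center = FALSE)
  expect_equal(nrow(pg), 1)
  expect_equal(unlist(pg[1, -1], use.names = FALSE), log2(v), tolerance = 1e-12)

  # a zero in one channel excludes that peptide entirely
  reps2 <- rbind(v, v, replace(v, 7, 0))
  psms2 <- make_psms(reps2, peptide = c("AAAAAAAAK", "CCCCCCCCK", "EEEEEEEEK"))
  pg2 <- summarize_protein_groups(psms2, center = FALSE)
  expect_equal(unlist(pg2[1, -1], use.names = FALSE), log2(v), tolerance = 1e-12)
  counts <- attr(pg2, "peptide_counts")
  expect_equal(counts$n_unique_peptides, 2)

  # fewer than two unique peptides drops the protein
  one <- make_psms(matrix(v, 1, 10), peptide = "AAAAAAAAK")
  pg3 <- summarize_protein_groups(one)
  expect_equal(nrow(pg3), 0)
  expect_true("P1" %in% attr(pg3, "dropped"))
})

test_that("protein rows are invariant to PSM ordering", {
  g <- generate_psm_table(generate_protein_sequences(10, seed = 3), seed = 3)
  f <- filter_psms(g$psms)
  pg1 <- summarize_protein_groups(f)
  set.seed(1)
  pg2 <- summarize_protein_groups(f[sample(nrow(f)), ])
  expect_equal(pg1, pg2, ignore_attr = TRUE)
})

test_that("tryptic digestion reproduces hand-worked cases", {
  expect_equal(digest_tryptic("MKWVTFISLLK"), c("MK", "WVTFISLLK"))
  expect_equal(digest_and_count_observable("MKWVTFISLLK"), 1)  # only WVTFISLLK in 8..25
  # K before P is not cleaved: single 13-mer
  expect_equal(digest_tryptic("AAAKPAAAAAAAR"), "AAAKPAAAAAAAR")
  expect_equal(digest_and_count_observable("AAAKPAAAAAAAR"), 1)
  expect_equal(digest_and_count_observable("AAAA"), 0)
  expect_equal(digest_and_count_observable(""), 0)
})

test_that("digestion agrees with a brute-force substring enumerator", {
  set.seed(17)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:100) {
    s <- paste(sample(aa, sample(1:60, 1), replace = TRUE), collapse = "")
    expect_equal(digest_and_count_observable(s), brute_force_observable(s),
                 info = s)
  }
})

test_that("precursor splitting conserves totals and medians ratios", {
  # one PSM with ratios 0.5/0.3/0.2 of 1e6
  psms <- make_psms(matrix(c(0.5, 0.3, 0.2) * 5000, 1, 3),
                    peptide = "AAAAAAAAK", precursor = 1e6)
  sp <- split_precursor_to_channels(psms, correct = FALSE)
  expect_equal(unlist(sp[1, c("channel_01", "channel_02", "channel_03")],
                      use.names = FALSE), c(5e5, 3e5, 2e5))

  # two PSMs of one peptide: per-channel medians, renormalized to sum 1
  psms2 <- make_psms(rbind(c(0.5, 0.5, 0) * 1000, c(0.3, 0.7, 0) * 1000),
                     peptide = rep("AAAAAAAAK", 2), precursor = c(600, 400))
  sp2 <- split_precursor_to_channels(psms2, correct = FALSE)
  got <- unlist(sp2[1, c("channel_01", "channel_02", "channel_03")],
                use.names = FALSE)
  expect_equal(got / sum(got), c(0.4, 0.6, 0))
  expect_equal(sum(got), 1000)

  # symmetric channels give identical correction factors
  psms3 <- make_psms(matrix(1000, 4, 4),
                     peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK", "EEEEEEEEK"))
  sp3c <- split_precursor_to_channels(psms3, correct = TRUE)
  sp3 <- split_precursor_to_channels(psms3, correct = FALSE)
  chan <- grep("^channel_", names(sp3), value = TRUE)
  ratio <- as.matrix(sp3c[chan]) / as.matrix(sp3[chan])
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("split conservation holds on realistic generated tables", {
  g <- generate_psm_table(generate_protein_sequences(15, seed = 5), seed = 5)
  f <- filter_psms(g$psms)
  sp <- split_precursor_to_channels(f, correct = FALSE)
  chan <- grep("^channel_", names(sp), value = TRUE)
  rel_err <- abs(rowSums(as.matrix(sp[chan])) / sp$precursor_total - 1)
  expect_lt(max(rel_err), 1e-9)
})

test_that("iBAQ follows the stated arithmetic and scale invariance", {
  # 2 peptides at 3e5 each over 4 observable peptides -> 1.5e5
  sp <- tibble::tibble(
    protein_group_id = c("P1", "P1"),
    peptide_sequence = c("AAAAAAAAK", "CCCCCCCCK"),
    precursor_total = c(3e5, 3e5),
    channel_01 = c(3e5, 3e5),
    is_unique_peptide = TRUE
  )
  ib <- compute_ibaq(sp, c(P1 = 4), normalize = FALSE)
  expect_equal(ib$channel_01, 1.5e5)

  # doubling one sample's intensities is absorbed by median normalization
  g <- generate_psm_table(generate_protein_sequences(12, seed = 7), seed = 7)
  f <- filter_psms(g$psms)
  sp1 <- split_precursor_to_channels(f)
  nobs <- vapply(generate_protein_sequences(12, seed = 7),
                 digest_and_count_observable, integer(1))
  ib1 <- compute_ibaq(sp1, nobs)
  sp2 <- sp1
  sp2$channel_03 <- sp2$channel_03 * 2
  ib2 <- compute_ibaq(sp2, nobs)
  expect_equal(omics_as_matrix(ib1), omics_as_matrix(ib2), tolerance = 1e-9)

  # zero observable count excludes the protein
  ib3 <- compute_ibaq(sp, c(P1 = 0), normalize = FALSE)
  expect_equal(nrow(ib3), 0)
  expect_equal(attr(ib3, "excluded"), "P1")
})

test_that("iBAQ pipeline matches an independent reference implementation", {
  seqs <- generate_protein_sequences(20, seed = 9)
  g <- generate_psm_table(seqs, seed = 9)
  f <- filter_psms(g$psms)
  nobs <- vapply(seqs, digest_and_count_observable, integer(1))
  sp <- split_precursor_to_channels(f, correct = TRUE)
  mine <- omics_as_matrix(compute_ibaq(sp, nobs, normalize = FALSE))
  ref <- reference_ibaq(f, nobs, correct = TRUE)
  ref <- ref[rownames(mine), , drop = FALSE]
  expect_equal(unname(mine), unname(ref), tolerance = 1e-9)
})

test_that("generated PSM tables honour their contracts", {
  seqs <- generate_protein_sequences(20, seed = 13)
  g <- generate_psm_table(seqs, decoy = 0, frac_low_score = 0.1, seed = 13)
  expect_false(any(g$psms$is_reverse))
  # every target peptide is a tryptic substring of its source protein
  tgt <- g$psms[!g$psms$is_contaminant, ]
  ok <- vapply(seq_len(nrow(tgt)), function(i) {
    tgt$peptide_sequence[i] %in% digest_tryptic(seqs[[tgt$protein_group_id[i]]])
  }, logical(1))
  expect_true(all(ok))
  # determinism
  g2 <- generate_psm_table(seqs, decoy = 0, frac_low_score = 0.1, seed = 13)
  expect_identical(g$psms, g2$psms)
  # the low-score mixture is removed at the expected rate (binomial slack)
  n_low <- sum(tgt$search_score < 15)
  expect_gt(stats::binom.test(n_low, nrow(tgt), 0.1)$p.value, 1e-4)
})
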