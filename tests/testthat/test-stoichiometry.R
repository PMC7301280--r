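test_that("complex-relative normalization centres on the trimmed mean", {
  # one complex, one sample: {1,2,3,4,100} -> trimmed mean 3 (drop 1 and 100)
  m <- matrix(c(1, 2, 3, 4, 100), 5, 1,
              dimnames = list(paste0("p", 1:5), "s1"))
  res <- normalize_to_complex(matrix_as_omics(m), list(c1 = paste0("p", 1:5)))
  expect_equal(res$s1, c(-2, -1, 0, 1, 97))

  # all members equal -> all zero; location shifts cancel
  m2 <- matrix(5, 6, 2, dimnames = list(paste0("p", 1:6), c("s1", "s2")))
  res2 <- normalize_to_complex(matrix_as_omics(m2), list(c1 = paste0("p", 1:6)))
  expect_true(all(as.matrix(res2[c("s1", "s2")]) == 0))
  m3 <- matrix(rnorm(12), 6, 2, dimnames = dimnames(m2))
  r3a <- normalize_to_complex(matrix_as_omics(m3), list(c1 = paste0("p", 1:6)))
  r3b <- normalize_to_complex(matrix_as_omics(sweep(m3, 2, c(3, -7), "+")),
                              list(c1 = paste0("p", 1:6)))
  expect_equal(r3a$s1, r3b$s1, tolerance = 1e-12)
  expect_equal(r3a$s2, r3b$s2, tolerance = 1e-12)

  # complexes under the member floor are skipped
  res4 <- normalize_to_complex(matrix_as_omics(m3),
                               list(small = paste0("p", 1:3),
                                    ok = paste0("p", 1:5)))
  expect_equal(attr(res4, "skipped"), "small")
  expect_equal(unique(res4$complex_id), "ok")
})

test_that("trimmed means of normalized member values are zero", {
  set.seed(21)
  m <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("p%02d", 1:40), sprintf("s%d", 1:6)))
  catalog <- list(c1 = sprintf("p%02d", 1:10), c2 = sprintf("p%02d", 11:25))
  res <- normalize_to_complex(matrix_as_omics(m), catalog)
  for (cid in names(catalog)) {
    sub <- as.matrix(res[res$complex_id == cid, sprintf("s%d", 1:6)])
    centred <- apply(sub, 2, proteoage:::trimmed_mean, trim = 0.2)
    expect_lt(max(abs(centred)), 1e-9)
  }
})

make_complex_cohort <- function(n_complexes = 100, size = 6, n = 4, noise = 0.2,
                                base_sd = 1.5, shift_members = integer(),
                                shift = 0, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("p%04d", seq_len(n_complexes * size))
    catalog <- split(ids, rep(seq_len(n_complexes), each = size))
    names(catalog) <- sprintf("c%03d", seq_len(n_complexes))
    base <- rnorm(length(ids), 20, base_sd)
    m <- matrix(rnorm(length(ids) * 2 * n, base, noise), length(ids), 2 * n,
                dimnames = list(ids, c(paste0("y", 1:n), paste0("o", 1:n))))
    # shift selected members of the first complex in the old group
    if (length(shift_members) > 0) {
      rows <- catalog[[1]][shift_members]
      m[rows, paste0("o", 1:n)] <- m[rows, paste0("o", 1:n)] + shift
    }
    list(data = matrix_as_omics(m), catalog = catalog,
         ga = paste0("o", 1:n), gb = paste0("y", 1:n))
  })
}

test_that("null complexes are called affected at no more than the nominal rate", {
  fracs <- vapply(1:20, function(s) {
    cc <- make_complex_cohort(n_complexes = 100, seed = s)
    norm <- normalize_to_complex(cc$data, cc$catalog)
    calls <- call_affected(norm, cc$ga, cc$gb)
    attr(calls, "fraction_affected")
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("a two-member 1.2-log2 stoichiometry shift is detected reliably", {
  hits <- vapply(1:40, function(s) {
    cc <- make_complex_cohort(n_complexes = 40, shift_members = 1:2,
                              shift = 1.2, seed = s)
    norm <- normalize_to_complex(cc$data, cc$catalog)
    calls <- call_affected(norm, cc$ga, cc$gb)
    calls$is_affected[calls$complex_id == "c001"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a single affected member does not call the complex", {
  # rule level: one member of the complex-relative table carries an
  # arbitrarily large shift; the >= 2-member rule never calls the complex
  withr::with_seed(41, {
    ids <- sprintf("p%02d", 1:12)
    rel <- matrix(rnorm(12 * 8, 0, 0.2), 12, 8,
                  dimnames = list(ids, c(paste0("y", 1:4), paste0("o", 1:4))))
    rel[1, paste0("o", 1:4)] <- rel[1, paste0("o", 1:4)] + 50
    norm <- dplyr::bind_cols(
      tibble::tibble(feature_id = paste0("c001::", ids),
                     complex_id = "c001", member_id = ids),
      tibble::as_tibble(rel))
    calls <- call_affected(norm, paste0("o", 1:4), paste0("y", 1:4))
    expect_false(calls$is_affected)
    expect_equal(calls$n_affected, 1)
  })

  # end to end at a typical effect size: the trimmed mean keeps co-members
  # centred and only the shifted member registers
  for (s in 1:5) {
    cc <- make_complex_cohort(n_complexes = 30, size = 10, shift_members = 1,
                              shift = 1.2, seed = s)
    norm <- normalize_to_complex(cc$data, cc$catalog)
    calls <- call_affected(norm, cc$ga, cc$gb)
    expect_false(calls$is_affected[calls$complex_id == "c001"])
  }
})

test_that("whole-complex abundance changes do not trigger stoichiometry calls", {
  cc <- make_complex_cohort(n_complexes = 30, seed = 3)
  m <- omics_as_matrix(cc$data)
  m[cc$catalog[["c001"]], cc$ga] <- m[cc$catalog[["c001"]], cc$ga] + 3
  norm <- normalize_to_complex(matrix_as_omics(m), cc$catalog)
  calls <- call_affected(norm, cc$ga, cc$gb)
  expect_false(calls$is_affected[calls$complex_id == "c001"])
})

test_that("complex IQR uses linear-interpolation quantiles", {
  tbl <- tibble::tibble(complex_id = "a", log2fc = c(1, 2, 3, 4))
  expect_equal(complex_iqr(tbl, min_members = 4)$iqr, 1.5)  # Q1 1.75, Q3 3.25
  tbl0 <- tibble::tibble(complex_id = "a", log2fc = rep(0, 6))
  expect_equal(complex_iqr(tbl0)$iqr, 0)
  # translation-invariant, scales with multiplicative spread
  set.seed(4)
  x <- rnorm(9)
  t1 <- tibble::tibble(complex_id = "a", log2fc = x)
  t2 <- tibble::tibble(complex_id = "a", log2fc = x + 5)
  t3 <- tibble::tibble(complex_id = "a", log2fc = x * 3)
  expect_equal(complex_iqr(t2)$iqr, complex_iqr(t1)$iqr)
  expect_equal(complex_iqr(t3)$iqr, 3 * complex_iqr(t1)$iqr)
  # member floor
  expect_equal(nrow(complex_iqr(tibble::tibble(complex_id = "a", log2fc = 1:4))), 0)
})

test_that("IQR comparison and ranking behave under identity and antisymmetry", {
  iqr <- tibble::tibble(complex_id = sprintf("c%02d", 1:10), iqr = (1:10) / 10)
  expect_equal(compare_iqr(iqr, iqr)$p, 1)
  rk <- rank_iqr_difference(iqr, iqr)
  expect_true(all(rk$delta_iqr == 0))
  expect_equal(attr(rk, "fraction_increased"), 0.5)

  set.seed(9)
  iqr_b <- iqr
  iqr_b$iqr <- iqr_b$iqr + runif(10, -0.2, 0.2)
  fwd <- rank_iqr_difference(iqr, iqr_b)
  rev_ <- rank_iqr_difference(iqr_b, iqr)
  expect_equal(fwd$complex_id, rev(rev_$complex_id))

  # an injected late-life loss ranks first
  iqr_c <- iqr
  iqr_c$iqr[iqr_c$complex_id == "c07"] <- iqr_c$iqr[iqr_c$complex_id == "c07"] + 2
  expect_equal(rank_iqr_difference(iqr, iqr_c)$complex_id[1], "c07")
})

test_that("IQR comparison detects a genuine dispersion increase", {
  set.seed(10)
  early <- tibble::tibble(complex_id = rep(sprintf("c%02d", 1:30), each = 8),
                          log2fc = rnorm(240, 0, 0.3))
  late <- tibble::tibble(complex_id = rep(sprintf("c%02d", 1:30), each = 8),
                         log2fc = rnorm(240, 0, 1.0))
  cmp <- compare_iqr(complex_iqr(early), complex_iqr(late))
  expect_lt(cmp$p, 0.001)
  expect_lt(cmp$median_a, cmp$median_b)
})
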