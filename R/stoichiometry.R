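#' Normalize member abundances to their complex mean
#'
#' Expresses each complex member's log2 abundance relative to the complex as
#' a whole: per sample and complex, the trimmed mean of the member log2
#' intensities is subtracted from each member's value. Changes in
#' complex-relative values reflect stoichiometry shifts rather than changes
#' of overall complex abundance. A protein belonging to several complexes
#' contributes one complex-relative row per complex.
#'
#' @param data Wide log2 tibble (`feature_id` + sample columns).
#' @param catalog Named list of member vectors (protein complexes).
#' @param trim Total trimmed fraction (default 0.2, i.e. 10% per tail); at
#'   least one value is dropped from each tail when the complex has >= 5
#'   quantified members.
#' @param min_members Minimum quantified members per complex (default 5);
#'   smaller complexes are skipped and listed in the `skipped` attribute.
#' @return Tibble with `feature_id` = `"<complex_id>::<member_id>"`, columns
#'   `complex_id` and `member_id`, and complex-relative log2 sample columns.
#' @export
normalize_to_complex <- function(data, catalog, trim = 0.2, min_members = 5) {
  m <- omics_as_matrix(data)
  skipped <- character()
  blocks <- purrr::imap(catalog, function(members, cid) {
    members <- intersect(members, rownames(m))
    if (length(members) < min_members) {
      skipped <<- c(skipped, cid)
      return(NULL)
    }
    sub <- m[members, , drop = FALSE]
    centre <- apply(sub, 2, trimmed_mean, trim = trim)
    rel <- sweep(sub, 2, centre, "-")
    out <- matrix_as_omics(rel)
    out$feature_id <- paste0(cid, "::", members)
    dplyr::bind_cols(out[1], tibble(complex_id = cid, member_id = members),
                     out[-1])
  })
  out <- bind_rows(blocks)
  attr(out, "skipped") <- skipped
  attr(out, "trim") <- trim
  out
}

# Symmetric trimmed mean: drop max(1, floor(n * trim / 2)) values per tail
# when n >= 5, else plain mean. Errors if trimming leaves nothing.
trimmed_mean <- function(x, trim = 0.2) {
  n <- length(x)
  if (n < 5) return(mean(x))
  k <- max(1L, floor(n * trim / 2))
  if (n - 2 * k < 1) abort("trim fraction leaves no values")
  xs <- sort(x)
  mean(xs[(k + 1):(n - k)])
}

#' Call complexes with affected stoichiometry
#'
#' Member-level differential analysis on complex-relative values
#' ([moderated_t_test()] on the output of [normalize_to_complex()]); a
#' complex is *affected* when at least `min_members_affected` members show a
#' significant stoichiometry change (BH-adjusted p below `adj_p` and absolute
#' log2 fold change above `min_abs_fc`).
#'
#' @param normalized Output of [normalize_to_complex()].
#' @param group_a,group_b Sample column names for the contrast (a vs b).
#' @param adj_p Member-level significance threshold (default 0.05).
#' @param min_abs_fc Member-level absolute log2 fold-change threshold
#'   (default 0.5).
#' @param min_members_affected Members required to call the complex (default 2).
#' @return Tibble of class `proteoage_stoich`: `complex_id`, `n_quantified`,
#'   `n_affected`, `is_affected`, `affected_members` (list column of member
#'   ids). The member-level differential table is in the `member_de`
#'   attribute and via [tidy()]; the affected fraction via [glance()].
#' @export
call_affected <- function(normalized, group_a, group_b, adj_p = 0.05,
                          min_abs_fc = 0.5, min_members_affected = 2) {
  stopifnot(all(c("complex_id", "member_id") %in% names(normalized)))
  de_input <- select(normalized, -"complex_id", -"member_id")
  de <- moderated_t_test(de_input, group_a, group_b)
  mem <- as_tibble(de) %>%
    left_join(select(normalized, "feature_id", "complex_id", "member_id"),
              by = "feature_id") %>%
    mutate(affected = .data$adj_p < !!adj_p & abs(.data$log2fc) > min_abs_fc)
  out <- mem %>%
    group_by(.data$complex_id) %>%
    summarise(
      n_quantified = dplyr::n(),
      n_affected = sum(.data$affected),
      affected_members = list(.data$member_id[.data$affected]),
      .groups = "drop"
    ) %>%
    mutate(is_affected = .data$n_affected >= min_members_affected)
  structure(out, class = c("proteoage_stoich", class(out)),
            member_de = mem,
            fraction_affected = mean(out$is_affected),
            thresholds = list(adj_p = adj_p, min_abs_fc = min_abs_fc,
                              min_members_affected = min_members_affected))
}

#' Interquartile range of member fold changes per complex
#'
#' The stoichiometry-dispersion statistic: the IQR (Q3 - Q1, type-7
#' linear-interpolation quantiles) of the log2 fold changes of a complex's
#' members. Computed per complex from a member-level fold-change table.
#'
#' @param member_fcs Tibble with columns `complex_id` and `log2fc` (one row
#'   per complex member), e.g. built from a `proteoage_de` result joined to
#'   a catalog.
#' @param min_members Minimum fold changes per complex (default 5).
#' @return Tibble: `complex_id`, `n_members`, `iqr`.
#' @export
complex_iqr <- function(member_fcs, min_members = 5) {
  member_fcs %>%
    group_by(.data$complex_id) %>%
    summarise(n_members = dplyr::n(),
              iqr = unname(diff(quantile(.data$log2fc, c(0.25, 0.75), type = 7))),
              .groups = "drop") %>%
    filter(.data$n_members >= min_members)
}

#' Compare per-complex IQRs between two contrasts
#'
#' Two-sided Wilcoxon rank-sum test on the two IQR vectors, restricted to
#' complexes present in both contrasts.
#'
#' @param iqr_a,iqr_b Outputs of [complex_iqr()] for the two contrasts.
#' @return One-row tibble: `n_complexes`, `median_a`, `median_b`, `w`, `p`.
#' @export
compare_iqr <- function(iqr_a, iqr_b) {
  shared <- intersect(iqr_a$complex_id, iqr_b$complex_id)
  a <- iqr_a$iqr[match(shared, iqr_a$complex_id)]
  b <- iqr_b$iqr[match(shared, iqr_b$complex_id)]
  if (length(shared) == 0) abort("no shared complexes")
  if (identical(a, b)) {
    p <- 1; w <- NA_real_
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    p <- wt$p.value; w <- unname(wt$statistic)
  }
  tibble(n_complexes = length(shared), median_a = median(a),
         median_b = median(b), w = w, p = p)
}

#' Rank complexes by IQR difference between contrasts
#'
#' Descending ranking of complexes by the late-minus-early change in member
#' fold-change IQR; identifies complexes whose stoichiometry degrades most in
#' late life.
#'
#' @param iqr_a Early contrast IQRs ([complex_iqr()] output).
#' @param iqr_b Late contrast IQRs.
#' @return Tibble ranked by `delta_iqr = iqr_b - iqr_a` (descending, ties
#'   broken by complex id): `complex_id`, `iqr_a`, `iqr_b`, `delta_iqr`,
#'   `rank`, `pct_change`. The fraction of complexes with `delta_iqr > 0`
#'   (ties counted half) is the `fraction_increased` attribute.
#' @export
rank_iqr_difference <- function(iqr_a, iqr_b) {
  shared <- intersect(iqr_a$complex_id, iqr_b$complex_id)
  if (length(shared) == 0) abort("no shared complexes")
  out <- tibble(
    complex_id = shared,
    iqr_a = iqr_a$iqr[match(shared, iqr_a$complex_id)],
    iqr_b = iqr_b$iqr[match(shared, iqr_b$complex_id)]
  ) %>%
    mutate(delta_iqr = .data$iqr_b - .data$iqr_a,
           pct_change = ifelse(.data$iqr_a > 0,
                               100 * .data$delta_iqr / .data$iqr_a, NA_real_)) %>%
    arrange(desc(.data$delta_iqr), .data$complex_id) %>%
    mutate(rank = row_number())
  frac <- mean(out$delta_iqr > 0) + 0.5 * mean(out$delta_iqr == 0)
  structure(out, fraction_increased = frac)
}
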