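#' Normalize SEC elution profiles
#'
#' Divides each protein's intensities by its total across fractions so every
#' retained row sums to 1; all-zero rows are dropped (listed in the
#' `dropped` attribute). Idempotent.
#'
#' @param data Wide tibble: `feature_id` plus fraction columns (non-negative
#'   intensities, fraction order = elution order).
#' @return Normalized tibble of the same shape.
#' @export
normalize_sec_profiles <- function(data) {
  m <- omics_as_matrix(data)
  if (any(m < 0, na.rm = TRUE)) abort("negative intensities")
  m[is.na(m)] <- 0
  tot <- rowSums(m)
  dropped <- rownames(m)[tot == 0]
  m <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
  out <- matrix_as_omics(m)
  attr(out, "dropped") <- dropped
  out
}

#' Within-complex pairwise co-elution correlations
#'
#' All pairwise Pearson correlations across fractions between members of the
#' same complex, for complexes with at least `min_members` quantified
#' members. Zeros count as informative absence; all fractions enter the
#' correlation.
#'
#' @param profiles Normalized SEC tibble ([normalize_sec_profiles()]).
#' @param catalog Named list of member vectors.
#' @param min_members Member floor (default 5).
#' @return Tibble: `complex_id`, `member_a`, `member_b`, `r` (one row per
#'   unordered member pair). Excluded complexes are in the `excluded`
#'   attribute.
#' @export
within_complex_correlations <- function(profiles, catalog, min_members = 5) {
  m <- omics_as_matrix(profiles)
  excluded <- character()
  rows <- purrr::imap(catalog, function(members, cid) {
    members <- intersect(members, rownames(m))
    if (length(members) < min_members) {
      excluded <<- c(excluded, cid)
      return(NULL)
    }
    cm <- suppressWarnings(cor(t(m[members, , drop = FALSE])))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    tibble(complex_id = cid,
           member_a = members[idx[, 1]], member_b = members[idx[, 2]],
           r = cm[idx])
  })
  out <- bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}

#' Random-complex null for co-elution
#'
#' Draws random protein sets whose sizes match the size multiset of the
#' eligible real complexes, computes their within-set pairwise correlations,
#' and compares the real and null correlation distributions by a two-sided
#' Wilcoxon rank-sum test. A draw that exactly reproduces a real complex's
#' member set is rejected and redrawn.
#'
#' @param profiles Normalized SEC tibble.
#' @param catalog Named list of member vectors.
#' @param n_draws Number of random sets (default 1000).
#' @param seed Integer seed; the null is reproducible given (input, seed).
#' @param min_members Member floor applied to the real complexes (default 5).
#' @return List: `real` (tibble from [within_complex_correlations()]), `null`
#'   (tibble `draw`, `r`), `p` (rank-sum p), `statistic`.
#' @export
random_complex_null <- function(profiles, catalog, n_draws = 1000, seed = 1,
                                min_members = 5) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  real <- within_complex_correlations(profiles, catalog, min_members)
  m <- omics_as_matrix(profiles)
  ids <- rownames(m)
  sizes <- purrr::map_int(catalog, ~ length(intersect(.x, ids)))
  sizes <- sizes[sizes >= min_members]
  if (length(sizes) == 0) abort("no eligible complexes")
  if (max(sizes) > length(ids)) abort("profile universe smaller than largest complex")
  real_sets <- lapply(catalog, function(x) sort(intersect(x, ids)))

  null <- withr::with_seed(seed, {
    bind_rows(purrr::map(seq_len(n_draws), function(d) {
      size <- sizes[((d - 1L) %% length(sizes)) + 1L]
      repeat {
        draw <- sample(ids, size)
        if (!any(vapply(real_sets, identical, logical(1), y = sort(draw)))) break
      }
      cm <- suppressWarnings(cor(t(m[draw, , drop = FALSE])))
      tibble(draw = d, r = cm[upper.tri(cm)])
    }))
  })
  wt <- suppressWarnings(wilcox.test(real$r, null$r, alternative = "two.sided"))
  list(real = real, null = null, p = wt$p.value,
       statistic = unname(wt$statistic))
}

#' Consensus elution profile of a complex
#'
#' Per fraction, the median over the quantified members' normalized profiles,
#' scaled so the maximum equals 1.
#'
#' @param profiles Normalized SEC tibble.
#' @param members Character vector of member ids.
#' @param min_members Quantified-member floor (default 5).
#' @return Numeric vector of length `n_fractions`, max exactly 1.
#' @export
complex_profile <- function(profiles, members, min_members = 5) {
  m <- omics_as_matrix(profiles)
  members <- intersect(members, rownames(m))
  if (length(members) < min_members) {
    abort(paste0("fewer than ", min_members, " quantified members"))
  }
  med <- apply(m[members, , drop = FALSE], 2, median)
  if (max(med) == 0) abort("all-zero consensus profile")
  med / max(med)
}

#' Detect an elution shift between two conditions
#'
#' Compares two profiles of one complex (or protein) on the same fraction
#' axis by the apex (argmax) shift and the intensity-weighted
#' centre-of-mass shift. Positive shifts mean later elution, i.e. lower
#' apparent molecular weight. Flagged when the absolute centre-of-mass shift
#' reaches `min_shift` fractions.
#'
#' @param profile_a Reference-condition profile (numeric vector).
#' @param profile_b Comparison-condition profile, same length.
#' @param min_shift Flagging threshold in fractions (default 2).
#' @return One-row tibble: `apex_a`, `apex_b`, `apex_shift`, `com_a`,
#'   `com_b`, `com_shift`, `flagged`.
#' @export
detect_elution_shift <- function(profile_a, profile_b, min_shift = 2.0) {
  if (length(profile_a) != length(profile_b)) abort("unequal fraction axes")
  if (max(profile_a) == min(profile_a) || max(profile_b) == min(profile_b)) {
    warn("flat profile: apex tie broken to first fraction")
  }
  apex <- function(p) which.max(p)  # earliest fraction on ties
  com <- function(p) {
    if (sum(p) == 0) abort("all-zero profile has no centre of mass")
    sum(seq_along(p) * p) / sum(p)
  }
  a_a <- apex(profile_a); a_b <- apex(profile_b)
  c_a <- com(profile_a); c_b <- com(profile_b)
  tibble(apex_a = a_a, apex_b = a_b, apex_shift = a_b - a_a,
         com_a = c_a, com_b = c_b, com_shift = c_b - c_a,
         flagged = abs(c_b - c_a) >= min_shift)
}
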