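#' Quantile normalization
#'
#' Forces every sample column to the same empirical distribution: the mean of
#' the column-sorted values. Ranks within columns are preserved, ties receive
#' the average of the target values they span, and missing values are
#' excluded from the reference distribution and re-inserted by interpolated
#' rank. Idempotent.
#'
#' @param data Wide log2 tibble (`feature_id` + sample columns).
#' @return Tibble of the same shape.
#' @export
quantile_normalize <- function(data) {
  m <- omics_as_matrix(data)
  if (any(colSums(!is.na(m)) == 0)) abort("column(s) with no observed values")
  n <- nrow(m)
  # reference distribution on a common grid of n quantiles
  grid <- if (n == 1) 0.5 else seq(0, 1, length.out = n)
  ref_cols <- apply(m, 2, function(v) {
    obs <- sort(v[!is.na(v)])
    if (length(obs) == 1) rep(obs, n) else
      stats::approx(seq(0, 1, length.out = length(obs)), obs, xout = grid,
                    rule = 2)$y
  })
  ref <- rowMeans(ref_cols)
  out <- apply(m, 2, function(v) {
    ok <- !is.na(v)
    k <- sum(ok)
    tgt <- if (k == n) ref else
      stats::approx(grid, ref, xout = if (k == 1) 0.5 else
        seq(0, 1, length.out = k), rule = 2)$y
    r <- rank(v[ok], ties.method = "average")  # tied values share a mean rank
    v[ok] <- if (k == 1) tgt else stats::approx(seq_len(k), tgt, xout = r, rule = 2)$y
    v
  })
  rownames(out) <- rownames(m)
  matrix_as_omics(out)
}

#' Aggregate (pellet vs total homogenate) enrichment
#'
#' Differential abundance of SDS-insoluble pellet versus total homogenate:
#' proteins quantified in at least `min_replicates` replicates of each label
#' are retained, the matrix is quantile normalized, and a moderated t-test
#' contrasts pellet against homogenate. Enrichment is called on the *raw* p
#' (volcano-style cutoffs), not the BH-adjusted p.
#'
#' @param data Wide log2 tibble; missing values allowed before filtering.
#' @param samples Tibble with columns `sample_id`, `label` (values `"Pellet"`
#'   and `"TH"`).
#' @param p_threshold Raw-p cutoff (default 0.05).
#' @param fc_threshold Absolute log2 fold-change cutoff (default 0.5).
#' @param min_replicates Quantified-replicate floor per label (default 2).
#' @return A `proteoage_de` tibble (pellet minus homogenate) with extra
#'   logical columns `enriched` and `depleted`; the enriched-set ids are in
#'   the `enriched_set` attribute.
#' @export
aggregate_enrichment <- function(data, samples, p_threshold = 0.05,
                                 fc_threshold = 0.5, min_replicates = 2) {
  stopifnot(all(c("sample_id", "label") %in% names(samples)))
  pellet <- samples$sample_id[samples$label == "Pellet"]
  th <- samples$sample_id[samples$label == "TH"]
  if (length(pellet) < 2 || length(th) < 2) abort("need >= 2 replicates per label")
  m <- omics_as_matrix(data)[, c(pellet, th), drop = FALSE]
  keep <- rowSums(!is.na(m[, pellet, drop = FALSE])) >= min_replicates &
    rowSums(!is.na(m[, th, drop = FALSE])) >= min_replicates
  m <- m[keep, , drop = FALSE]
  qn <- quantile_normalize(matrix_as_omics(m))
  # moderated t needs complete rows; impute any residual NA by row mean
  qm <- omics_as_matrix(qn)
  if (anyNA(qm)) {
    rm_ <- rowMeans(qm, na.rm = TRUE)
    qm[is.na(qm)] <- rm_[row(qm)[is.na(qm)]]
  }
  de <- moderated_t_test(matrix_as_omics(qm), pellet, th)
  de$enriched <- de$p < p_threshold & de$log2fc > fc_threshold
  de$depleted <- de$p < p_threshold & de$log2fc < -fc_threshold
  attr(de, "enriched_set") <- de$feature_id[de$enriched]
  de
}

#' Signed classifier probability score
#'
#' Converts a binary biophysical classifier's output (label + probability of
#' correct classification) into a signed score: `-P` for a negative label,
#' `0` for indeterminate, `+P` for positive.
#'
#' @param label Character vector in `positive`, `indeterminate`, `negative`.
#' @param p Probability in \[0.5, 1\] (ignored for indeterminate).
#' @return Numeric score in \[-1, 1\].
#' @export
clever_score <- function(label, p) {
  label <- match.arg(label, c("positive", "indeterminate", "negative"),
                     several.ok = TRUE)
  out <- numeric(length(label))
  det <- label != "indeterminate"
  if (any(det)) {
    pv <- rep_len(p, length(label))[det]
    if (any(is.na(pv)) || any(pv < 0.5 | pv > 1)) {
      abort("probability must lie in [0.5, 1] for determinate labels")
    }
    out[det] <- ifelse(label[det] == "negative", -pv, pv)
  }
  out
}

#' Random-coil disorder score
#'
#' Fraction of residues predicted in a random-coil conformation:
#' `n_coil / n_residues`.
#'
#' @param n_coil Number of coil residues (0 <= n_coil <= n_residues).
#' @param n_residues Total residues (> 0).
#' @return Score in \[0, 1\].
#' @export
s2d_score <- function(n_coil, n_residues) {
  if (any(n_residues <= 0)) abort("n_residues must be > 0")
  if (any(n_coil < 0 | n_coil > n_residues)) abort("need 0 <= n_coil <= n_residues")
  n_coil / n_residues
}

#' Compare biophysical scores of extreme enrichment tails
#'
#' Ranks proteins by aggregate enrichment and compares the score
#' distributions of the top and bottom `quantile` tails with a two-sample
#' two-sided Kolmogorov-Smirnov test.
#'
#' @param data Tibble with columns `feature_id`, `log2fc` (enrichment) and
#'   `score`.
#' @param quantile Tail fraction (default 0.2).
#' @param min_tail Minimum proteins per tail (default 10).
#' @return One-row tibble: `n_tail`, `d` (KS statistic), `p`.
#' @export
compare_extremes <- function(data, quantile = 0.2, min_tail = 10) {
  stopifnot(all(c("log2fc", "score") %in% names(data)))
  dat <- filter(data, is.finite(.data$log2fc), is.finite(.data$score))
  n <- nrow(dat)
  k <- floor(n * quantile)
  if (k < min_tail) abort("fewer than `min_tail` proteins per tail")
  if (2 * k > n) abort("tails overlap: input too small for this quantile")
  ord <- order(dat$log2fc)
  bottom <- dat$score[ord[seq_len(k)]]
  top <- dat$score[ord[seq.int(n - k + 1, n)]]
  if (sd(c(top, bottom)) == 0) {
    return(tibble(n_tail = k, d = 0, p = 1))
  }
  ks <- suppressWarnings(ks.test(top, bottom, alternative = "two.sided"))
  tibble(n_tail = k, d = unname(ks$statistic), p = ks$p.value)
}

#' Set enrichment among aggregate-enriched proteins
#'
#' Per catalog set, a two-sided Fisher exact test on the 2x2 table of set
#' membership against aggregate enrichment (within the quantified universe),
#' BH-adjusted across sets; plus a ranking of complexes by the median member
#' enrichment (complexes with >= `min_members_rank` quantified members).
#'
#' @param enriched Character vector of enriched protein ids.
#' @param universe Character vector of all quantified proteins.
#' @param catalog Named list of member vectors.
#' @param enrichment Optional tibble `feature_id`, `log2fc` used for the
#'   median-enrichment ranking; omit to skip the ranking.
#' @param min_members_rank Member floor for the ranking (default 3).
#' @return List with `tests` (tibble `set_id`, `n_set`, `n_hits`, `odds_ratio`,
#'   `p`, `adj_p`) and `ranking` (tibble `complex_id`, `n_members`,
#'   `median_log2fc`, `rank`; `NULL` when `enrichment` is missing).
#' @export
set_enrichment_in_aggregates <- function(enriched, universe, catalog,
                                         enrichment = NULL,
                                         min_members_rank = 3) {
  enriched <- unique(enriched); universe <- unique(universe)
  if (!all(enriched %in% universe)) abort("`enriched` must be a subset of `universe`")
  tests <- bind_rows(purrr::imap(catalog, function(members, set_id) {
    inset <- intersect(members, universe)
    if (length(inset) == 0 || length(enriched) == 0) return(NULL)
    a <- length(intersect(inset, enriched))
    b <- length(setdiff(inset, enriched))
    c_ <- length(setdiff(enriched, inset))
    d <- length(universe) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2), alternative = "two.sided")
    tibble(set_id = set_id, n_set = length(inset), n_hits = a,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  }))
  if (nrow(tests) > 0) {
    tests$adj_p <- bh_adjust(tests$p)
    tests <- arrange(tests, .data$p)
  }
  ranking <- NULL
  if (!is.null(enrichment)) {
    ranking <- bind_rows(purrr::imap(catalog, function(members, cid) {
      fc <- enrichment$log2fc[enrichment$feature_id %in% members]
      fc <- fc[is.finite(fc)]
      if (length(fc) < min_members_rank) return(NULL)
      tibble(complex_id = cid, n_members = length(fc),
             median_log2fc = median(fc))
    }))
    if (!is.null(ranking) && nrow(ranking) > 0) {
      ranking <- ranking %>%
        arrange(desc(.data$median_log2fc), .data$complex_id) %>%
        mutate(rank = row_number())
    }
  }
  list(tests = tests, ranking = ranking)
}

#' Two-sample t utility
#'
#' Plain unpaired two-sample t-test on two numeric vectors (e.g. gel-band
#' densitometry yields of young vs old preparations).
#'
#' @param x,y Numeric vectors.
#' @param var_equal Pooled variance (default TRUE, classic unpaired t).
#' @return One-row tibble: `mean_x`, `mean_y`, `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  tt <- t.test(x, y, var.equal = var_equal)
  tibble(mean_x = mean(x), mean_y = mean(y), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
}

#' Presence/absence evidence filter
#'
#' Retains proteins identified with at least `min_peptides` unique peptides
#' in at least `min_replicates` replicates -- the qualitative
#' aggregate-identification rule.
#'
#' @param evidence Tibble with columns `feature_id`, `replicate`,
#'   `n_unique_peptides`.
#' @param min_peptides Unique-peptide floor per replicate (default 2).
#' @param min_replicates Replicate floor (default 1).
#' @return Character vector of retained protein ids.
#' @export
evidence_filter <- function(evidence, min_peptides = 2, min_replicates = 1) {
  evidence %>%
    filter(.data$n_unique_peptides >= min_peptides) %>%
    group_by(.data$feature_id) %>%
    summarise(n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop") %>%
    filter(.data$n_rep >= min_replicates) %>%
    pull(.data$feature_id)
}
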