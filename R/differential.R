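#' Empirical-Bayes moderated two-group t-test
#'
#' Per-feature differential abundance between two sample groups on a log2
#' matrix, with residual variances shrunk toward a common prior estimated
#' from the data by closed-form moment matching on log sample variances
#' (Smyth-style). The moderated statistic is
#' \deqn{t_g = \frac{\bar{x}_{gA} - \bar{x}_{gB}}{\tilde{s}_g
#'   \sqrt{1/n_A + 1/n_B}}, \qquad
#'   \tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},}
#' referred to a t-distribution with \eqn{d + d_0} degrees of freedom, where
#' \eqn{d} is the pooled residual df and \eqn{(d_0, s_0^2)} the prior df and
#' variance estimated from the marginal distribution of the \eqn{s_g^2}.
#'
#' @param data Wide tibble: `feature_id` plus numeric sample columns holding
#'   log2 abundances (finite values).
#' @param group_a,group_b Character vectors of sample column names; the fold
#'   change is `mean(group_a) - mean(group_b)`. Each group needs >= 2 samples.
#' @param prior_df Optional override of the estimated prior df \eqn{d_0}. `0`
#'   recovers the ordinary two-sample pooled t-test; `Inf` forces every
#'   feature to the common variance \eqn{s_0^2}.
#' @return A tibble of class `proteoage_de` with columns `feature_id`,
#'   `log2fc`, `mean_abundance`, `t`, `df_total`, `p`, `adj_p` (BH across
#'   features). The estimated `df_prior` and `s2_prior` are attached as
#'   attributes and reported by [glance()].
#' @examples
#' m <- simulate_null_matrix(50, 3, 3, seed = 1)
#' de <- moderated_t_test(m, paste0("a", 1:3), paste0("b", 1:3))
#' glance(de)
#' @export
moderated_t_test <- function(data, group_a, group_b, prior_df = NULL) {
  x <- omics_as_matrix(data)
  missing_cols <- setdiff(c(group_a, group_b), colnames(x))
  if (length(missing_cols) > 0) {
    abort(paste0("samples not in data: ", paste(missing_cols, collapse = ", ")))
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  if (!all(is.finite(xa)) || !all(is.finite(xb))) abort("non-finite values in data")
  na <- length(group_a); nb <- length(group_b)
  d <- na + nb - 2L
  if (d <= 0) abort("zero residual degrees of freedom")

  ma <- rowMeans(xa); mb <- rowMeans(xb)
  log2fc <- ma - mb
  s2 <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / d

  if (is.null(prior_df)) {
    pri <- estimate_variance_prior(s2, d)
  } else {
    stopifnot(prior_df >= 0)
    s0 <- if (prior_df > 0) estimate_variance_prior(s2, d)$s2_prior else NA_real_
    if (is.infinite(prior_df)) s0 <- estimate_variance_prior(s2, d)$s2_prior
    pri <- list(df_prior = prior_df, s2_prior = s0)
  }
  d0 <- pri$df_prior; s02 <- pri$s2_prior

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
    df_total <- rep(Inf, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(d, length(s2))
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- rep(d + d0, length(s2))
  }

  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(tstat), df = df_total), 1)
  # constant features: no variance anywhere and no difference -> uninformative
  degenerate <- se == 0

  out <- tibble(
    feature_id = rownames(x),
    log2fc = unname(log2fc),
    mean_abundance = unname((ma * na + mb * nb) / (na + nb)),
    t = unname(tstat),
    df_total = unname(df_total),
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    degenerate = unname(degenerate)
  )
  structure(out,
            class = c("proteoage_de", class(out)),
            df_prior = d0, s2_prior = s02, df_residual = d,
            contrast = list(group_a = group_a, group_b = group_b))
}

# Moment-matching estimate of the scaled inverse-chi-square prior (d0, s0^2)
# from sample variances s2 with d residual df each. Works on e = log(s2):
# under the hierarchical model, e - digamma(d/2) + log(d/2) has mean
# log(s0^2) + digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2).
estimate_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(df_prior = 0, s2_prior = stats::median(s2)))
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ev <- mean((e - mean(e))^2) * length(e) / (length(e) - 1) - trigamma(d / 2)
  if (ev <= 0) {
    # observed variances are less dispersed than pure chi-square noise:
    # infinite prior df, all features share one variance
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, s2_prior = s02)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (monotone, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. `NA`/`NaN` entries are propagated and excluded
#' from the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Combine p-values with Fisher's method
#'
#' \eqn{X = -2\sum_k \ln p_k} referred to the upper tail of a chi-square
#' distribution with \eqn{2k} df. A single p-value is returned unchanged.
#'
#' @param p Numeric vector of p-values in (0, 1\]. Zeros are clipped to the
#'   smallest positive double with a warning.
#' @return Combined p-value (scalar).
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) abort("no p-values to combine")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warn("zero p-value(s) clipped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  if (length(p) == 1) return(p)
  x <- -2 * sum(log(p))
  pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Hypergeometric over-representation test across a catalog
#'
#' For each set, an upper-tail hypergeometric test of overlap between the
#' selected features and the set, restricted to the analysis universe;
#' BH-adjusted across sets.
#'
#' @param selected Character vector, subset of `universe`.
#' @param universe Character vector of all features eligible for selection.
#' @param catalog Named list of character vectors (complexes/pathways).
#' @param fdr Adjusted-p cutoff for the `significant` flag.
#' @return Tibble: `set_id`, `n_set` (set size inside the universe), `n_hits`,
#'   `expected`, `p`, `adj_p`, `significant`. Sets disjoint from the universe
#'   are excluded.
#' @export
ora_test <- function(selected, universe, catalog, fdr = 0.05) {
  selected <- unique(selected); universe <- unique(universe)
  if (!all(selected %in% universe)) abort("`selected` must be a subset of `universe`")
  if (length(selected) == 0) {
    return(tibble(set_id = character(), n_set = integer(), n_hits = integer(),
                  expected = double(), p = double(), adj_p = double(),
                  significant = logical()))
  }
  N <- length(universe); n <- length(selected)
  rows <- purrr::imap(catalog, function(members, set_id) {
    K <- length(intersect(members, universe))
    if (K == 0) return(NULL)
    k <- length(intersect(members, selected))
    tibble(set_id = set_id, n_set = K, n_hits = k,
           expected = n * K / N,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < fdr
  arrange(out, .data$p)
}

#' Two-sample set test on per-feature scores
#'
#' Tests, for each catalog set, whether its members' scores differ from the
#' scores of all non-members (two-sided two-sample t-test, Welch variance).
#' Used downstream on per-gene Cox coefficients to find risk-gene sets.
#'
#' @param scores Tibble with columns `feature_id` and `score` (one row per
#'   feature), or a named numeric vector.
#' @param catalog Named list of character vectors.
#' @param min_members Minimum scored members for a set to be tested.
#' @return Tibble: `set_id`, `n_members`, `mean_diff`, `direction` (sign of
#'   the member-minus-background mean difference), `p`, `adj_p`.
#' @export
coefficient_set_test <- function(scores, catalog, min_members = 5) {
  if (is.data.frame(scores)) {
    v <- setNames(scores$score, scores$feature_id)
  } else {
    v <- scores
  }
  v <- v[is.finite(v)]
  rows <- purrr::imap(catalog, function(members, set_id) {
    inset <- v[names(v) %in% members]
    out <- v[!(names(v) %in% members)]
    if (length(inset) < min_members || length(out) < 2) return(NULL)
    md <- mean(inset) - mean(out)
    if (sd(inset) == 0 && sd(out) == 0) {
      p <- 1
    } else {
      p <- tryCatch(t.test(inset, out)$p.value, error = function(e) 1)
    }
    tibble(set_id = set_id, n_members = length(inset), mean_diff = md, p = p)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$direction <- sign(out$mean_diff)
  out$adj_p <- bh_adjust(out$p)
  arrange(out, .data$p)
}

#' Generic log2(CPM) transcript route for differential expression
#'
#' Converts raw counts to log2 counts-per-million with a pseudo-count and
#' applies [moderated_t_test()]; the pipeline's single generic
#' transcript-differential operation (count-model internals such as DESeq2's
#' dispersion fitting are outside its scope -- downstream stages need only a
#' fold change and an adjusted p).
#'
#' @param counts Wide tibble of non-negative counts.
#' @param group_a,group_b Sample column names.
#' @param pseudo Pseudo-count added to CPM before log2 (default 0.5).
#' @return A `proteoage_de` tibble (see [moderated_t_test()]).
#' @export
transcript_de <- function(counts, group_a, group_b, pseudo = 0.5) {
  m <- omics_as_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) abort("sample(s) with zero total counts")
  logcpm <- log2(sweep(m, 2, lib, "/") * 1e6 + pseudo)
  moderated_t_test(matrix_as_omics(logcpm), group_a, group_b)
}
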