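#' Per-fish expression change between two time points
#'
#' \eqn{\Delta_{ij} = \log_2\!\big((g_{ij}(t_2) + p)/(g_{ij}(t_1) + p)\big)}
#' on library-size-normalized counts (median-of-ratios size factors), where
#' \eqn{g_{ij}(t)} is the expression of gene i in fish j at time t and p a
#' pseudo-count guarding positivity.
#'
#' @param expr_t1,expr_t2 Wide count tibbles (`feature_id` + fish columns)
#'   at the first and second sampling time. Fish present at only one time
#'   are dropped (listed in the `dropped_fish` attribute).
#' @param pseudo Pseudo-count (default 0.5).
#' @param normalize Apply median-of-ratios size-factor normalization across
#'   all columns of both matrices before the ratio (default TRUE).
#' @return Wide tibble of \eqn{\Delta} values (`feature_id` + fish columns).
#' @export
compute_delta <- function(expr_t1, expr_t2, pseudo = 0.5, normalize = TRUE) {
  m1 <- omics_as_matrix(expr_t1)
  m2 <- omics_as_matrix(expr_t2)
  genes <- intersect(rownames(m1), rownames(m2))
  fish <- intersect(colnames(m1), colnames(m2))
  dropped <- setdiff(union(colnames(m1), colnames(m2)), fish)
  if (length(fish) == 0) abort("no fish present at both time points")
  m1 <- m1[genes, fish, drop = FALSE]
  m2 <- m2[genes, fish, drop = FALSE]
  if (normalize) {
    both <- cbind(m1, m2)
    sf <- median_of_ratios(both)
    m1 <- sweep(m1, 2, sf[seq_along(fish)], "/")
    m2 <- sweep(m2, 2, sf[seq_along(fish) + length(fish)], "/")
  }
  delta <- log2((m2 + pseudo) / (m1 + pseudo))
  if (!all(is.finite(delta))) abort("non-finite delta values; check pseudo-count")
  out <- matrix_as_omics(delta)
  attr(out, "dropped_fish") <- dropped
  out
}

# Median-of-ratios size factors: per sample, the median across genes of the
# ratio to the geometric-mean reference row (genes with any zero excluded).
median_of_ratios <- function(m) {
  logs <- log(m)
  ok <- rowSums(!is.finite(logs)) == 0
  if (sum(ok) < 1) abort("no all-positive genes for size-factor estimation")
  ref <- rowMeans(logs[ok, , drop = FALSE])
  sf <- apply(logs[ok, , drop = FALSE], 2, function(v) exp(median(v - ref)))
  sf / exp(mean(log(sf)))
}

#' Cox proportional-hazards fit for a single covariate
#'
#' Fits the hazard model \eqn{h(t \mid x_j) = h_0(t)\exp(c\, x_j)} by
#' Newton-Raphson maximization of the Breslow partial likelihood, honouring
#' left truncation (fish enter the risk set after `entry_time`). A positive
#' coefficient means larger covariate values increase mortality risk.
#'
#' @param x Per-subject covariate vector (e.g. one gene's \eqn{\Delta}),
#'   aligned with `surv`.
#' @param surv Tibble with columns `lifespan`, `event` (1 = death observed)
#'   and optionally `entry_time` (default 0).
#' @param max_iter,tol Newton-Raphson controls.
#' @return One-row tibble: `coef`, `se`, `z`, `p`, `n`, `n_events`,
#'   `converged`, `degenerate` (`"none"`, `"constant"` or `"divergent"`).
#'   Constant covariates report `coef = 0`, `p = 1`; monotone likelihoods
#'   (risk perfectly ordered by the covariate) are flagged `"divergent"`
#'   with no finite estimate.
#' @export
cox_fit_single <- function(x, surv, max_iter = 50, tol = 1e-9) {
  stopifnot(length(x) == nrow(surv))
  if (!all(is.finite(x))) abort("non-finite covariate values")
  event <- as.integer(surv$event)
  time <- surv$lifespan
  entry <- if ("entry_time" %in% names(surv)) surv$entry_time else rep(0, length(time))
  if (any(time <= entry)) abort("lifespan must exceed entry_time")
  if (sum(event) < 2) abort("need at least 2 observed events")

  if (sd(x) == 0) {
    return(tibble(coef = 0, se = NA_real_, z = NA_real_, p = 1,
                  n = length(x), n_events = sum(event),
                  converged = TRUE, degenerate = "constant"))
  }
  xc <- x - mean(x)  # centring stabilizes exp() without changing the MLE

  beta <- 0
  converged <- FALSE
  diverged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- cox_partial_derivs(beta, xc, time, event, entry)
    if (d$info <= 0) { diverged <- TRUE; break }
    step <- d$score / d$info
    if (!is.finite(step)) { diverged <- TRUE; break }
    step <- sign(step) * min(abs(step), 5)  # damped step
    beta <- beta + step
    if (abs(beta) > 30) { diverged <- TRUE; break }
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  if (diverged || !converged) {
    return(tibble(coef = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                  n = length(x), n_events = sum(event),
                  converged = FALSE, degenerate = "divergent"))
  }
  d <- cox_partial_derivs(beta, xc, time, event, entry)
  se <- 1 / sqrt(d$info)
  z <- beta / se
  tibble(coef = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
         n = length(x), n_events = sum(event),
         converged = TRUE, degenerate = "none")
}

# Score and information of the Breslow partial log-likelihood at beta.
# Risk set at event time t: subjects with entry < t <= time.
cox_partial_derivs <- function(beta, x, time, event, entry) {
  ev_times <- sort(unique(time[event == 1]))
  eta <- beta * x
  w <- exp(eta)
  score <- 0; info <- 0
  for (t in ev_times) {
    at_risk <- entry < t & time >= t
    dead <- event == 1 & time == t
    sw <- sum(w[at_risk])
    m1 <- sum(w[at_risk] * x[at_risk]) / sw
    m2 <- sum(w[at_risk] * x[at_risk]^2) / sw
    d_ <- sum(dead)
    score <- score + sum(x[dead]) - d_ * m1
    info <- info + d_ * (m2 - m1^2)
  }
  list(score = score, info = info)
}

# Breslow partial log-likelihood (exposed for oracle-style checks).
cox_partial_loglik <- function(beta, x, surv) {
  event <- as.integer(surv$event)
  time <- surv$lifespan
  entry <- if ("entry_time" %in% names(surv)) surv$entry_time else rep(0, length(time))
  xc <- x - mean(x)
  eta <- beta * xc
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- entry < t & time >= t
    dead <- event == 1 & time == t
    ll <- ll + sum(eta[dead]) - sum(dead) * log(sum(w[at_risk]))
  }
  ll
}

#' Gene-wise Cox screening
#'
#' [cox_fit_single()] applied to every gene of a \eqn{\Delta} matrix, with
#' BH adjustment of the Wald p-values across genes. Per-gene failures are
#' recorded, not fatal.
#'
#' @param delta Wide \eqn{\Delta} tibble (`feature_id` + fish columns), see
#'   [compute_delta()].
#' @param surv Survival tibble with `fish_id`, `lifespan`, `event` and
#'   optionally `entry_time`; fish are matched to `delta` columns by
#'   `fish_id`.
#' @return Tibble of class `proteoage_cox`: one row per gene with the
#'   [cox_fit_single()] columns plus `feature_id` and `adj_p`. The
#'   coefficient vector (named by gene) feeds [coefficient_set_test()].
#' @export
genewise_cox <- function(delta, surv) {
  m <- omics_as_matrix(delta)
  fish <- intersect(colnames(m), surv$fish_id)
  if (length(fish) < 3) abort("fewer than 3 fish shared between delta and surv")
  m <- m[, fish, drop = FALSE]
  sv <- surv[match(fish, surv$fish_id), , drop = FALSE]
  fits <- purrr::map(seq_len(nrow(m)), function(i) {
    tryCatch(cox_fit_single(m[i, ], sv),
             error = function(e) tibble(coef = NA_real_, se = NA_real_,
                                        z = NA_real_, p = NA_real_,
                                        n = length(fish), n_events = sum(sv$event),
                                        converged = FALSE, degenerate = "error"))
  })
  out <- bind_rows(fits)
  out <- dplyr::bind_cols(tibble(feature_id = rownames(m)), out)
  out$adj_p <- bh_adjust(out$p)
  structure(out, class = c("proteoage_cox", class(out)), n_fish = length(fish))
}

#' Extreme-group lifespan comparison
#'
#' Summarizes each fish's expression change over a gene set (mean by
#' default), takes the `k` fish with the most pronounced decreases and the
#' `k` with the most pronounced increases, and compares their lifespans with
#' the two-group log-rank test (chi-square, 1 df).
#'
#' @param delta Wide \eqn{\Delta} tibble.
#' @param surv Survival tibble (`fish_id`, `lifespan`, `event`).
#' @param gene_set Character vector of genes defining the risk signature.
#' @param k Fish per extreme group (default 32).
#' @param summary Per-fish summary of the gene-set \eqn{\Delta}s: `"mean"`,
#'   `"median"` or `"pc1"` (first principal-component score).
#' @return List: `groups` (tibble `fish_id`, `score`, `group` in
#'   `"decrease"`/`"increase"`/`NA`), `chisq`, `p`. Ties at the k-th rank
#'   are broken deterministically by fish id.
#' @export
extreme_group_logrank <- function(delta, surv, gene_set, k = 32,
                                  summary = c("mean", "median", "pc1")) {
  summary <- match.arg(summary)
  m <- omics_as_matrix(delta)
  genes <- intersect(gene_set, rownames(m))
  if (length(genes) == 0) abort("gene_set has no genes in delta")
  fish <- intersect(colnames(m), surv$fish_id)
  if (2 * k > length(fish)) abort("2k exceeds the number of fish")
  sub <- m[genes, fish, drop = FALSE]
  score <- switch(summary,
    mean = colMeans(sub),
    median = apply(sub, 2, median),
    pc1 = {
      pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
      s <- pc$x[, 1]
      if (cor(s, colMeans(sub)) < 0) s <- -s  # orient along mean change
      s
    })
  ord <- order(score, fish)  # fish_id breaks ties deterministically
  grp <- rep(NA_character_, length(fish))
  grp[ord[seq_len(k)]] <- "decrease"
  grp[ord[seq.int(length(fish) - k + 1, length(fish))]] <- "increase"
  groups <- tibble(fish_id = fish, score = unname(score), group = grp)

  sel <- !is.na(grp)
  sv <- surv[match(fish[sel], surv$fish_id), , drop = FALSE]
  gl <- factor(grp[sel])
  if (length(unique(sv$lifespan)) == 1 ||
      identical(sort(sv$lifespan[gl == "decrease"]), sort(sv$lifespan[gl == "increase"]))) {
    chisq <- 0; p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(sv$lifespan, sv$event) ~ gl)
    chisq <- unname(sd_$chisq)
    p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  list(groups = groups, chisq = chisq, p = p)
}
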