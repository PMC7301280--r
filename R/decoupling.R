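#' Per-sample protein-transcript correlation
#'
#' Pearson correlation of log10 protein versus log10 transcript abundance,
#' computed per sample over the features detected (positive) in both layers,
#' followed by a one-way ANOVA of the per-sample correlations across age
#' groups. The global readout of transcript-protein decoupling.
#'
#' @param protein Wide tibble of protein abundances (e.g. iBAQ), linear scale.
#' @param transcript Wide tibble of transcript abundances (e.g. RPKM or
#'   normalized counts), linear scale.
#' @param samples Sample metadata tibble with columns `sample_id` and `group`.
#'   In matched mode each `sample_id` must be a column of both matrices; in
#'   unmatched mode (`matched = FALSE`) each protein sample is compared to the
#'   mean transcript abundance of its group.
#' @param matched Logical; see `samples`.
#' @param min_shared Minimum features positive in both layers for a sample to
#'   enter the ANOVA (default 100); samples below the floor are flagged
#'   `excluded`.
#' @return A tibble of class `proteoage_cor` with columns `sample_id`,
#'   `group`, `n_shared`, `r`, `excluded`; ANOVA F and p are attached as
#'   attributes and reported by [glance()].
#' @export
per_sample_correlation <- function(protein, transcript, samples,
                                   matched = TRUE, min_shared = 100) {
  pm <- omics_as_matrix(protein)
  tm <- omics_as_matrix(transcript)
  shared_feat <- intersect(rownames(pm), rownames(tm))
  if (length(shared_feat) == 0) abort("no shared features between layers")
  pm <- pm[shared_feat, , drop = FALSE]
  tm <- tm[shared_feat, , drop = FALSE]

  rows <- purrr::pmap(samples[c("sample_id", "group")], function(sample_id, group) {
    if (!sample_id %in% colnames(pm)) {
      return(tibble(sample_id = sample_id, group = group,
                    n_shared = 0L, r = NA_real_, excluded = TRUE))
    }
    p <- pm[, sample_id]
    if (matched) {
      if (!sample_id %in% colnames(tm)) {
        abort(paste0("matched mode: transcript column missing for ", sample_id))
      }
      t_ <- tm[, sample_id]
    } else {
      grp_cols <- intersect(samples$sample_id[samples$group == group], colnames(tm))
      if (length(grp_cols) == 0) abort(paste0("no transcript samples for group ", group))
      t_ <- rowMeans(tm[, grp_cols, drop = FALSE])
    }
    ok <- is.finite(p) & is.finite(t_) & p > 0 & t_ > 0
    n <- sum(ok)
    r <- if (n >= 3) cor(log10(p[ok]), log10(t_[ok])) else NA_real_
    tibble(sample_id = sample_id, group = group, n_shared = n,
           r = r, excluded = n < min_shared)
  })
  out <- bind_rows(rows)

  usable <- out[!out$excluded & !is.na(out$r), ]
  if (length(unique(usable$group)) >= 2 && nrow(usable) > length(unique(usable$group))) {
    if (sd(usable$r) < 1e-10) {
      f_stat <- 0; p_anova <- 1
    } else {
      fit <- aov(r ~ factor(group), data = usable)
      tab <- anova(fit)
      f_stat <- tab$`F value`[1]; p_anova <- tab$`Pr(>F)`[1]
    }
  } else {
    f_stat <- NA_real_; p_anova <- NA_real_
  }
  structure(out, class = c("proteoage_cor", class(out)),
            anova_f = f_stat, anova_p = p_anova)
}

#' Fold-change concordance quadrants
#'
#' Restricts to features significant in both the transcript and the protein
#' contrast, assigns them to the four fold-change sign quadrants, and reports
#' the Pearson correlation of the two fold-change vectors.
#'
#' @param protein_de,transcript_de `proteoage_de` tibbles (see
#'   [moderated_t_test()]) sharing a feature namespace.
#' @param adj_p_threshold Significance cutoff on both layers (default 0.05).
#' @return A tibble of class `proteoage_quadrants` with one row per jointly
#'   significant feature (`feature_id`, `transcript_log2fc`,
#'   `protein_log2fc`, `quadrant` in `"up/up"`, `"up/down"`, `"down/up"`,
#'   `"down/down"` as transcript/protein). Quadrant counts and the
#'   fold-change correlation `r` (NA when fewer than 3 features) are
#'   attributes, summarized by [glance()].
#' @export
concordance_quadrants <- function(protein_de, transcript_de,
                                  adj_p_threshold = 0.05) {
  joint <- dplyr::inner_join(
    select(as_tibble(transcript_de), "feature_id",
           transcript_log2fc = "log2fc", transcript_adj_p = "adj_p"),
    select(as_tibble(protein_de), "feature_id",
           protein_log2fc = "log2fc", protein_adj_p = "adj_p"),
    by = "feature_id"
  ) %>%
    filter(.data$transcript_adj_p < adj_p_threshold,
           .data$protein_adj_p < adj_p_threshold,
           .data$transcript_log2fc != 0, .data$protein_log2fc != 0)
  joint <- mutate(joint, quadrant = paste0(
    ifelse(.data$transcript_log2fc > 0, "up", "down"), "/",
    ifelse(.data$protein_log2fc > 0, "up", "down")))
  counts <- table(factor(joint$quadrant,
                         levels = c("up/up", "up/down", "down/up", "down/down")))
  r <- if (nrow(joint) >= 3) {
    cor(joint$transcript_log2fc, joint$protein_log2fc)
  } else NA_real_
  structure(joint, class = c("proteoage_quadrants", class(joint)),
            quadrant_counts = as.list(counts), r = r,
            n_joint = nrow(joint))
}

#' Classify the regulatory mechanism behind each affected protein
#'
#' Proteins differentially abundant at the protein level are assigned to five
#' mutually exclusive regulatory classes, evaluated in this order:
#'
#' * `no_transcript` -- the transcript was not detected;
#' * `concordant_significant` -- transcript significant with the same
#'   fold-change sign;
#' * `transcript_consistent` -- transcript fold change has the same sign and
#'   a non-negligible magnitude (at least `min_consistent_fc`) but is not
#'   significant;
#' * `mirna_candidate` -- protein down-regulated and targeted by at least one
#'   miRNA up-regulated in the same contrast (canonical repressive miRNA
#'   action);
#' * `other_post_transcriptional` -- everything that remains.
#'
#' @param protein_de,transcript_de `proteoage_de` tibbles for the same
#'   contrast.
#' @param transcript_detected Character vector of transcripts considered
#'   detected (the transcript universe).
#' @param mirna_de Tibble with columns `mirna_id`, `log2fc`, `adj_p` for the
#'   same contrast.
#' @param target_map Tibble with columns `mirna_id`, `feature_id` mapping
#'   miRNAs to target genes.
#' @param adj_p Significance threshold used throughout (default 0.05).
#' @param min_consistent_fc Minimal absolute transcript log2 fold change for
#'   a non-significant transcript to count as a "consistent" change (default
#'   0.3); below it, a matching sign is indistinguishable from noise.
#' @return Tibble: `feature_id`, `class`, `protein_log2fc`, `protein_adj_p`,
#'   `transcript_log2fc`, `transcript_adj_p`, `n_mirna` (matched up-regulated
#'   miRNAs). Class fractions are in the `class_fractions` attribute.
#' @export
classify_mechanism <- function(protein_de, transcript_de, transcript_detected,
                               mirna_de, target_map, adj_p = 0.05,
                               min_consistent_fc = 0.3) {
  affected <- as_tibble(protein_de) %>%
    filter(.data$adj_p < !!adj_p) %>%
    select("feature_id", protein_log2fc = "log2fc", protein_adj_p = "adj_p")
  tr <- select(as_tibble(transcript_de), "feature_id",
               transcript_log2fc = "log2fc", transcript_adj_p = "adj_p")
  up_mirnas <- mirna_de$mirna_id[mirna_de$log2fc > 0 & mirna_de$adj_p < adj_p]
  targets_of_up <- target_map[target_map$mirna_id %in% up_mirnas, , drop = FALSE]
  n_mirna <- targets_of_up %>% dplyr::count(.data$feature_id, name = "n_mirna")

  out <- affected %>%
    left_join(tr, by = "feature_id") %>%
    left_join(n_mirna, by = "feature_id") %>%
    mutate(
      n_mirna = dplyr::coalesce(.data$n_mirna, 0L),
      detected = .data$feature_id %in% transcript_detected,
      class = case_when(
        !.data$detected ~ "no_transcript",
        !is.na(.data$transcript_adj_p) & .data$transcript_adj_p < !!adj_p &
          sign(.data$transcript_log2fc) == sign(.data$protein_log2fc) ~
          "concordant_significant",
        !is.na(.data$transcript_log2fc) &
          sign(.data$transcript_log2fc) == sign(.data$protein_log2fc) &
          abs(.data$transcript_log2fc) >= min_consistent_fc ~
          "transcript_consistent",
        .data$protein_log2fc < 0 & .data$n_mirna > 0 ~ "mirna_candidate",
        TRUE ~ "other_post_transcriptional"
      )
    ) %>%
    select(-"detected")
  missing_tr <- out$feature_id[is.na(out$transcript_log2fc) &
                                 out$class != "no_transcript"]
  if (length(missing_tr) > 0) {
    abort(paste0("features marked transcript-detected but absent from the ",
                 "transcript results: ", paste(head(missing_tr, 5), collapse = ", ")))
  }
  fracs <- table(factor(out$class, levels = c(
    "concordant_significant", "transcript_consistent", "no_transcript",
    "mirna_candidate", "other_post_transcriptional"))) / max(1L, nrow(out))
  attr(out, "class_fractions") <- as.list(fracs)
  out
}

#' Group fold change of means
#'
#' Small utility: per-feature log2 ratio of group means on a linear-scale
#' matrix (used e.g. for marker panels or footprint-style TPM comparisons).
#'
#' @param data Wide tibble, linear scale.
#' @param group_a,group_b Sample column names.
#' @param pseudo Pseudo-count guarding against zero means.
#' @return Tibble `feature_id`, `log2fc`.
#' @export
fold_change_of_means <- function(data, group_a, group_b, pseudo = 0.5) {
  m <- omics_as_matrix(data)
  tibble(feature_id = rownames(m),
         log2fc = log2((rowMeans(m[, group_a, drop = FALSE]) + pseudo) /
                         (rowMeans(m[, group_b, drop = FALSE]) + pseudo)))
}
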