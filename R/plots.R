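#' Volcano plot of a differential result
#'
#' @param object A `proteoage_de` tibble.
#' @param p_threshold,fc_threshold Dashed cutoff lines (raw p and |log2 FC|).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.proteoage_de <- function(object, p_threshold = 0.05,
                                  fc_threshold = 0.5, ...) {
  dat <- as_tibble(object) %>%
    mutate(hit = .data$p < p_threshold & abs(.data$log2fc) > fc_threshold)
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                    colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_bw()
}

#' Boxplot of per-sample protein-transcript correlations by age group
#'
#' @param object A `proteoage_cor` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.proteoage_cor <- function(object, ...) {
  dat <- as_tibble(object) %>% filter(!.data$excluded)
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$r)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "protein-transcript correlation (Pearson r)") +
    ggplot2::theme_bw()
}

#' Fold-change concordance scatter
#'
#' @param object A `proteoage_quadrants` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.proteoage_quadrants <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$transcript_log2fc, .data$protein_log2fc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "transcript log2 fold change",
                  y = "protein log2 fold change",
                  subtitle = sprintf("r = %.3f over %d jointly significant features",
                                     attr(object, "r"), attr(object, "n_joint"))) +
    ggplot2::theme_bw()
}

#' Plot SEC elution profiles
#'
#' Consensus (or single-protein) profiles across fractions for one or more
#' conditions.
#'
#' @param profiles Named list of numeric profile vectors (one per condition).
#' @return A ggplot object.
#' @export
plot_sec_profiles <- function(profiles) {
  dat <- purrr::imap(profiles, function(p, nm) {
    tibble(condition = nm, fraction = seq_along(p), intensity = p)
  }) %>% bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(.data$fraction, .data$intensity,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SEC fraction (later = smaller assembly)",
                  y = "relative intensity (max = 1)") +
    ggplot2::theme_bw()
}

#' Kaplan-Meier curves for the extreme proteasome-change groups
#'
#' @param logrank Result of [extreme_group_logrank()].
#' @param surv The survival tibble used for the test.
#' @return A ggplot object.
#' @export
plot_extreme_survival <- function(logrank, surv) {
  dat <- logrank$groups %>%
    filter(!is.na(.data$group)) %>%
    left_join(surv, by = "fish_id") %>%
    group_by(.data$group) %>%
    arrange(.data$lifespan, .by_group = TRUE) %>%
    mutate(surv_frac = 1 - row_number() / dplyr::n()) %>%
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(.data$lifespan, .data$surv_frac,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "lifespan (weeks)", y = "fraction surviving",
                  subtitle = sprintf("log-rank chi-square = %.2f, p = %.2g",
                                     logrank$chisq, logrank$p)) +
    ggplot2::theme_bw()
}
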