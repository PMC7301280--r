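#' @name proteoage-tidiers
#' @title Broom-style tidiers for proteoage result objects
#' @description `tidy()` returns the per-feature (or per-sample / per-complex)
#'   table as a plain tibble; `glance()` returns a one-row model-level
#'   summary.
#' @param x A proteoage result object.
#' @param ... Unused.
NULL

#' @rdname proteoage-tidiers
#' @exportS3Method generics::tidy
tidy.proteoage_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "proteoage_de")
  out
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::glance
glance.proteoage_de <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$adj_p < 0.05, na.rm = TRUE),
    df_prior = attr(x, "df_prior"),
    s2_prior = attr(x, "s2_prior"),
    df_residual = attr(x, "df_residual")
  )
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::tidy
tidy.proteoage_cor <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "proteoage_cor")
  out
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::glance
glance.proteoage_cor <- function(x, ...) {
  usable <- x[!x$excluded & !is.na(x$r), ]
  grp <- usable %>% group_by(.data$group) %>%
    summarise(mean_r = mean(.data$r), .groups = "drop")
  tibble(
    n_samples = nrow(x), n_excluded = sum(x$excluded),
    anova_f = attr(x, "anova_f"), anova_p = attr(x, "anova_p"),
    group_means = list(setNames(grp$mean_r, grp$group))
  )
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::tidy
tidy.proteoage_quadrants <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "proteoage_quadrants")
  out
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::glance
glance.proteoage_quadrants <- function(x, ...) {
  qc <- attr(x, "quadrant_counts")
  tibble(n_joint = attr(x, "n_joint"), r = attr(x, "r"),
         up_up = qc[["up/up"]], up_down = qc[["up/down"]],
         down_up = qc[["down/up"]], down_down = qc[["down/down"]])
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::tidy
tidy.proteoage_stoich <- function(x, ...) {
  attr(x, "member_de")
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::glance
glance.proteoage_stoich <- function(x, ...) {
  tibble(n_complexes = nrow(x), n_affected = sum(x$is_affected),
         fraction_affected = attr(x, "fraction_affected"))
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::tidy
tidy.proteoage_cox <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "proteoage_cox")
  out
}

#' @rdname proteoage-tidiers
#' @exportS3Method generics::glance
glance.proteoage_cox <- function(x, ...) {
  tibble(n_genes = nrow(x), n_fish = attr(x, "n_fish"),
         n_converged = sum(x$converged),
         n_significant = sum(x$adj_p < 0.05, na.rm = TRUE))
}
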