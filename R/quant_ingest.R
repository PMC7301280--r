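#' Filter peptide-spectrum matches
#'
#' Discards PSMs that map to reverse (decoy) or contaminant hits, fall below
#' the search-score cutoff, or have reporter-ion intensities below the
#' intensity floor in *all* channels. The standard first step of reporter-ion
#' TMT processing.
#'
#' @param psms PSM tibble with columns `psm_id`, `peptide_sequence`,
#'   `protein_group_id`, `is_unique_peptide`, `search_score`, `is_reverse`,
#'   `is_contaminant`, `precursor_intensity`, and reporter columns
#'   `reporter_01` ... `reporter_NN`.
#' @param min_score Minimum search score (default 15).
#' @param min_reporter Reporter floor; a PSM survives if at least one channel
#'   is `>= min_reporter` (default 1e3).
#' @return The retained PSM tibble; a `filter_report` attribute (tibble of
#'   per-criterion removal counts, in application order) records what was
#'   discarded.
#' @export
filter_psms <- function(psms, min_score = 15, min_reporter = 1e3) {
  if (nrow(psms) == 0) abort("empty PSM table")
  rep_cols <- reporter_columns(psms)
  n0 <- nrow(psms)
  keep_flag <- !(psms$is_reverse | psms$is_contaminant)
  n_flag <- sum(!keep_flag)
  keep_score <- psms$search_score >= min_score
  n_score <- sum(keep_flag & !keep_score)
  rmax <- do.call(pmax, c(as.list(psms[rep_cols]), list(na.rm = TRUE)))
  keep_rep <- !is.na(rmax) & rmax >= min_reporter
  n_rep <- sum(keep_flag & keep_score & !keep_rep)
  out <- psms[keep_flag & keep_score & keep_rep, , drop = FALSE]
  report <- tibble(
    criterion = c("reverse_or_contaminant", "low_search_score",
                  "all_reporters_below_floor", "retained"),
    n = c(n_flag, n_score, n_rep, nrow(out))
  )
  if (nrow(out) == 0) {
    abort(paste0("no PSMs survive filtering (",
                 paste(report$criterion, report$n, sep = "=", collapse = ", "), ")"))
  }
  attr(out, "filter_report") <- report
  attr(out, "n_input") <- n0
  out
}

reporter_columns <- function(psms) {
  rc <- grep("^reporter_\\d+$", names(psms), value = TRUE)
  if (length(rc) == 0) abort("no reporter_NN columns found")
  rc[order(as.integer(sub("reporter_", "", rc)))]
}

#' Summarize filtered PSMs into protein-group quantities
#'
#' Reporter intensities are log2-transformed, median-centred per channel, and
#' summarized per protein group by the median over peptide-level values. Only
#' unique (proteotypic) peptides quantified in every channel contribute, and
#' protein groups need at least two distinct unique peptides.
#'
#' @param psms Output of [filter_psms()].
#' @param min_unique_peptides Minimum distinct unique peptides per protein
#'   group (default 2).
#' @param center Median-centre each channel in log2 space (default TRUE).
#' @return Wide tibble (`feature_id` = protein group, one log2 column per
#'   channel) plus per-protein peptide counts in the `peptide_counts`
#'   attribute. Dropped proteins are listed in the `dropped` attribute.
#' @export
summarize_protein_groups <- function(psms, min_unique_peptides = 2, center = TRUE) {
  rep_cols <- reporter_columns(psms)
  pep <- psms %>%
    filter(.data$is_unique_peptide) %>%
    group_by(.data$protein_group_id, .data$peptide_sequence) %>%
    summarise(dplyr::across(dplyr::all_of(rep_cols), ~ median(.x)), .groups = "drop")
  # complete-case rule: every channel must be observed (> 0)
  complete <- apply(as.matrix(pep[rep_cols]), 1, function(r) all(is.finite(r) & r > 0))
  pep <- pep[complete, , drop = FALSE]
  m <- log2(as.matrix(pep[rep_cols]))
  if (center) m <- sweep(m, 2, apply(m, 2, median), "-")
  pep[rep_cols] <- as_tibble(m)
  counts <- pep %>% dplyr::count(.data$protein_group_id, name = "n_unique_peptides")
  keep_ids <- counts$protein_group_id[counts$n_unique_peptides >= min_unique_peptides]
  dropped <- setdiff(unique(psms$protein_group_id), keep_ids)
  out <- pep %>%
    filter(.data$protein_group_id %in% keep_ids) %>%
    group_by(.data$protein_group_id) %>%
    summarise(dplyr::across(dplyr::all_of(rep_cols), ~ median(.x)), .groups = "drop") %>%
    rename(feature_id = "protein_group_id") %>%
    arrange(.data$feature_id)
  attr(out, "peptide_counts") <- counts
  attr(out, "dropped") <- dropped
  out
}

#' In-silico tryptic digestion
#'
#' Fully-tryptic peptides: cleavage C-terminal to K or R, suppressed when the
#' next residue is P; no missed cleavages. Unknown residues (X/B/Z/U/O) are
#' treated as non-cleaving and retained inside peptides.
#'
#' @param sequence Amino-acid string.
#' @return Character vector of peptides in N-to-C order (possibly empty).
#' @export
digest_tryptic <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) == 0) return(character())
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1] != "P"]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  vapply(seq_len(length(bounds) - 1L), function(i) {
    paste(aa[(bounds[i] + 1L):bounds[i + 1L]], collapse = "")
  }, character(1))
}

#' Count potentially observable unique tryptic peptides
#'
#' The iBAQ denominator: distinct fully-tryptic peptides of length 8--25
#' (inclusive), no missed cleavages.
#'
#' @param sequence Amino-acid string.
#' @param min_length,max_length Inclusive peptide-length window.
#' @return Integer count.
#' @export
digest_and_count_observable <- function(sequence, min_length = 8, max_length = 25) {
  peps <- digest_tryptic(sequence)
  len <- nchar(peps)
  length(unique(peps[len >= min_length & len <= max_length]))
}

#' Split precursor intensities into TMT channels
#'
#' The MS1 (precursor) area of a peptide is the sum of its TMT channels;
#' per-channel reporter ratios therefore split the precursor total into
#' channel intensity portions. Per peptide the channel ratio is the median
#' over its PSMs of `reporter_c / sum(reporters)`, renormalized to sum to 1;
#' after splitting, each channel is multiplied by the per-channel median
#' ratio to correct for sampling aberrations.
#'
#' @param psms Output of [filter_psms()].
#' @param correct Apply the per-channel median-ratio correction (default TRUE).
#' @return Tibble: `protein_group_id`, `peptide_sequence`,
#'   `is_unique_peptide`, `precursor_total`, and split `channel_NN` columns.
#'   With `correct = FALSE` the channel values of each peptide sum exactly to
#'   its precursor total.
#' @export
split_precursor_to_channels <- function(psms, correct = TRUE) {
  rep_cols <- reporter_columns(psms)
  rmat <- as.matrix(psms[rep_cols])
  rsum <- rowSums(rmat)
  usable <- rsum > 0 & psms$precursor_intensity > 0
  dropped <- unique(psms$peptide_sequence[!usable])
  dat <- psms[usable, , drop = FALSE]
  ratios <- rmat[usable, , drop = FALSE] / rsum[usable]

  key <- paste(dat$protein_group_id, dat$peptide_sequence, sep = "\r")
  split_idx <- split(seq_len(nrow(dat)), key)
  rows <- purrr::map(split_idx, function(ix) {
    r <- apply(ratios[ix, , drop = FALSE], 2, median)
    if (sum(r) == 0) return(NULL)
    r <- r / sum(r)
    total <- sum(dat$precursor_intensity[ix])
    c(total, total * r)
  })
  keep <- !vapply(rows, is.null, logical(1))
  rows <- rows[keep]
  ids <- do.call(rbind, strsplit(names(rows), "\r", fixed = TRUE))
  mat <- do.call(rbind, rows)
  chan_cols <- sub("reporter", "channel", rep_cols)
  out <- tibble(
    protein_group_id = ids[, 1],
    peptide_sequence = ids[, 2],
    precursor_total = mat[, 1]
  )
  out[chan_cols] <- as_tibble(mat[, -1, drop = FALSE], .name_repair = ~chan_cols)
  uniq <- dat %>%
    dplyr::distinct(.data$protein_group_id, .data$peptide_sequence,
                    .data$is_unique_peptide)
  out <- left_join(out, uniq, by = c("protein_group_id", "peptide_sequence"))
  if (correct) {
    # per-channel median of the peptide ratio vectors
    rm2 <- as.matrix(out[chan_cols]) / out$precursor_total
    corr <- apply(rm2, 2, median)
    out[chan_cols] <- as_tibble(sweep(as.matrix(out[chan_cols]), 2, corr, "*"),
                                .name_repair = ~chan_cols)
  }
  attr(out, "dropped_peptides") <- dropped
  attr(out, "corrected") <- correct
  out
}

#' Compute iBAQ intensities from split channel intensities
#'
#' Per protein and channel, unique-peptide intensities are summed and divided
#' by the number of potentially observable tryptic peptides; protein scores
#' are then median-normalized across samples: each channel is divided by its
#' median, so rescaling any one channel cancels exactly.
#'
#' @param split_table Output of [split_precursor_to_channels()].
#' @param observable_counts Named integer vector (or tibble with
#'   `protein_group_id`, `n_observable`) of observable-peptide counts.
#' @param unique_only Use only proteotypic peptides (default TRUE).
#' @param normalize Median-normalize across channels (default TRUE).
#' @return Wide tibble (`feature_id` × `channel_NN`) of iBAQ intensities on
#'   the linear scale. Proteins with zero observable peptides are excluded
#'   and listed in the `excluded` attribute.
#' @export
compute_ibaq <- function(split_table, observable_counts, unique_only = TRUE,
                         normalize = TRUE) {
  if (is.data.frame(observable_counts)) {
    observable_counts <- setNames(observable_counts$n_observable,
                                  observable_counts$protein_group_id)
  }
  chan_cols <- grep("^channel_\\d+$", names(split_table), value = TRUE)
  dat <- split_table
  if (unique_only) dat <- filter(dat, .data$is_unique_peptide)
  miss <- setdiff(unique(dat$protein_group_id), names(observable_counts))
  if (length(miss) > 0) {
    abort(paste0("no observable-peptide count for: ", paste(miss, collapse = ", ")))
  }
  prot <- dat %>%
    group_by(.data$protein_group_id) %>%
    summarise(dplyr::across(dplyr::all_of(chan_cols), sum), .groups = "drop")
  n_obs <- observable_counts[prot$protein_group_id]
  excluded <- prot$protein_group_id[n_obs == 0]
  prot <- prot[n_obs > 0, , drop = FALSE]
  if (nrow(prot) == 0) {
    out <- tibble(feature_id = character())
    out[chan_cols] <- lapply(chan_cols, function(x) double())
    attr(out, "excluded") <- excluded
    return(out)
  }
  m <- as.matrix(prot[chan_cols]) / n_obs[n_obs > 0]
  rownames(m) <- prot$protein_group_id
  if (normalize && nrow(m) > 0) {
    lm2 <- log2(m)
    med <- apply(lm2, 2, function(v) median(v[is.finite(v)]))
    m <- 2^sweep(lm2, 2, med, "-")
  }
  out <- matrix_as_omics(m) %>% arrange(.data$feature_id)
  attr(out, "excluded") <- excluded
  out
}
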