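# Shared fixture builders. Everything is generated in code; no files.

# A tiny wide omics tibble from a matrix-like specification.
wide_tbl <- function(m, features = NULL, samples = NULL) {
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  matrix_as_omics(m)
}

# Minimal PSM tibble; reporters given as a matrix (one row per PSM).
make_psms <- function(reporters, score = 50, reverse = FALSE, contaminant = FALSE,
                      peptide = NULL, protein = NULL, unique_pep = TRUE,
                      precursor = NULL) {
  n <- nrow(reporters)
  if (is.null(peptide)) peptide <- sprintf("PEPTIDEK%02d", seq_len(n))
  if (is.null(protein)) protein <- rep("P1", n)
  if (is.null(precursor)) precursor <- rowSums(reporters)
  out <- tibble::tibble(
    psm_id = sprintf("psm%03d", seq_len(n)),
    peptide_sequence = peptide,
    protein_group_id = protein,
    is_unique_peptide = rep_len(unique_pep, n),
    search_score = rep_len(score, n),
    is_reverse = rep_len(reverse, n),
    is_contaminant = rep_len(contaminant, n),
    precursor_intensity = precursor,
    run_id = "run1"
  )
  colnames(reporters) <- sprintf("reporter_%02d", seq_len(ncol(reporters)))
  dplyr::bind_cols(out, tibble::as_tibble(reporters))
}

# Brute-force observable-peptide counter: enumerate all substrings and keep
# those that are valid fully-tryptic peptides under the K/R-not-before-P rule.
brute_force_observable <- function(seq, min_len = 8, max_len = 25) {
  n <- nchar(seq)
  if (n == 0) return(0L)
  aa <- strsplit(seq, "")[[1]]
  is_cut <- function(i) {            # cleavage allowed after position i?
    if (i == 0 || i == n) return(TRUE)  # termini
    aa[i] %in% c("K", "R") && aa[i + 1] != "P"
  }
  peps <- character()
  for (start in 1:n) {
    for (end in start:n) {
      len <- end - start + 1
      if (len < min_len || len > max_len) next
      # fully tryptic: boundaries are cleavage sites, no internal site
      if (!is_cut(start - 1) || !is_cut(end)) next
      internal <- FALSE
      if (end - 1 >= start) {
        for (i in start:(end - 1)) if (is_cut(i)) { internal <- TRUE; break }
      }
      if (!internal) peps <- c(peps, substr(seq, start, end))
    }
  }
  length(unique(peps))
}

# Independent iBAQ reference: plain-loop recomputation of split + iBAQ from a
# filtered PSM table (no shared code with the package implementation).
reference_ibaq <- function(psms, n_observable, correct = TRUE) {
  rep_cols <- grep("^reporter_", names(psms), value = TRUE)
  keys <- unique(paste(psms$protein_group_id, psms$peptide_sequence, sep = "|"))
  pep_rows <- list()
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sel <- psms$protein_group_id == parts[1] & psms$peptide_sequence == parts[2]
    rmat <- as.matrix(psms[sel, rep_cols, drop = FALSE])
    rs <- rowSums(rmat)
    ok <- rs > 0 & psms$precursor_intensity[sel] > 0
    if (!any(ok)) next
    ratios <- rmat[ok, , drop = FALSE] / rs[ok]
    med <- apply(ratios, 2, stats::median)
    med <- med / sum(med)
    total <- sum(psms$precursor_intensity[sel][ok])
    pep_rows[[k]] <- list(protein = parts[1], unique = psms$is_unique_peptide[sel][1],
                          split = total * med, total = total)
  }
  split_mat <- do.call(rbind, lapply(pep_rows, `[[`, "split"))
  if (correct) {
    corr <- apply(split_mat / vapply(pep_rows, `[[`, numeric(1), "total"), 2,
                  stats::median)
    split_mat <- sweep(split_mat, 2, corr, "*")
  }
  prots <- unique(vapply(pep_rows, `[[`, character(1), "protein"))
  out <- matrix(0, length(prots), ncol(split_mat), dimnames = list(prots, NULL))
  for (i in seq_along(pep_rows)) {
    pr <- pep_rows[[i]]
    if (!pr$unique) next
    out[pr$protein, ] <- out[pr$protein, ] + split_mat[i, ]
  }
  out <- out / n_observable[rownames(out)]
  out[n_observable[rownames(out)] > 0, , drop = FALSE]
}
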