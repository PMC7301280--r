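#' Cohort design for synthetic studies
#'
#' Bundles the structural parameters every generator shares: a three-group
#' age design (young / adult / old) with a few animals per group, a gene
#' universe, and a complex catalog drawn from a size distribution.
#'
#' @param n_groups Number of age groups (default 3, labelled
#'   `young`, `adult`, `old`).
#' @param n_per_group Animals per group (>= 2; default 5).
#' @param n_genes Genes in the universe (default 2000).
#' @param n_complexes Protein complexes (default 20).
#' @param complex_size_range Inclusive size range for complexes (default
#'   5--60; sizes are drawn uniformly).
#' @param seed Integer seed; a fixed seed makes every generated object
#'   byte-identical across runs.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_groups = 3, n_per_group = 5, n_genes = 2000,
                          n_complexes = 20, complex_size_range = c(5, 60),
                          seed = 1) {
  stopifnot(n_per_group >= 2, n_genes >= 10, complex_size_range[1] >= 5)
  labels <- if (n_groups == 3) c("young", "adult", "old") else
    paste0("group", seq_len(n_groups))
  structure(list(n_groups = n_groups, n_per_group = n_per_group,
                 n_genes = n_genes, n_complexes = n_complexes,
                 complex_size_range = complex_size_range,
                 group_labels = labels, seed = seed),
            class = "cohort_design")
}

default_mechanism_fractions <- c(
  concordant = 0.30, transcript_consistent = 0.15, no_transcript = 0.10,
  mirna_explained = 0.10, other_post_transcriptional = 0.35
)

#' Generate a matched transcript/protein cohort with known truth
#'
#' Simulates the input surface of the decoupling analysis: transcript counts
#' (negative binomial around log-normal gene means), protein intensities
#' linked to transcripts through per-gene mechanism classes, an aging miRNA
#' differential table with a target map, and a truth record. Per-sample
#' log-log transcript-protein correlations can be steered to group-specific
#' targets: the per-sample protein noise variance is solved from the
#' realized transcript values so the achieved Pearson correlation lands
#' within about +/-0.05 of the target for `n_genes >= 2000`.
#'
#' Mechanism classes (applied to the `affected_fraction` of genes; the rest
#' are background `concordant` genes with zero fold change, marked
#' `affected = FALSE` in the truth):
#' * `concordant` -- transcript and protein share the fold change;
#' * `transcript_consistent` -- protein changes, transcript moves the same
#'   way but weakly (non-significant);
#' * `no_transcript` -- protein changes, transcript absent from the
#'   transcript matrix;
#' * `mirna_explained` -- protein down, transcript flat, gene targeted by an
#'   up-regulated miRNA;
#' * `other_post_transcriptional` -- protein changes, transcript flat, no
#'   miRNA assigned.
#'
#' @param design A [cohort_design()].
#' @param decoupling_targets Per-group target correlations in (0, 1), named
#'   by group label, or `NULL` to use a fixed `protein_noise_sd` instead.
#'   Unreachable targets (solved noise variance < 0) trigger a warning and
#'   report the achievable ceiling in the truth record.
#' @param mechanism_fractions Named fractions over the five classes (sum 1).
#' @param affected_fraction Fraction of genes receiving an aging effect
#'   (default 0.2).
#' @param effect_size Mean absolute protein log2 fold change for affected
#'   genes (old/adult vs young; default 1.5).
#' @param protein_noise_sd Per-sample log2 protein noise when
#'   `decoupling_targets` is NULL (default 0.1).
#' @param dispersion Negative-binomial gene dispersion (default 0.1).
#' @param transcript_bio_sd Extra per-sample biological log2 scatter given to
#'   `transcript_consistent` genes (default 0.8), which keeps their real
#'   trend below the significance threshold.
#' @param n_mirna miRNAs in the differential table (default 60).
#' @return List: `transcripts` (counts), `proteins` (linear intensities),
#'   `samples` (metadata: `sample_id`, `group`, `animal`), `mirna_de`,
#'   `mirna_targets`, `truth` (list with `genes` tibble, solved noise,
#'   achieved correlations).
#' @export
generate_omics_cohort <- function(design = cohort_design(),
                                  decoupling_targets = NULL,
                                  mechanism_fractions = default_mechanism_fractions,
                                  affected_fraction = 0.2,
                                  effect_size = 1.5,
                                  protein_noise_sd = 0.1,
                                  dispersion = 0.1,
                                  transcript_bio_sd = 0.8,
                                  n_mirna = 60) {
  stopifnot(abs(sum(mechanism_fractions) - 1) < 1e-8)
  if (!is.null(decoupling_targets)) {
    stopifnot(all(decoupling_targets > 0 & decoupling_targets < 1),
              length(decoupling_targets) == design$n_groups)
    if (is.null(names(decoupling_targets))) {
      names(decoupling_targets) <- design$group_labels
    }
  }
  classes_all <- c("concordant", "transcript_consistent", "no_transcript",
                   "mirna_explained", "other_post_transcriptional")
  mf <- mechanism_fractions[classes_all]
  mf[is.na(mf)] <- 0
  withr::with_seed(design$seed, {
    ng <- design$n_genes
    genes <- sprintf("gene_%04d", seq_len(ng))
    samples <- tibble(
      sample_id = paste0(rep(design$group_labels, each = design$n_per_group), "_",
                         rep(seq_len(design$n_per_group), design$n_groups)),
      group = rep(design$group_labels, each = design$n_per_group),
      animal = seq_len(design$n_groups * design$n_per_group)
    )

    # gene-level baseline (log2 mean abundance) and class assignment
    mu <- rnorm(ng, mean = 8, sd = 2)
    n_aff <- round(affected_fraction * ng)
    affected <- c(rep(TRUE, n_aff), rep(FALSE, ng - n_aff))
    cls <- rep("concordant", ng)
    if (n_aff > 0) {
      cls[seq_len(n_aff)] <- sample(classes_all, n_aff, replace = TRUE, prob = mf)
    }
    dmag <- abs(rnorm(ng, effect_size, 0.3))
    dsign <- sample(c(-1, 1), ng, replace = TRUE)
    dsign[cls == "mirna_explained"] <- -1
    d <- ifelse(affected, dmag * dsign, 0)

    # per-group fold changes (linear aging trajectory: 0, d/2, d)
    grp_scale <- seq(0, 1, length.out = design$n_groups)
    p_fc <- outer(d, grp_scale)                     # protein log2 fc per group
    t_fc <- p_fc
    t_fc[cls %in% c("mirna_explained", "other_post_transcriptional"), ] <- 0
    # consistent-but-not-significant genes: half the protein fold change plus
    # inflated biological scatter (added below), so the trend is real but
    # stays under the significance threshold
    t_fc[cls == "transcript_consistent", ] <-
      0.5 * t_fc[cls == "transcript_consistent", , drop = FALSE]
    detected <- cls != "no_transcript"

    # transcript counts: NB around 2^(mu + t_fc)
    tmat <- matrix(0L, ng, nrow(samples), dimnames = list(genes, samples$sample_id))
    bio_sd <- ifelse(cls == "transcript_consistent", transcript_bio_sd, 0)
    for (s in seq_len(nrow(samples))) {
      g <- match(samples$group[s], design$group_labels)
      mu_s <- 2^(mu + t_fc[, g] + rnorm(ng, 0, bio_sd))  # median depth ~250
      tmat[, s] <- rnbinom(ng, mu = mu_s, size = 1 / dispersion)
    }
    tmat <- tmat[detected, , drop = FALSE]

    # protein log2 signal
    sig <- matrix(0, ng, nrow(samples), dimnames = list(genes, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      g <- match(samples$group[s], design$group_labels)
      sig[, s] <- mu + p_fc[, g]
    }

    solved_sd <- rep(NA_real_, nrow(samples))
    unreachable <- character()
    pmat <- sig
    for (s in seq_len(nrow(samples))) {
      if (is.null(decoupling_targets)) {
        sd_s <- protein_noise_sd
      } else {
        target <- decoupling_targets[[samples$group[s]]]
        # solve noise sd from the realized transcript values of the detected
        # genes so that cor(log P, log T) = target for this sample; restrict
        # to positive counts, matching how the correlation is computed
        pos <- tmat[, s] > 0
        tx <- log10(tmat[pos, s])
        ps <- sig[detected, s][pos] * log10(2)       # protein signal, log10
        A <- stats::cov(tx, ps); vx <- var(tx); vm <- var(ps)
        s2 <- (A / target)^2 / vx - vm               # log10 variance
        if (s2 <= 0) {
          unreachable <- c(unreachable, samples$sample_id[s])
          sd_s <- 0.01
        } else {
          sd_s <- sqrt(s2) / log10(2)                # back to log2 units
        }
      }
      solved_sd[s] <- sd_s
      pmat[, s] <- sig[, s] + rnorm(ng, 0, sd_s)
    }
    if (length(unreachable) > 0) {
      warn(paste0("correlation target unreachable for sample(s): ",
                  paste(unreachable, collapse = ", "),
                  "; minimal noise used, achieved value reported in truth"))
    }
    proteins <- matrix_as_omics(2^pmat)
    transcripts <- matrix_as_omics(tmat)

    # achieved per-sample correlations
    achieved <- vapply(seq_len(nrow(samples)), function(s) {
      pos <- tmat[, s] > 0
      cor(log10(tmat[pos, s]), pmat[detected, s][pos])
    }, numeric(1))

    # miRNA layer: up-regulated significant miRNAs target the
    # mirna_explained genes; the rest are noise
    mirnas <- sprintf("mir_%03d", seq_len(n_mirna))
    up <- seq_len(max(1L, floor(n_mirna / 3)))
    mirna_de <- tibble(
      mirna_id = mirnas,
      log2fc = ifelse(seq_len(n_mirna) %in% up, abs(rnorm(n_mirna, 1.2, 0.3)),
                      rnorm(n_mirna, 0, 0.2)),
      p = ifelse(seq_len(n_mirna) %in% up, runif(n_mirna, 0, 1e-4),
                 runif(n_mirna, 0.2, 1))
    )
    mirna_de$adj_p <- bh_adjust(mirna_de$p)
    mir_genes <- genes[cls == "mirna_explained"]
    mirna_targets <- if (length(mir_genes) > 0) {
      tibble(mirna_id = sample(mirnas[up], length(mir_genes), replace = TRUE),
             feature_id = mir_genes)
    } else {
      tibble(mirna_id = character(), feature_id = character())
    }
    # decoys: some up-miRNAs also target unaffected genes
    n_decoy <- min(50L, ng - n_aff)
    if (n_decoy > 0) {
      decoy_genes <- sample(genes[!affected], n_decoy)
      mirna_targets <- bind_rows(mirna_targets,
        tibble(mirna_id = sample(mirnas[up], n_decoy, replace = TRUE),
               feature_id = decoy_genes))
    }

    truth_genes <- tibble(
      feature_id = genes, class = cls, affected = affected,
      baseline_log2 = mu, protein_log2fc_final = d,
      transcript_detected = detected
    )
    list(
      transcripts = transcripts,
      proteins = proteins,
      samples = samples,
      mirna_de = mirna_de,
      mirna_targets = mirna_targets,
      truth = list(genes = truth_genes,
                   protein_noise_sd = setNames(solved_sd, samples$sample_id),
                   achieved_correlation = setNames(achieved, samples$sample_id),
                   targets = decoupling_targets,
                   unreachable = unreachable)
    )
  })
}

#' Generate random protein sequences
#'
#' Uniform random amino-acid sequences over the 20-letter alphabet with K/R
#' frequency typical of tryptic proteomes.
#'
#' @param n Number of proteins.
#' @param length_range Sequence-length range (default 80--400).
#' @param seed Integer seed.
#' @return Named character vector (`prot_0001`, ...).
#' @export
generate_protein_sequences <- function(n, length_range = c(80, 400), seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20); names(w) <- aa
  w[c("K", "R")] <- 1.6; w[c("L", "A", "S")] <- 1.4; w["W"] <- 0.4
  withr::with_seed(seed, {
    lr <- seq.int(length_range[1], length_range[2])
    lens <- if (length(lr) == 1) rep(lr, n) else sample(lr, n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE, prob = w), collapse = "")
    }, character(1))
    setNames(seqs, sprintf("prot_%04d", seq_len(n)))
  })
}

#' Generate a synthetic PSM table
#'
#' Builds PSMs from tryptic peptides of the supplied proteins with
#' channel-wise reporter intensities consistent with per-channel protein
#' abundances, a search-score mixture with a controlled low-score fraction,
#' decoy (`reverse`) and contaminant records, and precursor intensities
#' equal to the reporter sum times a per-PSM scale factor.
#'
#' @param sequences Named character vector of protein sequences.
#' @param n_channels Plex width (default 10).
#' @param psms_per_peptide Mean PSMs per sampled peptide (default 1.5).
#' @param frac_low_score Fraction of target PSMs drawn below the score
#'   cutoff of 15 (default 0.1).
#' @param decoy,contamination Fractions of extra decoy / contaminant PSMs
#'   relative to the target PSM count (in `[0, 1)`).
#' @param noise_sd Log-normal reporter noise sd (log2 units; default 0.1).
#' @param seed Integer seed.
#' @return List: `psms` (tibble), `abundance` (true protein-by-channel log2
#'   matrix as a wide tibble), `truth` (per-protein observable-peptide
#'   counts; proteins with zero observable peptides yield no PSMs).
#' @export
generate_psm_table <- function(sequences, n_channels = 10,
                               psms_per_peptide = 1.5, frac_low_score = 0.1,
                               decoy = 0.05, contamination = 0.02,
                               noise_sd = 0.1, seed = 1) {
  stopifnot(length(sequences) > 0, decoy >= 0, decoy < 1,
            contamination >= 0, contamination < 1)
  withr::with_seed(seed, {
    prot_ids <- names(sequences)
    abund <- matrix(rnorm(length(sequences) * n_channels, 16, 1.5),
                    nrow = length(sequences),
                    dimnames = list(prot_ids, sprintf("channel_%02d", seq_len(n_channels))))
    rows <- list()
    n_obs <- integer(length(sequences)); names(n_obs) <- prot_ids
    psm_i <- 0L
    for (pi in seq_along(sequences)) {
      peps <- digest_tryptic(sequences[[pi]])
      len <- nchar(peps)
      obs <- unique(peps[len >= 8 & len <= 25])
      n_obs[pi] <- length(obs)
      if (length(obs) == 0) next
      sampled <- obs[runif(length(obs)) < 0.8]
      if (length(sampled) == 0) sampled <- obs[1]
      for (pep in sampled) {
        n_psm <- max(1L, stats::rpois(1, psms_per_peptide))
        eff <- 2^rnorm(1, 0, 0.5)  # peptide ionization efficiency
        for (j in seq_len(n_psm)) {
          psm_i <- psm_i + 1L
          rep_int <- 2^(abund[pi, ] + rnorm(n_channels, 0, noise_sd)) * eff / 50
          rows[[psm_i]] <- c(list(
            psm_id = sprintf("psm_%06d", psm_i),
            peptide_sequence = pep,
            protein_group_id = prot_ids[pi],
            is_unique_peptide = TRUE,
            search_score = if (runif(1) < frac_low_score) runif(1, 2, 14.99)
                           else 15 + stats::rexp(1, 1 / 35),
            is_reverse = FALSE, is_contaminant = FALSE,
            precursor_intensity = sum(rep_int) * 2^rnorm(1, 0, 0.2),
            run_id = "run_1"
          ), setNames(as.list(rep_int), sprintf("reporter_%02d", seq_len(n_channels))))
        }
      }
    }
    psms <- bind_rows(lapply(rows, as_tibble))
    n_target <- nrow(psms)
    extra <- function(n, reverse, contam, tag) {
      if (n == 0) return(NULL)
      purrr::map(seq_len(n), function(i) {
        rep_int <- 2^rnorm(n_channels, 14, 1.5)
        as_tibble(c(list(
          psm_id = sprintf("psm_%s_%05d", tag, i),
          peptide_sequence = paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                          12, replace = TRUE), collapse = ""),
          protein_group_id = paste0(tag, "_", i),
          is_unique_peptide = TRUE,
          search_score = 15 + stats::rexp(1, 1 / 35),
          is_reverse = reverse, is_contaminant = contam,
          precursor_intensity = sum(rep_int),
          run_id = "run_1"
        ), setNames(as.list(rep_int), sprintf("reporter_%02d", seq_len(n_channels)))))
      })
    }
    psms <- bind_rows(psms,
                      bind_rows(extra(round(decoy * n_target), TRUE, FALSE, "REV")),
                      bind_rows(extra(round(contamination * n_target), FALSE, TRUE, "CON")))
    list(psms = psms,
         abundance = matrix_as_omics(abund),
         truth = list(n_observable = n_obs,
                      zero_psm_proteins = prot_ids[n_obs == 0],
                      frac_low_score = frac_low_score))
  })
}

#' Generate a random complex catalog
#'
#' @param n_proteins Universe size; ids `prot_0001`...
#' @param n_complexes Number of complexes.
#' @param size_range Inclusive size range (default 5--12).
#' @param seed Integer seed.
#' @return Named list of disjointly sampled member vectors (`cpx_01`, ...).
#' @export
generate_complex_catalog <- function(n_proteins, n_complexes,
                                     size_range = c(5, 12), seed = 1) {
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  withr::with_seed(seed, {
    sz <- seq.int(size_range[1], size_range[2])
    sizes <- if (length(sz) == 1) rep(sz, n_complexes) else
      sample(sz, n_complexes, replace = TRUE)
    stopifnot(sum(sizes) <= n_proteins)
    pool <- sample(ids)
    start <- cumsum(c(1, head(sizes, -1)))
    out <- purrr::map2(start, sizes, function(s, k) pool[seq(s, s + k - 1)])
    setNames(out, sprintf("cpx_%02d", seq_len(n_complexes)))
  })
}

#' Generate SEC co-elution profiles for two conditions
#'
#' Members of a complex share a Gaussian elution apex (plus a small member
#' jitter); in the second ("old") condition selected complexes have their
#' apex displaced by the requested shift (positive = later elution). Free
#' proteins get independent apexes. Apexes pushed outside the fraction axis
#' are clipped with a warning.
#'
#' @param catalog Named list of member vectors.
#' @param n_fractions Fractions along the chromatogram (default 39).
#' @param shifts Named numeric vector of per-complex fraction offsets
#'   (names must be catalog complexes; others error).
#' @param n_free Free (non-complex) proteins to add (default 50).
#' @param noise_sd Multiplicative log-normal intensity noise sd (default 0.05).
#' @param member_jitter Sd of the per-member apex jitter (default 0.5).
#' @param peak_width Gaussian elution peak sd in fractions (default 1.5).
#' @param seed Integer seed.
#' @return List: `young`, `old` (wide raw-intensity tibbles), `truth`
#'   (per-complex apexes and shifts).
#' @export
generate_sec_profiles <- function(catalog, n_fractions = 39, shifts = NULL,
                                  n_free = 50, noise_sd = 0.05,
                                  member_jitter = 0.5, peak_width = 1.5,
                                  seed = 1) {
  if (!is.null(shifts)) {
    bad <- setdiff(names(shifts), names(catalog))
    if (length(bad) > 0) abort(paste0("shift(s) for unknown complex: ",
                                      paste(bad, collapse = ", ")))
  }
  withr::with_seed(seed, {
    members <- unique(unlist(catalog))
    free <- if (n_free > 0) sprintf("free_%03d", seq_len(n_free)) else character()
    all_ids <- c(members, free)
    fr <- seq_len(n_fractions)

    apex_young <- setNames(numeric(length(all_ids)), all_ids)
    apex_old <- apex_young
    cpx_apex <- setNames(runif(length(catalog), 6, n_fractions - 6), names(catalog))
    clipped <- character()
    for (cid in names(catalog)) {
      jit <- rnorm(length(catalog[[cid]]), 0, member_jitter)
      a_y <- cpx_apex[cid] + jit
      sh <- if (!is.null(shifts) && cid %in% names(shifts)) shifts[[cid]] else 0
      a_o <- a_y + sh
      if (any(a_o < 1 | a_o > n_fractions)) clipped <- c(clipped, cid)
      apex_young[catalog[[cid]]] <- pmin(pmax(a_y, 1), n_fractions)
      apex_old[catalog[[cid]]] <- pmin(pmax(a_o, 1), n_fractions)
    }
    if (length(free) > 0) {
      a <- runif(length(free), 1, n_fractions)
      apex_young[free] <- a
      apex_old[free] <- a
    }
    if (length(clipped) > 0) {
      warn(paste0("shift clips apex to the fraction axis for: ",
                  paste(unique(clipped), collapse = ", ")))
    }
    amp <- setNames(2^rnorm(length(all_ids), 20, 1), all_ids)
    build <- function(apexes) {
      m <- t(vapply(all_ids, function(id) {
        base <- amp[id] * dnorm(fr, apexes[id], peak_width)
        if (noise_sd > 0) base <- base * 2^rnorm(n_fractions, 0, noise_sd)
        base
      }, numeric(n_fractions)))
      colnames(m) <- sprintf("fraction_%02d", fr)
      matrix_as_omics(m)
    }
    list(young = build(apex_young), old = build(apex_old),
         truth = list(complex_apex = cpx_apex,
                      shifts = if (is.null(shifts)) setNames(numeric(0), character(0)) else shifts,
                      member_apex_young = apex_young,
                      member_apex_old = apex_old))
  })
}

#' Generate an aggregate (pellet vs homogenate) experiment
#'
#' Total-homogenate and pellet log2 intensity matrices with `n_replicates`
#' each; proteins in `enriched_set` receive a pellet-minus-homogenate log2
#' shift drawn around `shift_mean`, and per-protein biophysical classifier
#' outputs are generated with a controllable link to the true enrichment.
#'
#' @param n_proteins Universe size.
#' @param enriched_set Character vector of enriched protein ids (subset of
#'   `prot_0001...`; empty for a null experiment).
#' @param n_replicates Replicates per label (default 3).
#' @param shift_mean,shift_sd True enrichment shift distribution (default
#'   +1, 0.3).
#' @param noise_sd Replicate log2 noise (default 0.2).
#' @param score_link Correlation strength in \[0, 1\] between the
#'   biophysical scores and the true enrichment (`0` = independent).
#' @param seed Integer seed.
#' @return List: `data` (wide log2 tibble), `samples` (metadata with
#'   `label`), `scores` (tibble `feature_id`, `clever_label`, `clever_p`,
#'   `clever_score`, `n_coil`, `n_residues`, `s2d_score`), `truth`.
#' @export
generate_aggregate_experiment <- function(n_proteins, enriched_set = character(),
                                          n_replicates = 3, shift_mean = 1,
                                          shift_sd = 0.3, noise_sd = 0.2,
                                          score_link = 0.6, seed = 1) {
  ids <- sprintf("prot_%04d", seq_len(n_proteins))
  if (!all(enriched_set %in% ids)) abort("enriched_set must be a subset of the universe")
  stopifnot(score_link >= 0, score_link <= 1, n_replicates >= 2)
  withr::with_seed(seed, {
    base <- rnorm(n_proteins, 25, 2)
    shift <- setNames(numeric(n_proteins), ids)
    shift[enriched_set] <- rnorm(length(enriched_set), shift_mean, shift_sd)
    th_cols <- sprintf("TH_%d", seq_len(n_replicates))
    pe_cols <- sprintf("Pellet_%d", seq_len(n_replicates))
    m <- cbind(
      matrix(rnorm(n_proteins * n_replicates, base, noise_sd), n_proteins,
             dimnames = list(ids, th_cols)),
      matrix(rnorm(n_proteins * n_replicates, base + shift, noise_sd), n_proteins,
             dimnames = list(ids, pe_cols))
    )
    samples <- tibble(sample_id = c(th_cols, pe_cols),
                      label = rep(c("TH", "Pellet"), each = n_replicates))

    z_enrich <- as.numeric(scale(shift))
    if (all(shift == 0)) z_enrich <- rep(0, n_proteins)
    latent <- score_link * z_enrich +
      sqrt(max(0, 1 - score_link^2)) * rnorm(n_proteins)
    clever_p <- 0.5 + 0.5 * stats::plogis(1.5 * abs(latent))
    clever_p <- pmin(clever_p, 1)
    lab <- ifelse(abs(latent) < 0.2, "indeterminate",
                  ifelse(latent > 0, "positive", "negative"))
    n_res <- sample(100:800, n_proteins, replace = TRUE)
    coil_frac <- stats::plogis(0.8 * latent + rnorm(n_proteins, -0.5, 0.3))
    n_coil <- rbinom(n_proteins, n_res, coil_frac)
    scores <- tibble(
      feature_id = ids, clever_label = lab, clever_p = clever_p,
      clever_score = clever_score(lab, clever_p),
      n_coil = n_coil, n_residues = n_res,
      s2d_score = s2d_score(n_coil, n_res)
    )
    list(data = matrix_as_omics(m), samples = samples, scores = scores,
         truth = list(enriched_set = enriched_set, shift = shift,
                      score_link = score_link))
  })
}

#' Generate a longitudinal expression-to-lifespan cohort
#'
#' Per-fish gene expression changes \eqn{\Delta_{ij}} (Gaussian per gene)
#' and lifespans drawn from the proportional-hazards model
#' \eqn{h(t \mid \Delta_j) = h_0 \exp(\sum_i c_i \Delta_{ij})} with an
#' exponential baseline, by inverse-transform sampling conditional on
#' survival past the second sampling time (so every fish enters the risk
#' set at `entry_time`).
#'
#' @param n_fish Cohort size (default 159).
#' @param n_genes Genes in the matrix (default 200).
#' @param risk_sets Named list of gene sets with per-set coefficients given
#'   in `coefficients` (e.g. `list(proteasome = c("gene_0001", ...))`).
#' @param coefficients Named numeric vector, one value per risk set
#'   (applied to each member gene). Non-finite values error.
#' @param delta_sd Per-gene sd of \eqn{\Delta} (default 1).
#' @param baseline_rate Exponential baseline hazard per week (default 0.03).
#' @param entry_time Second sampling time in weeks (default 20).
#' @param seed Integer seed.
#' @return List: `delta` (wide tibble genes x fish), `surv` (tibble
#'   `fish_id`, `lifespan`, `event`, `entry_time`), `truth` (per-gene true
#'   coefficients).
#' @export
generate_longitudinal_survival <- function(n_fish = 159, n_genes = 200,
                                           risk_sets = list(),
                                           coefficients = numeric(),
                                           delta_sd = 1,
                                           baseline_rate = 0.03,
                                           entry_time = 20, seed = 1) {
  if (length(risk_sets) > 0) {
    stopifnot(identical(sort(names(risk_sets)), sort(names(coefficients))))
    if (!all(is.finite(coefficients))) abort("non-finite coefficients")
  }
  withr::with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    fish <- sprintf("fish_%03d", seq_len(n_fish))
    delta <- matrix(rnorm(n_genes * n_fish, 0, delta_sd), n_genes, n_fish,
                    dimnames = list(genes, fish))
    cvec <- setNames(rep(0, n_genes), genes)
    for (s in names(risk_sets)) {
      mem <- intersect(risk_sets[[s]], genes)
      cvec[mem] <- coefficients[[s]]
    }
    eta <- as.numeric(crossprod(delta, cvec))
    # exponential baseline is memoryless: conditional on surviving to entry,
    # the residual lifetime is Exp(h0 * exp(eta))
    lifespan <- entry_time + rexp(n_fish, rate = baseline_rate * exp(eta))
    surv <- tibble(fish_id = fish, lifespan = lifespan, event = 1L,
                   entry_time = entry_time)
    list(delta = matrix_as_omics(delta), surv = surv,
         truth = list(coefficients = cvec, baseline_rate = baseline_rate,
                      linear_predictor = setNames(eta, fish)))
  })
}

#' Null Gaussian matrix helper
#'
#' A features-by-samples matrix of iid Gaussian noise with two sample groups
#' (`a1..an`, `b1..bn`); convenient for calibration checks and examples.
#'
#' @param n_features,n_a,n_b Dimensions.
#' @param sd Noise sd (default 1).
#' @param seed Integer seed.
#' @return Wide tibble.
#' @export
simulate_null_matrix <- function(n_features, n_a, n_b, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_features * (n_a + n_b), 0, sd), n_features,
                dimnames = list(sprintf("f_%04d", seq_len(n_features)),
                                c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b)))))
    matrix_as_omics(m)
  })
}
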