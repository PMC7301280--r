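#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic run, with the package
#' defaults. Unknown keys passed to [run_pipeline()] are rejected.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_config <- function() {
  list(
    n_per_group = 5, n_genes = 2000, n_complexes = 20,
    decoupling_targets = c(young = 0.48, adult = 0.43, old = 0.33),
    adj_p = 0.05, min_abs_fc = 0.5, trim = 0.2, min_members = 5,
    n_fractions = 39, sec_n_draws = 200, sec_min_shift = 2,
    aggregate_n_proteins = 800, aggregate_n_enriched = 80,
    n_fish = 159, logrank_k = 32,
    stages = c("cohort", "decoupling", "stoichiometry", "sec",
               "aggregates", "survival")
  )
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a synthetic multi-omics cohort and pushes it through every
#' analysis stage, writing stage outputs as commented TSVs plus a JSON
#' provenance manifest (config, seed, package version) that suffices to
#' reproduce the run byte-identically.
#'
#' @param config Named list overriding entries of
#'   [default_pipeline_config()]; unknown keys error.
#' @param seed Integer master seed; every stochastic stage receives a seed
#'   derived from it.
#' @param outdir Output directory (created if missing); `NULL` skips
#'   writing files.
#' @return (Invisibly) a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), seed = 1, outdir = NULL) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, config)
  seeds <- seed + seq_len(6)  # one derived seed per stochastic stage
  results <- list()
  stage_on <- function(s) s %in% cfg$stages

  if (stage_on("cohort") || stage_on("decoupling") || stage_on("stoichiometry")) {
    design <- cohort_design(n_per_group = cfg$n_per_group, n_genes = cfg$n_genes,
                            n_complexes = cfg$n_complexes, seed = seeds[1])
    cohort <- generate_omics_cohort(design,
                                    decoupling_targets = cfg$decoupling_targets)
    results$cohort <- cohort
  }

  if (stage_on("decoupling")) {
    cor_res <- per_sample_correlation(cohort$proteins, cohort$transcripts,
                                      cohort$samples)
    grp <- split(cohort$samples$sample_id, cohort$samples$group)
    prot_log2 <- matrix_as_omics(log2(omics_as_matrix(cohort$proteins)))
    de_adult <- moderated_t_test(prot_log2, grp$adult, grp$young)
    de_old <- moderated_t_test(prot_log2, grp$old, grp$adult)
    tr_adult <- transcript_de(cohort$transcripts, grp$adult, grp$young)
    tr_old <- transcript_de(cohort$transcripts, grp$old, grp$adult)
    mech <- classify_mechanism(de_old, tr_old,
                               transcript_detected = cohort$transcripts$feature_id,
                               mirna_de = cohort$mirna_de,
                               target_map = cohort$mirna_targets,
                               adj_p = cfg$adj_p)
    results$decoupling <- list(
      correlation = cor_res,
      quadrants = concordance_quadrants(de_old, tr_old, cfg$adj_p),
      mechanism = mech,
      protein_de = list(adult_vs_young = de_adult, old_vs_adult = de_old),
      transcript_de = list(adult_vs_young = tr_adult, old_vs_adult = tr_old)
    )
  }

  if (stage_on("stoichiometry")) {
    catalog <- generate_complex_catalog(cfg$n_genes, cfg$n_complexes, seed = seeds[2])
    catalog <- lapply(catalog, function(x) sub("prot_", "gene_", x))
    grp <- split(cohort$samples$sample_id, cohort$samples$group)
    prot_log2 <- matrix_as_omics(log2(omics_as_matrix(cohort$proteins)))
    norm <- normalize_to_complex(prot_log2, catalog, trim = cfg$trim,
                                 min_members = cfg$min_members)
    calls <- call_affected(norm, grp$old, grp$adult, adj_p = cfg$adj_p,
                           min_abs_fc = cfg$min_abs_fc)
    results$stoichiometry <- list(catalog = catalog, calls = calls)
  }

  if (stage_on("sec")) {
    sec_cat <- generate_complex_catalog(400, 12, size_range = c(5, 10),
                                        seed = seeds[3])
    sec <- generate_sec_profiles(sec_cat, n_fractions = cfg$n_fractions,
                                 shifts = c(cpx_01 = 4), seed = seeds[3])
    young <- normalize_sec_profiles(sec$young)
    old <- normalize_sec_profiles(sec$old)
    nul <- random_complex_null(young, sec_cat, n_draws = cfg$sec_n_draws,
                               seed = seeds[4])
    shift <- detect_elution_shift(
      complex_profile(young, sec_cat$cpx_01),
      complex_profile(old, sec_cat$cpx_01),
      min_shift = cfg$sec_min_shift)
    results$sec <- list(null = nul, shift = shift, truth = sec$truth)
  }

  if (stage_on("aggregates")) {
    agg <- generate_aggregate_experiment(
      cfg$aggregate_n_proteins,
      enriched_set = sprintf("prot_%04d", seq_len(cfg$aggregate_n_enriched)),
      seed = seeds[5])
    enr <- aggregate_enrichment(agg$data, agg$samples)
    ext <- compare_extremes(
      dplyr::inner_join(select(as_tibble(enr), "feature_id", "log2fc"),
                        select(agg$scores, "feature_id", score = "s2d_score"),
                        by = "feature_id"))
    results$aggregates <- list(enrichment = enr, extremes = ext, truth = agg$truth)
  }

  if (stage_on("survival")) {
    lon <- generate_longitudinal_survival(
      n_fish = cfg$n_fish,
      risk_sets = list(proteasome = sprintf("gene_%04d", 1:30)),
      coefficients = c(proteasome = -0.5), seed = seeds[6])
    cox <- genewise_cox(lon$delta, lon$surv)
    lr <- extreme_group_logrank(lon$delta, lon$surv,
                                gene_set = sprintf("gene_%04d", 1:30),
                                k = cfg$logrank_k)
    results$survival <- list(cox = cox, logrank = lr, truth = lon$truth)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(stage) paste0(stage, " | params=", cfg_hash(cfg))
    if (!is.null(results$cohort)) {
      write_omics_tsv(results$cohort$transcripts,
                      file.path(outdir, "transcripts.tsv"), stamp("cohort"))
      write_omics_tsv(results$cohort$proteins,
                      file.path(outdir, "proteins.tsv"), stamp("cohort"))
      readr::write_tsv(results$cohort$samples, file.path(outdir, "samples.tsv"))
    }
    if (!is.null(results$decoupling)) {
      readr::write_tsv(as_tibble(results$decoupling$correlation),
                       file.path(outdir, "per_sample_correlation.tsv"))
      readr::write_tsv(results$decoupling$mechanism,
                       file.path(outdir, "mechanism_classes.tsv"))
    }
    if (!is.null(results$stoichiometry)) {
      write_gmt(results$stoichiometry$catalog, file.path(outdir, "complexes.gmt"))
      readr::write_tsv(select(as_tibble(results$stoichiometry$calls),
                              -"affected_members"),
                       file.path(outdir, "complex_calls.tsv"))
    }
    if (!is.null(results$survival)) {
      readr::write_tsv(as_tibble(results$survival$cox),
                       file.path(outdir, "genewise_cox.tsv"))
    }
    manifest <- list(
      package = "proteoage",
      version = as.character(utils::packageVersion("proteoage")),
      seed = seed, derived_seeds = seeds, config = cfg
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}

# Short deterministic hash of a config list (provenance stamps).
cfg_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 97)) %% .Machine$integer.max)
}
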