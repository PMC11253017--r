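#' Export / read a per-allele SNP score file
#'
#' Three tab-separated columns (`snp_id`, `allele`, `coefficient`), plus an
#' optional `frequency` column used for mean-imputing missing calls when
#' scoring. The layout matches standard per-allele score files so the
#' coefficients are consumable by external scorers; [score_lines()] on the
#' training panel reproduces the in-memory scores bit-exactly after a
#' round trip (frequencies included).
#'
#' @param model `snp_effect_model`.
#' @param path Output path.
#' @param include_freq Also write the `frequency` column (default TRUE;
#'   without it, scoring panels with missing calls loses the training
#'   imputation frequencies).
#' @return `export_coefficients` returns `path` invisibly;
#'   `read_snp_effects` returns a `snp_effect_model` (with `other_allele`
#'   `NA`: flips cannot be detected without it, matches by effect allele).
#' @export
export_coefficients <- function(model, path, include_freq = TRUE) {
  stopifnot(inherits(model, "snp_effect_model"))
  if (length(model$snp_ids) == 0) stop("empty model", call. = FALSE)
  # %.17g survives the text round trip without losing a bit
  df <- data.frame(snp_id = model$snp_ids, allele = model$effect_allele,
                   coefficient = sprintf("%.17g", model$coefficient))
  if (include_freq) df$frequency <- sprintf("%.17g", model$frequency)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_coefficients
#' @param other_alleles Optional named character vector (by snp_id) giving
#'   the non-effect allele, enabling allele-flip reconciliation on scoring.
#' @export
read_snp_effects <- function(path, other_alleles = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "allele", "coefficient")
  if (!all(need %in% names(df))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  oa <- if (is.null(other_alleles)) rep(NA_character_, nrow(df)) else
    unname(other_alleles[df$snp_id])
  structure(
    list(snp_ids = df$snp_id, effect_allele = df$allele,
         other_allele = oa, coefficient = df$coefficient,
         frequency = df$frequency %||% rep(NA_real_, nrow(df)),
         mu = NA_real_, n_train = NA_integer_, m = sum(df$coefficient != 0),
         sigma_g2 = NA_real_, sigma_e2 = NA_real_),
    class = "snp_effect_model"
  )
}

#' Run the full genomic-selection analysis end to end
#'
#' Orchestrates the pipeline: simulate (or load) genotypes and phenotypes,
#' QC-filter, compute the GRM, fit REML/BLUP and back-solve SNP
#' coefficients per trait on the full panel, cross-validate prediction
#' accuracy per trait, and compute response to selection. All tables are
#' written under `out_dir` and summarized in a JSON manifest with per-file
#' MD5 checksums, so identical configs reproduce identical artifacts.
#'
#' Exactly one of `sim_config` or (`genotype_prefix` + `phenotype_path`)
#' must be given.
#'
#' @param sim_config A [panel_config()] to simulate from.
#' @param genotype_prefix PLINK prefix to load instead of simulating.
#' @param genotype_dialect `"binary"` or `"text"`.
#' @param phenotype_path Phenotype TSV to load instead of simulating.
#' @param out_dir Output directory (created if needed).
#' @param qc QC thresholds, as for [qc_filter()].
#' @param grm_diagonal,grm_missing_max GRM options.
#' @param cv_k,cv_seed,nominal,adjusted Cross-validation options.
#' @param selection_k Selected-set size for response to selection.
#' @return Invisibly, a list with all in-memory results (`panel`,
#'   `qc_report`, `grm`, per-trait `fits`, `cv`, `selection`,
#'   `manifest`).
#' @export
run_pipeline <- function(sim_config = NULL, genotype_prefix = NULL,
                         genotype_dialect = "binary", phenotype_path = NULL,
                         out_dir,
                         qc = list(max_snp_missing = 0.05, min_maf = 0.01,
                                   max_sample_missing = 0.05),
                         grm_diagonal = "yang", grm_missing_max = 0.02,
                         cv_k = 5, cv_seed = 1, nominal = 0.05,
                         adjusted = 0.001, selection_k = 30) {
  t0 <- Sys.time()
  simulate <- !is.null(sim_config)
  load_files <- !is.null(genotype_prefix) || !is.null(phenotype_path)
  if (simulate == load_files) {
    stop("provide exactly one of sim_config or ",
         "(genotype_prefix + phenotype_path)", call. = FALSE)
  }
  if (load_files && (is.null(genotype_prefix) || is.null(phenotype_path))) {
    stop("both genotype_prefix and phenotype_path are required when ",
         "loading from files", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[gsblup] ", sprintf(...))

  timing <- list()
  tick <- function(stage, t_start) {
    timing[[stage]] <<- round(as.numeric(Sys.time() - t_start, units = "secs"), 3)
  }

  # --- stage: input ---------------------------------------------------
  ts <- Sys.time()
  if (simulate) {
    log_stage("simulating panel: %d lines x %d SNPs, %d traits, seed %d",
              sim_config$n_lines, sim_config$n_snps, sim_config$n_traits,
              sim_config$seed)
    sim <- simulate_panel(sim_config)
    panel0 <- sim$panel
    phenos <- sim$phenotypes
    write_plink(panel0, file.path(out_dir, "panel"), dialect = "binary")
    write_phenotypes(phenos, file.path(out_dir, "phenotypes.tsv"))
    write_panel_config(sim_config, file.path(out_dir, "panel_config.yaml"))
    utils::write.table(
      data.frame(line_id = rownames(sim$architecture$true_bv),
                 sim$architecture$true_bv, check.names = FALSE),
      file.path(out_dir, "true_breeding_values.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    log_stage("loading genotypes from %s (%s) and phenotypes from %s",
              genotype_prefix, genotype_dialect, phenotype_path)
    panel0 <- read_plink(genotype_prefix, dialect = genotype_dialect)
    phenos <- read_phenotypes(phenotype_path)
  }
  traits <- unique(phenos$trait)
  tick("input", ts)

  # --- stage: QC ------------------------------------------------------
  ts <- Sys.time()
  qc_res <- qc_filter(panel0, qc$max_snp_missing %||% 0.05,
                      qc$min_maf %||% 0.01, qc$max_sample_missing %||% 0.05)
  panel <- qc_res$panel
  log_stage("QC: %d -> %d SNPs, %d -> %d lines",
            qc_res$report$n_snps_in, qc_res$report$n_snps_out,
            qc_res$report$n_samples_in, qc_res$report$n_samples_out)
  write_qc_report(qc_res$report, file.path(out_dir, "qc_report.json"))
  tick("qc", ts)

  # --- stage: GRM -----------------------------------------------------
  ts <- Sys.time()
  grm <- compute_grm(panel, diagonal = grm_diagonal,
                     grm_missing_max = grm_missing_max)
  log_stage("GRM: %d lines from %d SNPs (%s diagonal)",
            length(grm$sample_ids), length(grm$snp_ids), grm$diagonal)
  write_grm_tsv(grm, file.path(out_dir, "grm.tsv"))
  tick("grm", ts)

  # --- stage: per-trait fit on the full panel ------------------------
  ts <- Sys.time()
  fits <- list()
  herit_rows <- list()
  mean_rows <- list()
  for (tr in traits) {
    y <- line_means(phenos, tr, sample_ids = panel$sample_ids)
    vc <- reml_fit(y, grm)
    bv <- blup_breeding_values(vc, y, grm)
    model <- backsolve_snp_effects(bv, vc, panel)
    fits[[tr]] <- list(vc = vc, bv = bv, model = model)
    write_variance_components(
      vc, file.path(out_dir, sprintf("variance_components_%s.json", tr)))
    write_breeding_values(
      bv, file.path(out_dir, sprintf("breeding_values_%s.tsv", tr)))
    export_coefficients(
      model, file.path(out_dir, sprintf("snp_effects_%s.tsv", tr)))
    herit_rows[[tr]] <- data.frame(trait = tr, sigma_g2 = vc$sigma_g2,
                                   sigma_e2 = vc$sigma_e2, h2 = vc$h2,
                                   se_h2 = vc$se_h2,
                                   converged = vc$converged)
    mean_rows[[tr]] <- data.frame(trait = tr, mean = mean(y),
                                  sd = stats::sd(y), n = length(y))
    log_stage("fit %s: h2 = %.3f (SE %.3f)", tr, vc$h2, vc$se_h2)
  }
  utils::write.table(do.call(rbind, herit_rows),
                     file.path(out_dir, "heritability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, mean_rows),
                     file.path(out_dir, "trait_means.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(traits) >= 2) {
    utils::write.table(
      data.frame(trait = rownames(trait_correlation_matrix(phenos)),
                 trait_correlation_matrix(phenos), check.names = FALSE),
      file.path(out_dir, "trait_correlations.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }
  tick("fit", ts)

  # --- stage: cross-validation ---------------------------------------
  ts <- Sys.time()
  cv <- list()
  cv_rows <- list()
  for (tr in traits) {
    rep_tr <- cross_validate(panel, phenos, tr, k = cv_k, seed = cv_seed,
                             nominal = nominal, adjusted = adjusted,
                             diagonal = grm_diagonal,
                             grm_missing_max = grm_missing_max)
    cv[[tr]] <- rep_tr
    cv_rows[[tr]] <- rep_tr$folds
    log_stage("cv %s: mean r = %.3f, %s", tr, rep_tr$mean_r,
              if (rep_tr$verdict$significant) "significant" else
                "not significant")
  }
  cv_folds <- do.call(rbind, cv_rows)
  utils::write.table(cv_folds, file.path(out_dir, "cv_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cv_summary <- lapply(cv, function(x) {
    list(mean_r = x$mean_r, significant = x$verdict$significant,
         n_below_nominal = x$verdict$n_below_nominal,
         n_below_adjusted = x$verdict$n_below_adjusted)
  })
  jsonlite::write_json(cv_summary, file.path(out_dir, "cv_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tick("cv", ts)

  # --- stage: selection ----------------------------------------------
  ts <- Sys.time()
  sel_rows <- list()
  selection <- list()
  for (tr in traits) {
    for (mode in c("by_bv", "by_phenotype")) {
      sr <- response_to_selection(fits[[tr]]$bv, phenos, tr, fits[[tr]]$vc,
                                  k = min(selection_k,
                                          length(panel$sample_ids)),
                                  mode = mode)
      selection[[paste(tr, mode, sep = ".")]] <- sr
      sel_rows[[paste(tr, mode)]] <- data.frame(
        trait = tr, mode = mode, k = sr$k, bv_response = sr$bv_response,
        pheno_response = sr$pheno_response, p_top = sr$p_top,
        p_mean = sr$p_mean, h2 = sr$h2)
    }
  }
  sel_df <- do.call(rbind, sel_rows)
  rownames(sel_df) <- NULL
  utils::write.table(sel_df, file.path(out_dir, "selection_response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tick("selection", ts)

  # --- manifest -------------------------------------------------------
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seeds = list(simulation = if (simulate) sim_config$seed else NULL,
                 cv = cv_seed),
    config = list(simulate = simulate, qc = qc, grm_diagonal = grm_diagonal,
                  grm_missing_max = grm_missing_max, cv_k = cv_k,
                  nominal = nominal, adjusted = adjusted,
                  selection_k = selection_k),
    versions = list(gsblup = as.character(utils::packageVersion("gsblup")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    checksums = as.list(tools::md5sum(files)),
    timing_seconds = timing
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done in %.1f s; artifacts in %s",
            as.numeric(Sys.time() - t0, units = "secs"), out_dir)

  invisible(list(panel = panel, phenotypes = phenos,
                 qc_report = qc_res$report, grm = grm, fits = fits,
                 cv = cv, selection = selection, selection_table = sel_df,
                 manifest = manifest))
}
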