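# End-to-end orchestration: simulate paired corpora, compute DE, build
# signatures, run the retrieval benchmark, compute agreement statistics,
# fit the explanatory regression, and persist every intermediate as text.

default_run_config <- function() {
  list(
    stages = list(simulate = TRUE, de = TRUE, signatures = TRUE,
                  agree = TRUE, retrieve = TRUE, model = TRUE),
    corpus = list(n_genes = 1000L, n_landmark = 200L,
                  compounds = sprintf("cpd%02d", 1:20),
                  concentrations = c(0.08, 0.4, 2, 10),
                  cell_lines = c("MCF7", "PC3"), duration_h = 6,
                  n_replicate_profiles = 3L, n_samples_per_group = 4L,
                  sample_noise_sd = 0.5, platform_noise_sd = 0.25,
                  plate_effect_sd = 0.3, concordance_rho = 0.7,
                  frac_de_genes = 0.15, effect_scale = 2),
    thresholds = list(fc_cutoff = 1, mzs_cutoff = 2,
                      sig_min = 10L, sig_max = 150L),
    retrieval = list(aggregate = "max", signature_method = "hybrid"),
    seed = 1L,
    log_level = "info"
  )
}

check_known_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop(sprintf("unknown config key%s: %s",
                 if (nzchar(path)) sprintf(" under '%s'", path) else "",
                 paste(extra, collapse = ", ")), call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        k %in% c("stages", "thresholds", "retrieval")) {
      check_known_keys(cfg[[k]], template[[k]], k)
    }
  }
  invisible(cfg)
}

#' Build a validated pipeline run configuration
#'
#' Starts from the default demo configuration (1,000 genes, 20 compounds,
#' 2 cell lines, 4 doses) and overrides any supplied blocks. Unknown keys
#' are rejected before any stage runs.
#'
#' @param ... named overrides for the top-level blocks `stages`, `corpus`,
#'   `thresholds`, `retrieval`, `seed`, `log_level`. List blocks are merged
#'   key-wise.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  overrides <- list(...)
  check_known_keys(overrides, cfg)
  for (k in names(overrides)) {
    if (is.list(cfg[[k]]) && is.list(overrides[[k]]) && k != "corpus") {
      check_known_keys(overrides[[k]], cfg[[k]], k)
      cfg[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else if (k == "corpus") {
      extra <- setdiff(names(overrides$corpus), names(cfg$corpus))
      if (length(extra))
        stop(sprintf("unknown config key under 'corpus': %s",
                     paste(extra, collapse = ", ")), call. = FALSE)
      cfg$corpus[names(overrides$corpus)] <- overrides$corpus
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `run_config` list (validated against known keys).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

log_info <- function(cfg, stage, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full reproducibility-evaluation pipeline
#'
#' Executes the enabled stages in order — simulate paired corpora, compute
#' plate-matched fold-change profiles, build query signatures, compute
#' within- and cross-dataset agreement, run the cross-platform and
#' self-query retrieval benchmarks, and fit the three-predictor
#' agreement regression — persisting every intermediate under `outdir` as
#' GCT/GRP/TSV/JSON text. Re-running with an identical configuration
#' produces byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed); `NULL` skips all
#'   file output.
#' @return a `run_report` list: per-stage record counts, exclusion tables,
#'   summary statistics, config hash, seed and package version.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  persist <- !is.null(outdir)
  if (persist) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  config_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE)
  config_hash <- md5_of_string(as.character(config_json))
  if (persist) writeLines(as.character(config_json), file.path(outdir, "config.json"))

  report <- list(config_hash = config_hash, seed = config$seed,
                 version = as.character(utils::packageVersion("sigrepro")),
                 stages = list())

  ## simulate ---------------------------------------------------------------
  spec <- do.call(corpus_spec, c(config$corpus, list(seed = config$seed)))
  truth <- generate_ground_truth(spec)
  corpus_a <- simulate_corpus(truth, spec, "A")
  corpus_b <- simulate_corpus(truth, spec, "B")
  log_info(config, "simulate", "platform A/B corpora: %d genes x %d samples",
           nrow(corpus_a$values), ncol(corpus_a$values))
  report$stages$simulate <- list(n_genes = nrow(corpus_a$values),
                                 n_samples = ncol(corpus_a$values))
  if (persist && isTRUE(config$stages$simulate)) {
    write_gct(corpus_a$values, file.path(outdir, "expression_A.gct"))
    write_gct(corpus_b$values, file.path(outdir, "expression_B.gct"))
    write_tsv(corpus_a$sample_meta, file.path(outdir, "sample_meta_A.tsv"))
    write_tsv(corpus_b$sample_meta, file.path(outdir, "sample_meta_B.tsv"))
    write_tsv(corpus_a$gene_info, file.path(outdir, "gene_info.tsv"))
  }
  if (!isTRUE(config$stages$de)) return(finish_report(report, persist, outdir))

  ## differential expression ------------------------------------------------
  de_a <- compute_fc_profiles(corpus_a, seed = substream_seed(config$seed, "de_A"))
  de_b <- compute_fc_profiles(corpus_b, seed = substream_seed(config$seed, "de_B"))
  log_info(config, "de", "FC profiles: A %d, B %d (exclusions %d / %d)",
           ncol(de_a$values), ncol(de_b$values),
           nrow(de_a$exclusions), nrow(de_b$exclusions))
  report$stages$de <- list(n_profiles_a = ncol(de_a$values),
                           n_profiles_b = ncol(de_b$values),
                           n_excluded_a = nrow(de_a$exclusions),
                           n_excluded_b = nrow(de_b$exclusions))
  if (persist) {
    write_gct(de_a$values, file.path(outdir, "de_fc_A.gct"))
    write_gct(de_b$values, file.path(outdir, "de_fc_B.gct"))
    write_tsv(de_a$meta, file.path(outdir, "de_meta_A.tsv"))
    write_tsv(de_b$meta, file.path(outdir, "de_meta_B.tsv"))
    write_tsv(de_a$exclusions, file.path(outdir, "de_exclusions_A.tsv"))
    write_tsv(de_b$exclusions, file.path(outdir, "de_exclusions_B.tsv"))
  }

  rep_a <- select_representative_profiles(de_a, substream_seed(config$seed, "rep_A"))
  rep_b <- select_representative_profiles(de_b, substream_seed(config$seed, "rep_B"))

  ## agreement --------------------------------------------------------------
  if (isTRUE(config$stages$agree)) {
    within_b <- within_dataset_agreement(de_b, "spearman")
    within_b <- add_sample_agreement(within_b, corpus_b, "FC")
    within_a <- within_dataset_agreement(de_a, "spearman")
    harm <- harmonize(rep_a, rep_b, conc_tolerance = 0)
    cross <- cross_dataset_agreement(harm, "spearman", "all")
    cross_lm <- cross_dataset_agreement(harm, "spearman", "landmark",
                                        landmark_ids = landmark_genes(corpus_a))
    report$stages$agree <- list(
      n_conditions_within_a = nrow(within_a$summary),
      n_conditions_within_b = nrow(within_b$summary),
      n_harmonized = length(harm$pairs), n_unmatched = length(harm$unmatched),
      mean_within_max_a = mean(within_a$summary$max_value, na.rm = TRUE),
      mean_within_max_b = mean(within_b$summary$max_value, na.rm = TRUE),
      mean_cross_spearman = mean(cross$value, na.rm = TRUE),
      mean_cross_spearman_landmark = mean(cross_lm$value, na.rm = TRUE))
    log_info(config, "agree",
             "within A/B conditions %d/%d; cross-dataset pairs %d (mean r_s %.3f)",
             nrow(within_a$summary), nrow(within_b$summary),
             length(harm$pairs), report$stages$agree$mean_cross_spearman)
    if (persist) {
      write_tsv(within_a$pairs, file.path(outdir, "within_pairs_A.tsv"))
      write_tsv(within_b$pairs, file.path(outdir, "within_pairs_B.tsv"))
      write_tsv(within_a$summary, file.path(outdir, "within_summary_A.tsv"))
      write_tsv(within_b$summary, file.path(outdir, "within_summary_B.tsv"))
      write_tsv(cross, file.path(outdir, "cross_dataset_all.tsv"))
      write_tsv(cross_lm, file.path(outdir, "cross_dataset_landmark.tsv"))
      if (length(harm$unmatched))
        write_tsv(data.frame(condition = harm$unmatched,
                             reason = "no_matching_condition"),
                  file.path(outdir, "harmonization_unmatched.tsv"))
    }
  }

  ## signatures -------------------------------------------------------------
  sig_res <- NULL
  if (isTRUE(config$stages$signatures)) {
    sig_res <- build_signatures(rep_a, config$retrieval$signature_method,
                                landmark_ids = landmark_genes(corpus_a))
    report$stages$signatures <- list(
      n_eligible = length(sig_res$signatures),
      n_disqualified = sum(!is.na(sig_res$manifest$disqualified)))
    log_info(config, "signatures", "%d eligible, %d disqualified",
             report$stages$signatures$n_eligible,
             report$stages$signatures$n_disqualified)
    if (persist) {
      write_tsv(sig_res$manifest, file.path(outdir, "signature_manifest.tsv"))
      sigdir <- file.path(outdir, "signatures")
      dir.create(sigdir, showWarnings = FALSE)
      for (pid in names(sig_res$signatures))
        write_signature_grp(sig_res$signatures[[pid]], file.path(sigdir, pid))
    }
  }

  ## retrieval --------------------------------------------------------------
  if (isTRUE(config$stages$retrieve) && !is.null(sig_res) &&
      length(sig_res$signatures)) {
    universe <- sort(intersect(rep_a$meta$compound, rep_b$meta$compound))
    run_queries <- function(corpus_profiles) {
      lapply(names(sig_res$signatures), function(pid) {
        sig <- sig_res$signatures[[pid]]
        j <- match(pid, rep_a$meta$profile_id)
        query_corpus(sig, corpus_profiles,
                     target_compound = rep_a$meta$compound[j],
                     cell_line_filter = rep_a$meta$cell_line[j],
                     compound_universe = universe,
                     aggregate = config$retrieval$aggregate)
      })
    }
    cross_q <- run_queries(rep_b)
    self_q <- run_queries(rep_a)
    summarize_queries <- function(qs) {
      ranks <- vapply(qs, function(r) as.numeric(r$rank_of_target), numeric(1))
      succ <- vapply(qs, success_at_decile, logical(1))
      list(n_queries = length(qs), median_rank = median_rank(qs),
           decile_success_fraction = mean(succ, na.rm = TRUE),
           rank_1_fraction = mean(ranks == 1, na.rm = TRUE))
    }
    report$stages$retrieve <- list(cross = summarize_queries(cross_q),
                                   self = summarize_queries(self_q),
                                   universe_size = length(universe))
    log_info(config, "retrieve",
             "cross-platform decile success %.2f (median rank %.1f); self %.2f",
             report$stages$retrieve$cross$decile_success_fraction,
             report$stages$retrieve$cross$median_rank,
             report$stages$retrieve$self$decile_success_fraction)
    if (persist) {
      rows <- do.call(rbind, lapply(seq_along(cross_q), function(i) {
        data.frame(query_id = names(sig_res$signatures)[i],
                   target = cross_q[[i]]$target_compound,
                   rank_cross = cross_q[[i]]$rank_of_target,
                   inverse_rank_cross = cross_q[[i]]$inverse_rank_of_target,
                   rank_self = self_q[[i]]$rank_of_target,
                   universe_size = cross_q[[i]]$corpus_compound_count,
                   decile_success_cross = success_at_decile(cross_q[[i]]),
                   stringsAsFactors = FALSE)
      }))
      write_tsv(rows, file.path(outdir, "retrieval_results.tsv"))
    }
  }

  ## modeling ---------------------------------------------------------------
  if (isTRUE(config$stages$model) && isTRUE(config$stages$agree)) {
    reg_in <- build_regression_input(within_b)
    report$stages$model <- list(n_regression_rows = nrow(reg_in$data),
                                n_regression_excluded = reg_in$n_excluded)
    if (nrow(reg_in$data) >= 10) {
      fit <- try(standardized_linear_fit(reg_in), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        report$stages$model$standardized_coefficients <-
          as.list(fit$standardized_coefficients)
        report$stages$model$adjusted_r_squared <- fit$adjusted_r_squared
        report$stages$model$f_statistic <- fit$f_statistic
      }
    }
    dt <- dose_trend(within_b, de_b)
    report$stages$model$n_dose_trend_groups <- nrow(dt$records)
    report$stages$model$mean_dose_trend <- mean(dt$records$trend_statistic,
                                                na.rm = TRUE)
    log_info(config, "model", "regression rows %d; dose-trend groups %d",
             nrow(reg_in$data), nrow(dt$records))
    if (persist) {
      write_tsv(reg_in$data, file.path(outdir, "regression_input.tsv"))
      write_tsv(dt$records, file.path(outdir, "dose_trend_records.tsv"))
      write_tsv(dt$ineligible, file.path(outdir, "dose_trend_ineligible.tsv"))
      write_tsv(de_count_vs_dose(de_b), file.path(outdir, "de_count_vs_dose_B.tsv"))
    }
  }

  finish_report(report, persist, outdir)
}

finish_report <- function(report, persist, outdir) {
  class(report) <- "run_report"
  if (persist) {
    jsonlite::write_json(unclass(report), file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}

md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d, config %s): stages %s\n", x$seed,
              substr(x$config_hash, 1, 8),
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
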