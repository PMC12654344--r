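#' Default pipeline configuration
#'
#' Returns the full configuration list [run_pipeline()] starts from.
#' Thresholds default to the conventional instrument-selection settings
#' for this study design: microbiota-tier exposure p < 1e-5, metabolite
#' mediator p < 5e-6, genome-wide outcome p < 5e-8, clumping at
#' r2 < 0.001 within a 10,000 kb window, palindromic-SNP MAF limit 0.3,
#' weak-instrument cutoff F >= 10 and alpha 0.05.
#'
#' @return Named list of defaults; override any entry via the config
#'   passed to [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(
    exposure = NULL, outcome = NULL, mediator = NULL,
    ld = NULL, confounders = NULL, meta = NULL,
    taxa = NULL, metabolites = NULL,
    exposure_p = 1e-5, mediator_p = 5e-6, outcome_p = 5e-8,
    clump_r2 = 0.001, clump_window_kb = 10000,
    palindrome_maf = 0.3, f_min = 10, alpha = 0.05,
    confounder_p = 1e-5,
    ivw_variant = "multiplicative_random",
    n_boot = 1000, presso_sims = 1000,
    tau2_method = "REML",
    bidirectional = TRUE,
    correlation_method = "pearson", r_min = 0.7, n_perm = 999,
    seed = 1
  )
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    check_config(file.exists(config), paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  check_config(is.list(config), "`config` must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  check_config(length(unknown) == 0,
               paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  utils::modifyList(defaults, config)
}

#' Select, clump, screen and strength-filter instruments
#'
#' The instrument-preparation cascade applied to one exposure's summary
#' statistics: p-value selection, greedy LD clumping (when an LD matrix
#' is available), confounder screening (when an association table is
#' available) and the weak-instrument F filter. Filter input/output
#' counts are recorded in the `"counts"` attribute.
#'
#' @param stats Summary-statistics tibble.
#' @param p_threshold Selection threshold.
#' @param ld Optional squared-correlation matrix for [clump()].
#' @param confounders Optional confounder-association tibble for
#'   [screen_confounders()].
#' @param f_min Weak-instrument cutoff (default 10).
#' @param clump_r2,clump_window_kb Clumping parameters.
#' @param confounder_p Confounder-screen threshold (default 1e-5).
#' @return The surviving instruments with `r2`/`f_statistic` columns.
#' @export
prepare_instruments <- function(stats, p_threshold,
                                ld = NULL, confounders = NULL,
                                f_min = 10,
                                clump_r2 = 0.001, clump_window_kb = 10000,
                                confounder_p = 1e-5) {
  counts <- list(input = nrow(stats))
  out <- select_by_pvalue(stats, p_threshold)
  counts$after_pvalue <- nrow(out)
  if (!is.null(ld) && nrow(out) > 0) {
    out <- clump(out, ld, r2_threshold = clump_r2, window_kb = clump_window_kb)
    counts$after_clump <- nrow(out)
  }
  if (!is.null(confounders) && nrow(out) > 0) {
    out <- screen_confounders(out, confounders, threshold = confounder_p)
    counts$after_confounder_screen <- nrow(out)
  }
  if (nrow(out) > 0) {
    out <- filter_weak_instruments(out, f_min = f_min)
  }
  counts$after_f_filter <- nrow(out)
  attr(out, "counts") <- counts
  out
}

#' Run the full study-shaped workflow from one configuration
#'
#' Orchestrates the in-scope analysis stages from a single declarative
#' configuration (a list or YAML file; see [pipeline_defaults()] for
#' every key): instrument preparation and harmonization for the
#' exposure-outcome link (optionally bidirectional), the MR estimator
#' battery, two-step mediation when a mediator file is supplied,
#' random-effects meta-analysis when a study table is supplied, and the
#' correlation/Mantel integration layer when paired omics tables are
#' supplied. All tabular outputs are TSV, diagnostics are JSON, and a
#' machine-readable run log records every filter's input/output counts.
#' Reruns with an identical config are deterministic.
#'
#' @param config List or YAML path; only keys that deviate from
#'   [pipeline_defaults()] need to be given.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a manifest: named list of written file paths plus
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  log <- list(config = cfg[!purrr::map_lgl(cfg, is.null)])
  stage <- "setup"

  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    write_tsv_quiet(tbl, path)
    manifest[[name]] <<- path
    path
  }

  tryCatch({
    if (!is.null(cfg$exposure) && !is.null(cfg$outcome)) {
      stage <- "read"
      exposure <- read_summary_stats(cfg$exposure)
      outcome <- read_summary_stats(cfg$outcome)
      ld <- if (!is.null(cfg$ld)) read_ld_matrix(cfg$ld) else NULL
      conf <- if (!is.null(cfg$confounders)) {
        read_confounder_table(cfg$confounders)
      } else {
        NULL
      }

      stage <- "instruments"
      instr <- prepare_instruments(
        exposure, cfg$exposure_p, ld = ld, confounders = conf,
        f_min = cfg$f_min, clump_r2 = cfg$clump_r2,
        clump_window_kb = cfg$clump_window_kb,
        confounder_p = cfg$confounder_p
      )
      log$forward_instrument_counts <- attr(instr, "counts")
      if (nrow(instr) == 0) {
        rlang::abort("0 instruments survive the forward selection cascade",
                     class = "mrpath_validation_error")
      }
      emit(instr, "instruments_forward.tsv")

      stage <- "harmonize"
      fwd_pairs <- harmonize(instr, outcome,
                             palindrome_maf_limit = cfg$palindrome_maf)

      stage <- "mr_battery"
      battery_args <- list(
        alpha = cfg$alpha, ivw_variant = cfg$ivw_variant,
        n_boot = cfg$n_boot, presso_sims = cfg$presso_sims,
        seed = cfg$seed
      )
      fwd <- do.call(run_battery, c(
        list(fwd_pairs, exposure_name = "exposure", outcome_name = "outcome"),
        battery_args
      ))
      results$forward <- fwd
      emit(tidy(fwd), "battery_forward.tsv")
      write_battery_json(fwd, file.path(out_dir, "battery_forward.json"))
      manifest[["battery_forward.json"]] <-
        file.path(out_dir, "battery_forward.json")

      if (isTRUE(cfg$bidirectional)) {
        stage <- "bidirectional"
        rev_instr <- prepare_instruments(
          outcome, cfg$outcome_p, ld = ld, confounders = conf,
          f_min = cfg$f_min, clump_r2 = cfg$clump_r2,
          clump_window_kb = cfg$clump_window_kb,
          confounder_p = cfg$confounder_p
        )
        log$reverse_instrument_counts <- attr(rev_instr, "counts")
        rev_pairs <- if (nrow(rev_instr) > 0) {
          harmonize(rev_instr, exposure,
                    palindrome_maf_limit = cfg$palindrome_maf)
        } else {
          NULL
        }
        bid <- bidirectional(
          fwd_pairs, rev_pairs,
          alpha = cfg$alpha, ivw_variant = cfg$ivw_variant,
          n_boot = cfg$n_boot, presso_sims = cfg$presso_sims,
          seed = cfg$seed
        )
        results$bidirectional <- bid
        log$bidirectional_interpretation <- bid$interpretation
      }

      if (!is.null(cfg$mediator)) {
        stage <- "mediation"
        mediator <- read_summary_stats(cfg$mediator)
        m_instr <- prepare_instruments(
          mediator, cfg$mediator_p, ld = ld, confounders = conf,
          f_min = cfg$f_min, clump_r2 = cfg$clump_r2,
          clump_window_kb = cfg$clump_window_kb,
          confounder_p = cfg$confounder_p
        )
        log$mediator_instrument_counts <- attr(m_instr, "counts")
        if (nrow(m_instr) == 0) {
          rlang::abort("0 mediator instruments survive selection",
                       class = "mrpath_validation_error")
        }
        step1_pairs <- harmonize(instr, mediator,
                                 palindrome_maf_limit = cfg$palindrome_maf)
        step2_pairs <- harmonize(m_instr, outcome,
                                 palindrome_maf_limit = cfg$palindrome_maf)
        step1 <- do.call(run_battery, c(
          list(step1_pairs, exposure_name = "exposure",
               outcome_name = "mediator"), battery_args
        ))
        step2 <- do.call(run_battery, c(
          list(step2_pairs, exposure_name = "mediator",
               outcome_name = "outcome"), battery_args
        ))
        med <- two_step(step1, step2, fwd)
        results$mediation <- med
        emit(med, "mediation.tsv")
      }
    }

    if (!is.null(cfg$meta)) {
      stage <- "meta_analysis"
      studies <- read_meta_studies(cfg$meta)
      meta <- pool_random_effects(studies, tau2_method = cfg$tau2_method)
      results$meta <- meta
      emit(tidy(meta), "meta_forest.tsv")
      log$meta <- as.list(glance(meta))
    }

    if (!is.null(cfg$taxa) && !is.null(cfg$metabolites)) {
      stage <- "integration"
      taxa <- readr::read_tsv(cfg$taxa, col_types = readr::cols(),
                              progress = FALSE)
      metab <- readr::read_tsv(cfg$metabolites, col_types = readr::cols(),
                               progress = FALSE)
      corr <- correlate_features(
        taxa, metab, method = cfg$correlation_method,
        r_min = cfg$r_min, alpha = cfg$alpha
      )
      results$correlations <- corr
      emit(corr, "integration_correlations.tsv")
      mt <- mantel_test(
        dist_euclidean(taxa), dist_euclidean(metab),
        n_perm = cfg$n_perm, seed = cfg$seed,
        method = cfg$correlation_method
      )
      results$mantel <- mt
      log$mantel <- list(r = mt$r, pvalue = mt$pvalue, n_perm = mt$n_perm)
    }
  }, error = function(e) {
    rlang::abort(
      sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
      class = "mrpath_pipeline_error",
      manifest = manifest
    )
  })

  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest[["run_log.json"]] <- log_path

  invisible(c(manifest, list(results = results)))
}

write_battery_json <- function(battery, path) {
  payload <- list(
    summary = as.list(glance(battery)),
    estimates = battery$estimates,
    q = battery$q,
    presso = if (is.null(battery$presso)) NULL else list(
      global_pvalue = battery$presso$global_pvalue,
      rss_obs = battery$presso$rss_obs,
      outliers = battery$presso$outliers
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
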