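#' Pipeline configuration
#'
#' One master seed fans out into named per-module streams (simulation,
#' mother-daughter sampling, bootstrap, surrogates) so changing one analysis
#' leaves the others untouched. Either a simulation block or an input table
#' path must be present.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master seed.
#' @param sim [sim_params()] block, or `NULL` when reading an input table.
#' @param input_table path to a tracking-table CSV (used when `sim` is NULL).
#' @param records_csv optional precomputed per-cell database; when given, the
#'   extraction stage is skipped and downstream stages run from this file.
#' @param metadata [dataset_metadata()].
#' @param column_map column map for `input_table`.
#' @param n_boot bootstrap replicates for correlations.
#' @param gp_m,gp_surrogates Grassberger-Procaccia embedding dimension and
#'   surrogate count.
#' @param km_min_n per-generation stratum floor.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_params(seed = seed),
                            input_table = NULL, records_csv = NULL,
                            metadata = dataset_metadata(),
                            column_map = default_column_map(),
                            n_boot = 2000L, gp_m = 3L, gp_surrogates = 100L,
                            km_min_n = 10L) {
  if (is.null(sim) && is.null(input_table) && is.null(records_csv)) {
    stop("config needs a simulation block, an input table or a records file",
         call. = FALSE)
  }
  stopifnot(n_boot >= 1L, gp_surrogates >= 1L, gp_m %in% 1:3)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input_table = input_table, records_csv = records_csv,
                 metadata = metadata, column_map = column_map,
                 n_boot = as.integer(n_boot), gp_m = as.integer(gp_m),
                 gp_surrogates = as.integer(gp_surrogates),
                 km_min_n = as.integer(km_min_n)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> extract -> lineage -> survival -> correlation ->
#' determinism -> motility, writing a machine-readable bundle to
#' `config$out_dir`: `records.csv`, `km.csv`, `corr.json`, `gp.json`,
#' `motility.csv`, `colony.csv` and `manifest.json` (seeds, per-stage cell
#' counts, config hash, file hashes). Deterministic given the config seed.
#' Any stage failure aborts with the stage name.
#'
#' @param config [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisible list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  # --- acquire table ------------------------------------------------------
  tab <- stage("input", {
    if (!is.null(config$sim)) {
      say("simulating ", config$sim$n_colonies, " colonies per condition")
      simulate_experiment(config$sim)
    } else if (!is.null(config$input_table)) {
      read_tracking_table(config$input_table, config$metadata,
                          config$column_map)
    } else {
      NULL
    }
  })
  # --- extraction ---------------------------------------------------------
  records <- stage("extract", {
    if (!is.null(config$records_csv)) {
      read_database(config$records_csv)
    } else {
      extract_records(tab, config$metadata)
    }
  })
  paths$records <- file.path(config$out_dir, "records.csv")
  write_database(records, paths$records)
  forest <- stage("lineage", build_forest(records))
  conditions <- intersect(CONDITIONS, unique(records$condition))

  # --- survival -----------------------------------------------------------
  km_tidy <- stage("survival", {
    out <- list()
    for (cond in conditions) {
      for (v in c("CC_L", "G1_L", "SG2M_L")) {
        mt <- suppressWarnings(
          km_median_by_generation(records, v, cond, config$km_min_n))
        for (g in as.character(mt$generation)) {
          cv <- attr(mt, "curves")[[g]]$curve
          out[[length(out) + 1L]] <- data.frame(
            condition = cond, variable = v, generation = as.integer(g),
            time = cv$time, survival = cv$survival, n_risk = cv$n_risk,
            n_event = cv$n_event, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  paths$km <- file.path(config$out_dir, "km.csv")
  write.csv(km_tidy %||% data.frame(), paths$km, row.names = FALSE)

  # --- correlation --------------------------------------------------------
  corr <- stage("correlation", {
    res <- list()
    for (cond in conditions) {
      rc <- records[records$condition == cond, ]
      fo <- build_forest(rc)
      for (rel in c("SISTER", "MOTHER_DAUGHTER", "COUSIN")) {
        prs <- enumerate_pairs(fo, rc, rel,
                               seed = derive_seed(config$seed, "md-choice"))
        for (v in c("CC_L", "G1_L", "SG2M_L")) {
          pv <- pair_values(prs, rc, v)
          if (nrow(pv) < 10L || length(unique(pv$colony_id)) < 2L) next
          bc <- suppressWarnings(bootstrap_corr(
            pv, config$n_boot, seed = derive_seed(config$seed, "boot")))
          res[[paste(cond, rel, v, sep = ".")]] <- list(
            condition = cond, relation = rel, variable = v,
            rho = bc$rho_hat, ci_low = bc$ci_low, ci_high = bc$ci_high,
            p = bc$p_value, n_pairs = bc$n_pairs, n_boot = bc$n_boot)
        }
      }
    }
    res
  })
  paths$corr <- file.path(config$out_dir, "corr.json")
  jsonlite::write_json(corr, paths$corr, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # --- determinism --------------------------------------------------------
  gp <- stage("determinism", {
    res <- list()
    for (cond in conditions) {
      rc <- records[records$condition == cond, ]
      fo <- build_forest(rc)
      for (v in c("G1_L", "SG2M_L")) {
        out <- tryCatch(
          surrogate_test(rc, fo, v, m = config$gp_m,
                         n_surrogates = config$gp_surrogates,
                         seed = derive_seed(config$seed, "gp")),
          error = function(e) NULL)
        if (is.null(out)) next
        res[[paste(cond, v, sep = ".")]] <- list(
          condition = cond, variable = v, m = out$m, nu = out$nu_data,
          surrogate_q = out$threshold, verdict = out$verdict,
          n_points = out$n_points)
      }
    }
    res
  })
  paths$gp <- file.path(config$out_dir, "gp.json")
  jsonlite::write_json(gp, paths$gp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  # --- motility -----------------------------------------------------------
  have_frames <- !is.null(tab) && nrow(tab) > 0
  mot <- stage("motility", {
    if (have_frames) motility_summary(records, tab) else NULL
  })
  colony <- stage("colony", if (have_frames) colony_metrics(tab) else NULL)
  paths$motility <- file.path(config$out_dir, "motility.csv")
  paths$colony <- file.path(config$out_dir, "colony.csv")
  write.csv(mot %||% data.frame(), paths$motility, row.names = FALSE)
  write.csv(colony %||% data.frame(), paths$colony, row.names = FALSE)

  # --- manifest -----------------------------------------------------------
  counts <- lapply(conditions, function(cond) {
    r <- records[records$condition == cond, ]
    list(condition = cond, tracked = nrow(r), complete = sum(r$complete),
         censored = sum(r$fate %in% c("CENSORED_END", "TRACK_LOST")),
         apoptotic = sum(r$fate == "APOPTOSIS"))
  })
  cfg_repr <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                    collapse = "")
  manifest <- list(
    package = "fuccitrack",
    version = as.character(utils::packageVersion("fuccitrack")),
    seed = config$seed,
    config_hash = fxt_hash_text(cfg_repr),
    counts = counts,
    artifacts = lapply(paths, fxt_hash_file))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(records = records, forest = forest, km = km_tidy,
                 corr = corr, gp = gp, motility = mot, colony = colony,
                 manifest = manifest, paths = paths))
}
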