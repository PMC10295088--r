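#' Build a reproducible end-to-end run configuration
#'
#' Defaults mirror the published case-study setup: 1000 constraint
#' patterns, 20 samples per pattern, thinning 10,000, 10 chains, a +/-10
#' percent query window, correlation threshold 0.95, 800 orderings for the
#' minimum-flux estimate, and top-5 validation reporting. Desk-scale runs
#' override the sizes explicitly.
#'
#' @param model a `metabolic_model`, or a path to a model file.
#' @param substrate,growth,product anchor reaction ids.
#' @param substrate_interval signed uptake range for the substrate draw.
#' @param n_patterns,per_pattern constraint-seed count and kept samples per
#'   seed.
#' @param sampler a [sampler_config()].
#' @param n_default rows for the unconstrained comparison run (0 disables).
#' @param rel_window relative query window.
#' @param correlation_threshold absolute correlation cutoff for grouping.
#' @param n_orders orderings for the minimum-flux estimate.
#' @param k top-k size for validation.
#' @param seed master seed (mandatory: every stochastic stage derives its
#'   stream from it).
#' @param mfa_reference optional `mfa_reference` (or CSV path +
#'   `mfa_anchor`) enabling the validation stage.
#' @param mfa_anchor anchor reaction id when `mfa_reference` is a path.
#' @param output_dir directory for stage artifacts; `NULL` disables
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(model, substrate, growth, product, substrate_interval,
                       n_patterns = 1000L, per_pattern = 20L,
                       sampler = sampler_config(), n_default = 20000L,
                       rel_window = 0.10, correlation_threshold = 0.95,
                       n_orders = 800L, k = 5L, seed = 1L,
                       mfa_reference = NULL, mfa_anchor = NULL,
                       output_dir = NULL) {
  if (is.character(model)) model <- load_model(model)
  validate_model(model)
  for (r in c(substrate, growth, product)) {
    if (!r %in% model$reaction_ids) {
      rlang::abort(sprintf("configured reaction '%s' not in model", r))
    }
  }
  if (is.character(mfa_reference)) {
    if (is.null(mfa_anchor)) rlang::abort("mfa_anchor is required with a reference path")
    mfa_reference <- read_mfa_reference(mfa_reference, mfa_anchor)
  }
  sampler$seed <- as.integer(seed)
  structure(
    list(model = model, substrate = substrate, growth = growth, product = product,
         substrate_interval = substrate_interval,
         n_patterns = as.integer(n_patterns), per_pattern = as.integer(per_pattern),
         sampler = sampler, n_default = as.integer(n_default),
         rel_window = rel_window, correlation_threshold = correlation_threshold,
         n_orders = as.integer(n_orders), k = as.integer(k),
         seed = as.integer(seed), mfa_reference = mfa_reference,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the [run_config()] arguments; `model` is a file path,
#' `toy` selects a built-in toy topology instead, and `sampler` is a nested
#' block (`n_samples`, `thinning`, `n_chains`, `n_warmup`).
#'
#' @param path YAML file.
#' @param overrides named list applied over the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  model <- if (!is.null(y$toy)) {
    make_toy_model(y$toy, n_reactions = y$toy_n_reactions %||% NULL,
                   seed = y$toy_seed %||% 1L)
  } else {
    load_model(y$model)
  }
  sp <- y$sampler %||% list()
  sampler <- sampler_config(
    n_samples = sp$n_samples %||% 20000L, thinning = sp$thinning %||% 10000L,
    n_chains = sp$n_chains %||% 10L, seed = y$seed %||% 1L,
    n_warmup = sp$n_warmup
  )
  run_config(
    model = model, substrate = y$substrate, growth = y$growth, product = y$product,
    substrate_interval = as.numeric(y$substrate_interval),
    n_patterns = y$n_patterns %||% 1000L, per_pattern = y$per_pattern %||% 20L,
    sampler = sampler, n_default = y$n_default %||% 20000L,
    rel_window = y$rel_window %||% 0.10,
    correlation_threshold = y$correlation_threshold %||% 0.95,
    n_orders = y$n_orders %||% 800L, k = y$k %||% 5L, seed = y$seed %||% 1L,
    mfa_reference = y$mfa_reference, mfa_anchor = y$mfa_anchor,
    output_dir = y$output_dir
  )
}

#' Run the full prediction pipeline
#'
#' Executes the stages end to end: constraint-seed generation, sequential
#' constrained sampling, optional default-mode sampling, substrate
#' normalization, MDS diversity comparison, importance ranking, correlation
#' grouping, the minimum-flux estimate, and (when a reference is
#' configured) 13C-MFA validation. All tabular artifacts are written as CSV
#' under `output_dir`, namespaced by a hash of the configuration; rerunning
#' with the same configuration reproduces identical numbers.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `run_manifest`: `config_hash`, `versions`,
#'   `timings` (tibble stage/seconds), `warnings`, `outputs` (files
#'   written), and `results` (the in-memory stage objects).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  model <- config$model
  hash <- substr(rlang::hash(config[setdiff(names(config), "output_dir")]), 1, 12)
  out_dir <- config$output_dir
  outputs <- character(0)
  warnings <- character(0)
  timings <- list()
  results <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- withCallingHandlers(
      expr,
      warning = function(w) {
        warnings <<- c(warnings, sprintf("%s: %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    val
  }
  emit <- function(df, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- file.path(out_dir, sprintf("%s_%s", hash, file))
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
  }

  say("[seeds] generating %d constraint patterns", config$n_patterns)
  patterns <- stage("seeds", generate_constraint_patterns(
    model, config$substrate, config$growth, config$product,
    n_patterns = config$n_patterns, substrate_interval = config$substrate_interval,
    seed = config$seed
  ))
  results$patterns <- patterns
  emit(tibble::as_tibble(patterns), "patterns.csv")
  say("[seeds] %d feasible / %d", sum(patterns$feasible), nrow(patterns))

  say("[sample] sequential constrained sampling, %d per pattern", config$per_pattern)
  seq_samples <- stage("sequential_sampling", sequential_sampling(
    model, patterns, per_pattern = config$per_pattern, config = config$sampler
  ))
  results$sequential <- seq_samples
  emit(as.data.frame(seq_samples$matrix), "sequential_samples.csv")
  say("[sample] %d rows kept", nrow(seq_samples$matrix))

  default_samples <- NULL
  if (config$n_default > 0) {
    say("[sample] default-mode sampling, %d rows", config$n_default)
    def_cfg <- sampler_config(
      n_samples = config$n_default, thinning = config$sampler$thinning,
      n_chains = config$sampler$n_chains,
      seed = (config$seed + 424243L) %% 2147483629L,
      n_warmup = config$sampler$n_warmup
    )
    default_samples <- stage("default_sampling", sample_fluxes(model, def_cfg))
    results$default <- default_samples
    emit(as.data.frame(default_samples$matrix), "default_samples.csv")
  }

  say("[mds] substrate normalization and embedding")
  norm_seq <- stage("normalize", normalize_to_substrate(seq_samples, config$substrate))
  sets <- list(constrained = norm_seq)
  if (!is.null(default_samples)) {
    sets$default <- normalize_to_substrate(default_samples, config$substrate)
  }
  embedding <- stage("mds", mds_embed(sets, seed = config$seed))
  results$embedding <- embedding
  emit(tibble::as_tibble(embedding), "embedding.csv")
  spreads <- vapply(names(sets), function(l) spread_metric(embedding, l), numeric(1))
  results$spread <- spreads
  say("[mds] spread: %s", paste(sprintf("%s=%.3f", names(spreads), spreads),
                                collapse = ", "))

  say("[group] correlation grouping at |r| >= %.2f", config$correlation_threshold)
  groups <- stage("grouping", group_by_correlation(
    seq_samples, threshold = config$correlation_threshold))
  results$groups <- groups
  emit(tidy(groups), "groups.csv")
  say("[group] %d groups", nrow(groups))

  say("[rank] importance ranking over %d exchange fluxes", length(seq_samples$exchange))
  ranking <- stage("ranking", rank_flux_importance(
    seq_samples, rel_window = config$rel_window, groups = groups))
  results$ranking <- ranking
  emit(tidy(ranking), "importance_ranking.csv")

  say("[minflux] %d orderings", config$n_orders)
  minflux <- stage("min_flux", min_fluxes_to_identify(
    seq_samples, groups, n_orders = config$n_orders,
    rel_window = config$rel_window, seed = config$seed))
  results$minflux <- minflux
  emit(glance(minflux), "min_flux_estimate.csv")
  say("[minflux] mean %.3f, median %.1f", minflux$mean, minflux$median)

  if (!is.null(config$mfa_reference)) {
    say("[validate] anchor selection and MAPE scoring")
    ref <- config$mfa_reference
    norm_all <- normalize_to_substrate(seq_samples, config$substrate)
    selected <- stage("anchor_selection", select_by_anchor(
      norm_all, ref$anchor_reaction, ref$anchor_value, config$rel_window))
    validation <- if (nrow(selected$matrix) > 0) {
      stage("validation", top_k_by_mape(selected, ref, k = config$k))
    } else NULL
    results$validation <- validation
    if (!is.null(validation)) {
      emit(validation$scores, "validation_scores.csv")
      emit(validation$comparison, "validation_comparison.csv")
    }
  }

  manifest <- structure(
    list(
      config_hash = hash,
      versions = list(fluxpin = tryCatch(as.character(utils::packageVersion("fluxpin")),
                                         error = function(e) "dev"),
                      R = paste(R.version$major, R.version$minor, sep = ".")),
      timings = tibble::tibble(stage = names(timings),
                               seconds = unlist(timings, use.names = FALSE)),
      warnings = warnings,
      outputs = outputs,
      results = results
    ),
    class = "run_manifest"
  )
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, sprintf("%s_manifest.json", hash))
    jsonlite::write_json(
      manifest[c("config_hash", "versions", "warnings", "outputs")],
      mpath, auto_unbox = TRUE, pretty = TRUE)
    manifest$outputs <- c(manifest$outputs, mpath)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest %s>\n", x$config_hash))
  print(x$timings)
  if (length(x$warnings)) cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  if (length(x$outputs)) cat(sprintf("  %d file(s) written\n", length(x$outputs)))
  invisible(x)
}
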