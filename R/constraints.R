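#' Generate (substrate, growth, product) constraint seed patterns
#'
#' Builds the constraint seeds that force sample diversity in the three
#' phenotypically important fluxes. For each pattern: (1) the substrate
#' uptake value is drawn uniformly over `substrate_interval` (signed, COBRA
#' convention: uptake is negative); (2) with the substrate clamped, the
#' feasible growth range is found by FBA min/max and a growth value is drawn
#' uniformly inside it; (3) with both clamped, the feasible product range is
#' found the same way and a product value drawn. Draws that land on an
#' infeasible clamp are retried up to `max_retries`, then flagged
#' infeasible. The default of 1000 patterns matches the published case
#' study.
#'
#' @param model a `metabolic_model`.
#' @param substrate,growth,product reaction ids of the three anchor fluxes.
#' @param n_patterns number of seed patterns (default 1000).
#' @param substrate_interval length-2 numeric, the signed uptake range to
#'   draw from (e.g. `c(-10, -2)`); must lie within the model bounds.
#' @param seed integer seed.
#' @param max_retries retries per pattern before flagging it infeasible.
#' @return A tibble of class `constraint_patterns` with columns
#'   `pattern_id`, `substrate_flux`, `growth_flux`, `product_flux`,
#'   `feasible`.
#' @export
generate_constraint_patterns <- function(model, substrate, growth, product,
                                         n_patterns = 1000L,
                                         substrate_interval,
                                         seed = 1L, max_retries = 10L) {
  validate_model(model)
  ids <- c(substrate, growth, product)
  if (!all(ids %in% model$reaction_ids)) {
    rlang::abort(sprintf("anchor reaction(s) not in model: %s",
                         paste(setdiff(ids, model$reaction_ids), collapse = ", ")))
  }
  if (n_patterns < 1) rlang::abort("n_patterns must be at least 1")
  lo <- min(substrate_interval); hi <- max(substrate_interval)
  if (lo < model$lower[substrate] - 1e-9 || hi > model$upper[substrate] + 1e-9) {
    rlang::abort("substrate_interval outside the model bounds for the substrate")
  }
  # the interval must contain at least one feasible substrate value
  probe <- fba(model, substrate, "max",
               fixed = NULL)
  if (probe$status != "optimal") rlang::abort("model is infeasible")
  set.seed(seed)
  draw_in <- function(rng) {
    if (rng[2] - rng[1] < 1e-9) mean(rng) else stats::runif(1, rng[1], rng[2])
  }
  out <- purrr::map_dfr(seq_len(n_patterns), function(i) {
    for (try in seq_len(max_retries)) {
      sv <- stats::runif(1, lo, hi)
      gr <- flux_range(model, growth, fixed = stats::setNames(sv, substrate))
      if (gr$status != "optimal") next
      gv <- draw_in(c(gr$min_flux, gr$max_flux))
      pr <- flux_range(model, product,
                       fixed = stats::setNames(c(sv, gv), c(substrate, growth)))
      if (pr$status != "optimal") next
      pv <- draw_in(c(pr$min_flux, pr$max_flux))
      return(tibble::tibble(pattern_id = i, substrate_flux = sv,
                            growth_flux = gv, product_flux = pv, feasible = TRUE))
    }
    tibble::tibble(pattern_id = i, substrate_flux = NA_real_,
                   growth_flux = NA_real_, product_flux = NA_real_,
                   feasible = FALSE)
  })
  if (!any(out$feasible)) {
    rlang::abort("no feasible constraint pattern found in substrate_interval")
  }
  structure(out, class = c("constraint_patterns", class(out)),
            substrate = substrate, growth = growth, product = product)
}

#' Sequential constrained flux sampling
#'
#' For each feasible constraint pattern, clamps the three anchor fluxes at
#' the pattern values (narrow symmetric intervals, see [fba()]) and runs the
#' hit-and-run sampler for `per_pattern` kept samples inside the clamped
#' polytope. Rows are tagged with their pattern id and concatenated. The
#' published setup uses 1000 patterns x 20 samples each = 20,000 rows.
#'
#' @param model a `metabolic_model`.
#' @param patterns output of [generate_constraint_patterns()].
#' @param per_pattern kept samples per pattern (default 20).
#' @param config a [sampler_config()]; its `n_samples` is ignored in favour
#'   of `per_pattern`, and each pattern gets a sub-seed derived from
#'   `config$seed`.
#' @return A `flux_sample_set` with per-row `pattern_id` provenance, plus an
#'   attribute `skipped` listing patterns that were infeasible at clamp
#'   time.
#' @export
sequential_sampling <- function(model, patterns, per_pattern = 20L,
                                config = sampler_config()) {
  stopifnot(inherits(patterns, "constraint_patterns"))
  if (per_pattern < 1) rlang::abort("per_pattern must be at least 1")
  if (nrow(patterns) == 0) rlang::abort("patterns is empty")
  substrate <- attr(patterns, "substrate")
  growth <- attr(patterns, "growth")
  product <- attr(patterns, "product")
  feas <- patterns[patterns$feasible, , drop = FALSE]
  sets <- vector("list", nrow(feas))
  skipped <- integer()
  for (i in seq_len(nrow(feas))) {
    p <- feas[i, ]
    fx <- stats::setNames(c(p$substrate_flux, p$growth_flux, p$product_flux),
                          c(substrate, growth, product))
    bnd <- clamp_bounds(model, fx)
    sub_cfg <- sampler_config(
      n_samples = per_pattern,
      thinning = config$thinning,
      n_chains = min(config$n_chains, per_pattern),
      seed = (config$seed + 131071L * p$pattern_id) %% 2147483629L,
      n_warmup = config$n_warmup
    )
    res <- tryCatch(
      sample_fluxes(model, sub_cfg, pattern_id = as.character(p$pattern_id),
                    bounds = bnd),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- c(skipped, p$pattern_id)
      rlang::warn(sprintf("pattern %d infeasible at clamp time; skipped", p$pattern_id))
      next
    }
    sets[[i]] <- res
  }
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) == 0) rlang::abort("every pattern was infeasible at clamp time")
  mat <- do.call(rbind, lapply(sets, `[[`, "matrix"))
  prov <- dplyr::bind_rows(lapply(sets, `[[`, "provenance"))
  prov$row <- seq_len(nrow(mat))
  out <- new_sample_set(mat, model, prov, config$thinning)
  attr(out, "skipped") <- skipped
  out
}

#' Combine sample sets over a shared reaction index
#'
#' @param ... `flux_sample_set` objects with identical reaction indices.
#' @return A single `flux_sample_set` with concatenated rows and provenance.
#' @export
bind_sample_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1), "flux_sample_set")))
  ids <- sets[[1]]$reaction_ids
  if (!all(vapply(sets, function(s) identical(s$reaction_ids, ids), logical(1)))) {
    rlang::abort("sample sets have different reaction indices")
  }
  mat <- do.call(rbind, lapply(sets, `[[`, "matrix"))
  prov <- dplyr::bind_rows(lapply(sets, `[[`, "provenance"))
  prov$row <- seq_len(nrow(mat))
  structure(
    list(reaction_ids = ids, matrix = mat, provenance = prov,
         thinning = sets[[1]]$thinning, model_id = sets[[1]]$model_id),
    class = "flux_sample_set"
  )
}
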