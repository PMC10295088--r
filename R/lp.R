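#' Flux balance analysis
#'
#' Maximises or minimises the flux through one reaction over the steady-state
#' polytope `S v = 0`, `lb <= v <= ub`, optionally with a set of reactions
#' clamped at given values. Clamping uses a narrow symmetric interval
#' `value * (1 +/- 1e-6)` (absolute `1e-9` when the value is 0) rather than
#' exact equality, so floating-point noise cannot make a feasible clamp
#' spuriously infeasible.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @param fixed named numeric vector of reaction values to clamp.
#' @return A list of class `lp_result` with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, and `solution`
#'   (a named flux vector, present only when optimal).
#' @examples
#' m <- make_toy_model("diamond")
#' fba(m, "EX_out", "max")$objective_value  # 7: branch capacities 3 + 4
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min"),
                fixed = NULL) {
  sense <- match.arg(sense)
  validate_model(model)
  if (!objective %in% model$reaction_ids) {
    rlang::abort(sprintf("objective reaction '%s' not in model", objective))
  }
  bnd <- clamp_bounds(model, fixed)
  obj <- as.numeric(model$reaction_ids == objective)
  res <- lp_solve_bounded(model$S, rep(0, nrow(model$S)),
                          bnd$lower, bnd$upper, obj, sense)
  if (res$status == "error") {
    rlang::abort("LP engine failed to converge")
  }
  out <- list(
    status = res$status,
    objective_value = if (res$status == "optimal") res$objective else NA_real_,
    solution = if (res$status == "optimal") {
      stats::setNames(res$x, model$reaction_ids)
    } else NULL
  )
  class(out) <- "lp_result"
  out
}

# intersect the model bounds with the fixed-value clamp intervals
clamp_bounds <- function(model, fixed, rel = 1e-6, abs0 = 1e-9) {
  lower <- model$lower
  upper <- model$upper
  if (length(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% model$reaction_ids)) {
      rlang::abort("all fixed reactions must be named and present in the model")
    }
    for (r in names(fixed)) {
      v <- fixed[[r]]
      eps <- max(rel * abs(v), abs0)
      lower[r] <- max(lower[r], v - eps)
      upper[r] <- min(upper[r], v + eps)
    }
  }
  list(lower = lower, upper = upper)
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("<lp_result> status: %s, objective: %s\n",
              x$status, format(x$objective_value)))
  invisible(x)
}

#' Feasible flux range of one reaction
#'
#' Two FBA calls (minimise and maximise the target) under optional clamps;
#' the flux-variability-analysis primitive.
#'
#' @inheritParams fba
#' @param target reaction id whose range is sought.
#' @return A tibble with one row: `reaction`, `min_flux`, `max_flux`,
#'   `status` (`"optimal"` or `"infeasible"`).
#' @export
flux_range <- function(model, target, fixed = NULL) {
  lo <- fba(model, target, "min", fixed)
  hi <- fba(model, target, "max", fixed)
  st <- if (lo$status == "optimal" && hi$status == "optimal") "optimal" else lo$status
  tibble::tibble(
    reaction = target,
    min_flux = lo$objective_value,
    max_flux = hi$objective_value,
    status = st
  )
}

#' Flux variability analysis over many reactions
#'
#' @inheritParams fba
#' @param reactions reaction ids; defaults to all reactions.
#' @return A tibble with one row per reaction (`reaction`, `min_flux`,
#'   `max_flux`, `status`).
#' @export
fva <- function(model, reactions = model$reaction_ids, fixed = NULL) {
  purrr::map_dfr(reactions, function(r) flux_range(model, r, fixed))
}

#' Production envelope of one flux against another
#'
#' Sweeps `x_reaction` over its feasible range on a regular grid and records
#' the attainable minimum and maximum of `y_reaction` with `x` clamped at
#' each grid value — the boundary of the projected solution space, e.g.
#' product formation versus growth.
#'
#' @inheritParams fba
#' @param x_reaction,y_reaction reaction ids spanning the envelope plane.
#' @param n_points number of grid points (>= 2).
#' @return A tibble of class `production_envelope` with columns `x`, `y_min`,
#'   `y_max`, `feasible`, plus attributes `x_reaction`/`y_reaction`.
#' @export
production_envelope <- function(model, x_reaction, y_reaction, n_points = 20,
                                fixed = NULL) {
  if (n_points < 2) rlang::abort("n_points must be at least 2")
  xr <- flux_range(model, x_reaction, fixed)
  if (xr$status != "optimal") rlang::abort("x_reaction has no feasible range")
  grid <- seq(xr$min_flux, xr$max_flux, length.out = n_points)
  env <- purrr::map_dfr(grid, function(xv) {
    fr <- flux_range(model, y_reaction, fixed = c(fixed, stats::setNames(xv, x_reaction)))
    tibble::tibble(x = xv, y_min = fr$min_flux, y_max = fr$max_flux,
                   feasible = fr$status == "optimal")
  })
  structure(env,
            class = c("production_envelope", class(env)),
            x_reaction = x_reaction, y_reaction = y_reaction)
}
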