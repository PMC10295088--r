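#' Construct a constraint-based metabolic model
#'
#' A metabolic model is the polytope definition used everywhere else in the
#' package: a stoichiometric matrix `S` (metabolites x reactions), per-reaction
#' flux bounds, and an objective reaction. Fluxes follow the COBRA sign
#' convention: uptake through an exchange reaction is negative, so a glucose
#' uptake of 10 mmol/gDW/h is stored as `EX_glc = -10`.
#'
#' Exchange reactions are auto-detected as the reactions whose column of `S`
#' involves exactly one metabolite (the boundary convention used by BiGG
#' models); the detected set can be overridden with `exchange`.
#'
#' @param S numeric matrix, metabolites in rows and reactions in columns.
#'   Dimnames are used when `metabolite_ids`/`reaction_ids` are missing.
#' @param lower,upper numeric vectors of flux bounds (mmol/gDW/h), one entry
#'   per reaction.
#' @param objective id of the objective reaction (e.g. a biomass reaction).
#' @param metabolite_ids,reaction_ids character vectors of identifiers.
#' @param exchange optional character vector overriding exchange detection.
#' @param id model identifier carried into sample provenance.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [make_toy_model()], [load_model()], [fba()]
#' @export
metabolic_model <- function(S, lower, upper, objective,
                            metabolite_ids = rownames(S),
                            reaction_ids = colnames(S),
                            exchange = NULL,
                            id = "model") {
  S <- as.matrix(S)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(nrow(S)))
  if (is.null(reaction_ids)) reaction_ids <- paste0("r", seq_len(ncol(S)))
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  lower <- stats::setNames(as.numeric(lower), reaction_ids)
  upper <- stats::setNames(as.numeric(upper), reaction_ids)
  if (is.null(exchange)) exchange <- detect_exchanges(S)
  m <- structure(
    list(
      id = id,
      metabolite_ids = metabolite_ids,
      reaction_ids = reaction_ids,
      S = S,
      lower = lower,
      upper = upper,
      objective = objective,
      exchange = exchange
    ),
    class = "metabolic_model"
  )
  validate_model(m)
  m
}

detect_exchanges <- function(S) {
  n_mets <- colSums(S != 0)
  colnames(S)[n_mets == 1L]
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: consistent dimensions, finite
#' coefficients, `lower <= upper` for every reaction, and that the objective
#' and exchange reactions exist. Called by every constructor and loader.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly. Aborts with a descriptive error on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- model$S
  n <- length(model$reaction_ids)
  m <- length(model$metabolite_ids)
  if (!all(dim(S) == c(m, n))) {
    rlang::abort("stoichiometry dimensions do not match metabolite/reaction ids")
  }
  if (anyNA(S) || any(!is.finite(S))) {
    rlang::abort("stoichiometric coefficients must be finite")
  }
  if (length(model$lower) != n || length(model$upper) != n) {
    rlang::abort("bound vectors must have one entry per reaction")
  }
  bad <- which(model$lower > model$upper)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "lower bound exceeds upper bound for reaction(s): %s",
      paste(model$reaction_ids[bad], collapse = ", ")
    ))
  }
  if (!model$objective %in% model$reaction_ids) {
    rlang::abort(sprintf("objective reaction '%s' not in model", model$objective))
  }
  missing_ex <- setdiff(model$exchange, model$reaction_ids)
  if (length(missing_ex) > 0) {
    rlang::abort(sprintf(
      "exchange reaction(s) not in model: %s", paste(missing_ex, collapse = ", ")
    ))
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "<metabolic_model '%s'>  %d metabolites x %d reactions (%d exchange)\n",
    x$id, length(x$metabolite_ids), length(x$reaction_ids), length(x$exchange)
  ))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Reactions of a model as a tibble
#'
#' One row per reaction with its bounds and exchange/objective flags; the
#' tabular view used by the tidy pipeline functions.
#'
#' @param model a `metabolic_model`.
#' @return A tibble with columns `reaction`, `lower`, `upper`, `exchange`,
#'   `objective`.
#' @export
model_reactions <- function(model) {
  validate_model(model)
  tibble::tibble(
    reaction = model$reaction_ids,
    lower = unname(model$lower),
    upper = unname(model$upper),
    exchange = model$reaction_ids %in% model$exchange,
    objective = model$reaction_ids == model$objective
  )
}

#' Check a flux distribution against its model
#'
#' A flux distribution is a named numeric vector covering every reaction of
#' the model. This verifies the steady-state condition `|S v| <= tol` for
#' every metabolite and the flux bounds up to `tol`.
#'
#' @param v named numeric vector of fluxes (mmol/gDW/h).
#' @param model a `metabolic_model`.
#' @param tol numeric tolerance (default `1e-6`).
#' @return A list with `ok` (logical), `max_residual` (largest `|S v|` entry)
#'   and `bound_violation` (largest bound excess).
#' @export
check_flux_distribution <- function(v, model, tol = 1e-6) {
  if (!all(model$reaction_ids %in% names(v))) {
    rlang::abort("flux distribution must cover every reaction of the model")
  }
  v <- v[model$reaction_ids]
  resid <- max(abs(model$S %*% v))
  viol <- max(c(model$lower - v, v - model$upper, 0))
  list(ok = resid <= tol && viol <= tol, max_residual = resid, bound_violation = viol)
}
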