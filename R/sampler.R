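#' Sampler configuration
#'
#' Default parameters mirror the published OptGP-style setup this package
#' reproduces: 20,000 samples, thinning 10,000, 10 parallel chains
#' ("processes"). Desk-scale analyses pass smaller values explicitly.
#'
#' @param n_samples total number of kept flux vectors.
#' @param thinning keep every `thinning`-th chain point.
#' @param n_chains number of independent ACHR chains whose outputs are
#'   concatenated.
#' @param seed integer seed; the same (model, config) pair always yields a
#'   bit-identical sample matrix.
#' @param n_warmup number of warmup points; `NULL` means
#'   `max(4, 2 * n_reactions)` at sampling time. Values below 4 are
#'   rejected.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 20000L, thinning = 10000L,
                           n_chains = 10L, seed = 1L, n_warmup = NULL) {
  cfg <- list(n_samples = as.integer(n_samples), thinning = as.integer(thinning),
              n_chains = as.integer(n_chains), seed = as.integer(seed),
              n_warmup = if (!is.null(n_warmup)) as.integer(n_warmup))
  if (any(unlist(cfg[c("n_samples", "thinning", "n_chains")]) <= 0L)) {
    rlang::abort("n_samples, thinning and n_chains must be positive")
  }
  if (!is.null(cfg$n_warmup) && cfg$n_warmup < 4L) {
    rlang::abort("n_warmup must be at least 4")
  }
  structure(cfg, class = "sampler_config")
}

#' Generate warmup points on the flux polytope
#'
#' Feasible starting points for the hit-and-run chains: the first
#' `2 * n_reactions` points are flux-variability corners (each reaction
#' minimised then maximised); any further points optimise random +/-1
#' objective combinations, reaching additional vertices.
#'
#' @param model a `metabolic_model`.
#' @param n_warmup number of points (>= 4).
#' @param seed seed for the random objective combinations.
#' @return A numeric matrix `n_warmup x n_reactions` of feasible flux
#'   vectors (columns named by reaction).
#' @export
generate_warmup <- function(model, n_warmup = NULL, seed = 1L) {
  validate_model(model)
  n <- length(model$reaction_ids)
  if (is.null(n_warmup)) n_warmup <- max(4L, 2L * n)
  if (n_warmup < 4L) rlang::abort("n_warmup must be at least 4")
  if (fba(model, model$objective, "max")$status != "optimal") {
    rlang::abort("model is infeasible; cannot generate warmup points")
  }
  W <- matrix(0, n_warmup, n, dimnames = list(NULL, model$reaction_ids))
  zero <- rep(0, nrow(model$S))
  k <- 0L
  for (j in seq_len(n)) {
    for (sense in c("min", "max")) {
      if (k >= n_warmup) break
      obj <- as.numeric(seq_len(n) == j)
      res <- lp_solve_bounded(model$S, zero, model$lower, model$upper, obj, sense)
      if (res$status != "optimal") rlang::abort("FVA corner LP failed during warmup")
      k <- k + 1L
      W[k, ] <- res$x
    }
  }
  if (k < n_warmup) {
    set.seed(seed)
    while (k < n_warmup) {
      obj <- sample(c(-1, 1), n, replace = TRUE)
      res <- lp_solve_bounded(model$S, zero, model$lower, model$upper, obj, "max")
      if (res$status != "optimal") next
      k <- k + 1L
      W[k, ] <- res$x
    }
  }
  W
}

null_space_projector <- function(S, tol = 1e-10) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  rk <- sum(sv$d > tol * max(sv$d, 1))
  Nb <- sv$v[, seq(rk + 1, ncol(S)), drop = FALSE]
  if (rk == ncol(S)) return(matrix(0, ncol(S), ncol(S)))
  Nb %*% t(Nb)
}

#' Hit-and-run flux sampling (ACHR core, OptGP-style chains)
#'
#' Draws flux vectors approximately uniformly from the steady-state polytope.
#' Each chain starts from a distinct warmup point; at every step the search
#' direction is a random warmup point minus the running centre of all points
#' seen so far (the "artificial centering" that aligns steps with the
#' polytope's elongated axes), the step length is uniform on the feasible
#' segment, and every `thinning`-th point is kept. Kept points are
#' re-projected onto the null space of `S` every 100 samples so numerical
#' drift cannot accumulate over long thinned runs. Chains are independent
#' and deterministic given the seed, so the result does not depend on how
#' they are scheduled.
#'
#' @param model a `metabolic_model`.
#' @param config a [sampler_config()].
#' @param pattern_id provenance label for the rows (default `"default"`);
#'   used by the sequential constrained pipeline.
#' @param bounds optional list with `lower`/`upper` overriding the model
#'   bounds (already-clamped polytopes).
#' @return A `flux_sample_set`: list with `reaction_ids`, `matrix`
#'   (`n_samples x n_reactions`), `provenance` tibble (`row`, `pattern_id`,
#'   `chain`, `seed`), `thinning`, `model_id`.
#' @examples
#' m <- make_toy_model("box", 6, seed = 2)
#' s <- sample_fluxes(m, sampler_config(n_samples = 100, thinning = 5,
#'                                      n_chains = 2, seed = 42))
#' nrow(s$matrix)
#' @export
sample_fluxes <- function(model, config = sampler_config(), pattern_id = "default",
                          bounds = NULL) {
  validate_model(model)
  stopifnot(inherits(config, "sampler_config"))
  lower <- if (is.null(bounds)) model$lower else bounds$lower
  upper <- if (is.null(bounds)) model$upper else bounds$upper
  n <- length(model$reaction_ids)
  clamped <- metabolic_model(model$S, lower, upper, model$objective,
                             model$metabolite_ids, model$reaction_ids,
                             exchange = model$exchange, id = model$id)
  W <- generate_warmup(clamped, config$n_warmup, seed = config$seed)
  nw <- nrow(W)
  P <- null_space_projector(model$S)

  per_chain <- rep(config$n_samples %/% config$n_chains, config$n_chains)
  extra <- config$n_samples %% config$n_chains
  if (extra > 0) per_chain[seq_len(extra)] <- per_chain[seq_len(extra)] + 1L

  rows <- vector("list", config$n_chains)
  prov <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    n_keep <- per_chain[ch]
    if (n_keep == 0L) next
    chain_seed <- (config$seed + 77777L * ch) %% 2147483629L
    set.seed(chain_seed)
    x <- W[((ch - 1L) %% nw) + 1L, ]
    center <- colMeans(W)
    wgt <- nw
    kept <- matrix(0, n_keep, n)
    ik <- 0L
    fails <- 0L
    while (ik < n_keep) {
      for (s in seq_len(config$thinning)) {
        repeat {
          d <- W[sample.int(nw, 1L), ] - center
          nd <- sqrt(sum(d * d))
          if (nd > 1e-12) break
          fails <- fails + 1L
          if (fails > 1e6) rlang::abort("sampler stalled: too many degenerate directions")
        }
        d <- d / nd
        pos <- d > 1e-12
        neg <- d < -1e-12
        amax <- suppressWarnings(min((upper[pos] - x[pos]) / d[pos],
                                     (lower[neg] - x[neg]) / d[neg]))
        amin <- suppressWarnings(max((lower[pos] - x[pos]) / d[pos],
                                     (upper[neg] - x[neg]) / d[neg]))
        if (!is.finite(amax) || !is.finite(amin) || amax - amin < 1e-12) {
          fails <- fails + 1L
          if (fails > 1e6) rlang::abort("sampler stalled: empty feasible segments")
          next
        }
        fails <- 0L
        x <- x + stats::runif(1L, amin, amax) * d
        x <- pmin(pmax(x, lower), upper)
        center <- (center * wgt + x) / (wgt + 1)
        wgt <- wgt + 1
      }
      ik <- ik + 1L
      kept[ik, ] <- x
      if (ik %% 100L == 0L) {
        x <- as.numeric(P %*% x)
        x <- pmin(pmax(x, lower), upper)
      }
    }
    # re-project all kept rows once at the end of the chain
    kept <- kept %*% P
    rows[[ch]] <- kept
    prov[[ch]] <- tibble::tibble(pattern_id = rep(pattern_id, n_keep),
                                 chain = ch, seed = chain_seed)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- model$reaction_ids
  provenance <- dplyr::bind_rows(prov)
  provenance$row <- seq_len(nrow(mat))
  new_sample_set(mat, model, provenance[, c("row", "pattern_id", "chain", "seed")],
                 config$thinning)
}

#' Build a sample set from a flux matrix
#'
#' Wraps an existing matrix of flux distributions (rows = samples, columns
#' = reactions) as a `flux_sample_set` so externally produced or synthetic
#' samples can enter the analysis functions.
#'
#' @param mat numeric matrix with reaction ids as column names.
#' @param model_id provenance label.
#' @param exchange optional character vector of exchange reaction ids among
#'   the columns.
#' @param thinning thinning recorded in provenance (default 1).
#' @return A `flux_sample_set`.
#' @export
flux_sample_set <- function(mat, model_id = "external", exchange = character(0),
                            thinning = 1L) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) rlang::abort("matrix must have reaction ids as colnames")
  prov <- tibble::tibble(row = seq_len(nrow(mat)), pattern_id = "external",
                         chain = 1L, seed = NA_integer_)
  new_sample_set(mat, list(id = model_id, exchange = exchange), prov,
                 as.integer(thinning))
}

new_sample_set <- function(mat, model, provenance, thinning) {
  structure(
    list(reaction_ids = colnames(mat), matrix = mat, provenance = provenance,
         thinning = thinning, model_id = model$id,
         exchange = intersect(model$exchange, colnames(mat))),
    class = "flux_sample_set"
  )
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat(sprintf("<flux_sample_set> %d samples x %d reactions (model '%s', thinning %d)\n",
              nrow(x$matrix), length(x$reaction_ids), x$model_id, x$thinning))
  pats <- unique(x$provenance$pattern_id)
  cat(sprintf("  provenance: %d pattern(s), %d chain row group(s)\n",
              length(pats), nrow(unique(x$provenance[c("pattern_id", "chain")]))))
  invisible(x)
}

#' Tidy a sample set into long format
#'
#' @param x a `flux_sample_set`.
#' @param ... unused.
#' @return A tibble with columns `row`, `pattern_id`, `chain`, `reaction`,
#'   `flux`.
#' @method tidy flux_sample_set
#' @export
tidy.flux_sample_set <- function(x, ...) {
  wide <- tibble::as_tibble(x$matrix)
  wide$row <- seq_len(nrow(x$matrix))
  long <- tidyr::pivot_longer(wide, -"row", names_to = "reaction", values_to = "flux")
  dplyr::left_join(long, x$provenance[, c("row", "pattern_id", "chain")], by = "row")[
    , c("row", "pattern_id", "chain", "reaction", "flux")]
}

#' Check every sampled row against mass balance and bounds
#'
#' @param samples a `flux_sample_set`.
#' @param model the model it was drawn from.
#' @param tolerance numeric tolerance (default `1e-6`).
#' @return A list with `violations` (tibble: `row`, `type`, `reaction`,
#'   `amount`) and `max_residual` (largest steady-state residual over all
#'   rows). Sampler output yields an empty violations table.
#' @export
validate_samples <- function(samples, model, tolerance = 1e-6) {
  stopifnot(inherits(samples, "flux_sample_set"))
  if (!identical(samples$reaction_ids, model$reaction_ids)) {
    rlang::abort("sample reaction index does not match the model")
  }
  V <- samples$matrix
  resid <- abs(model$S %*% t(V))  # metabolites x rows
  max_resid <- max(resid, 0)
  bad_ss <- which(resid > tolerance, arr.ind = TRUE)
  lo <- sweep(V, 2, model$lower, "-")
  hi <- sweep(V, 2, model$upper, "-")
  bad_lo <- which(lo < -tolerance, arr.ind = TRUE)
  bad_hi <- which(hi > tolerance, arr.ind = TRUE)
  violations <- dplyr::bind_rows(
    if (nrow(bad_ss)) tibble::tibble(row = bad_ss[, 2], type = "steady_state",
                                     reaction = NA_character_,
                                     amount = resid[bad_ss]),
    if (nrow(bad_lo)) tibble::tibble(row = bad_lo[, 1], type = "lower_bound",
                                     reaction = model$reaction_ids[bad_lo[, 2]],
                                     amount = -lo[bad_lo]),
    if (nrow(bad_hi)) tibble::tibble(row = bad_hi[, 1], type = "upper_bound",
                                     reaction = model$reaction_ids[bad_hi[, 2]],
                                     amount = hi[bad_hi])
  )
  if (is.null(violations)) {
    violations <- tibble::tibble(row = integer(), type = character(),
                                 reaction = character(), amount = numeric())
  }
  list(violations = violations, max_residual = max_resid)
}
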