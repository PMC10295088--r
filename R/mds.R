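#' Normalize sampled fluxes to a common substrate basis
#'
#' Rescales every row so the substrate uptake magnitude equals `scale`
#' (default 100, i.e. fluxes per 100 units of substrate taken up). Flux
#' ratios within a row are unchanged; rows whose substrate flux is
#' numerically zero (`|v| < 1e-9`) cannot be rescaled and are dropped and
#' counted in the `dropped` attribute.
#'
#' @param samples a `flux_sample_set`.
#' @param substrate substrate exchange reaction id.
#' @param scale target uptake magnitude (default 100).
#' @return A `flux_sample_set` with rescaled rows; attribute `dropped`
#'   holds the number of removed rows.
#' @export
normalize_to_substrate <- function(samples, substrate, scale = 100) {
  stopifnot(inherits(samples, "flux_sample_set"))
  if (!substrate %in% samples$reaction_ids) {
    rlang::abort(sprintf("substrate reaction '%s' not in samples", substrate))
  }
  v <- samples$matrix[, substrate]
  keep <- abs(v) >= 1e-9
  if (!any(keep)) rlang::abort("all rows have zero substrate flux; cannot normalize")
  mat <- samples$matrix[keep, , drop = FALSE] * (scale / abs(v[keep]))
  prov <- samples$provenance[keep, , drop = FALSE]
  prov$row <- seq_len(nrow(mat))
  out <- new_sample_set(mat, list(id = samples$model_id, exchange = samples$exchange),
                        prov, samples$thinning)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Embed pooled sample sets on a 2-D plane by metric MDS
#'
#' Pools the labelled sample sets, computes Euclidean distances between flux
#' rows, and embeds them on one shared plane so the spread of differently
#' generated sets can be compared visually and via [spread_metric()]. The
#' embedding is classical scaling refined by SMACOF (Guttman transform)
#' iterations, which is deterministic, so the seed only namespaces the
#' result for provenance.
#'
#' @param sets named list of `flux_sample_set` objects (names become point
#'   labels), or a single set.
#' @param seed integer, recorded in the result.
#' @param reactions optional subset of reactions to compute distances over
#'   (e.g. exchange reactions only); default all shared reactions.
#' @param max_iter,tol SMACOF iteration controls.
#' @return A tibble of class `flux_embedding` with columns `x`, `y`,
#'   `label`, and attributes `stress` (normalised stress-1) and `seed`.
#' @export
mds_embed <- function(sets, seed = 1L, reactions = NULL, max_iter = 50L,
                      tol = 1e-6) {
  if (inherits(sets, "flux_sample_set")) sets <- list(samples = sets)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, logical(1), "flux_sample_set")))
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  ids <- sets[[1]]$reaction_ids
  if (!all(vapply(sets, function(s) identical(s$reaction_ids, ids), logical(1)))) {
    rlang::abort("all sample sets must share one reaction index")
  }
  if (is.null(reactions)) reactions <- ids
  if (!all(reactions %in% ids)) rlang::abort("unknown reaction in `reactions`")
  X <- do.call(rbind, lapply(sets, function(s) s$matrix[, reactions, drop = FALSE]))
  labels <- rep(names(sets), vapply(sets, function(s) nrow(s$matrix), integer(1)))
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  if (n < 2) rlang::abort("need at least two points to embed")
  # cmdscale warns when fewer than 2 positive eigenvalues exist (degenerate
  # clouds); the padding below handles that case
  Y <- suppressWarnings(stats::cmdscale(D, k = 2))
  if (ncol(Y) < 2) Y <- cbind(Y, matrix(0, n, 2L - ncol(Y)))  # degenerate clouds
  # SMACOF refinement: minimise raw stress by repeated Guttman transforms
  for (it in seq_len(max_iter)) {
    dY <- as.matrix(stats::dist(Y))
    ratio <- ifelse(dY > 1e-12, D / dY, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Ynew <- B %*% Y / n
    if (max(abs(Ynew - Y)) < tol) { Y <- Ynew; break }
    Y <- Ynew
  }
  dY <- as.matrix(stats::dist(Y))
  stress <- sqrt(sum((D - dY)^2) / max(sum(D^2), .Machine$double.eps))
  out <- tibble::tibble(x = Y[, 1], y = Y[, 2], label = labels)
  structure(out, class = c("flux_embedding", class(out)),
            stress = stress, seed = as.integer(seed))
}

#' Mean distance of an embedded cloud to its centroid
#'
#' The diversity summary used to compare constrained versus default
#' sampling: larger spread means the sample set covers the flux space more
#' widely. Rotation- and translation-invariant.
#'
#' @param embedding a `flux_embedding`.
#' @param label which point cloud to summarise; `NULL` means all points.
#' @return A scalar (mean Euclidean distance to the cloud centroid).
#' @export
spread_metric <- function(embedding, label = NULL) {
  stopifnot(inherits(embedding, "flux_embedding"))
  pts <- embedding
  if (!is.null(label)) {
    if (!label %in% embedding$label) rlang::abort(sprintf("label '%s' not present", label))
    pts <- embedding[embedding$label == label, , drop = FALSE]
  }
  if (nrow(pts) == 1) {
    rlang::warn("single point: spread is 0")
    return(0)
  }
  cx <- mean(pts$x); cy <- mean(pts$y)
  mean(sqrt((pts$x - cx)^2 + (pts$y - cy)^2))
}

#' @method glance flux_embedding
#' @export
glance.flux_embedding <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    n_sets = length(unique(x$label)),
    stress = attr(x, "stress")
  )
}
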