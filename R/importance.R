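#' Count samples matching a flux query
#'
#' The hit-count primitive of the importance analysis: a query assigns a
#' value to one or more reactions, and a row matches when every queried flux
#' lies within a relative window of the query value,
#' `|v - q| <= rel_window * |q|`. A query value of exactly zero falls back
#' to an absolute window `abs_tol`, since a relative window around zero
#' would only match exact zeros.
#'
#' @param samples a `flux_sample_set`.
#' @param query named numeric vector, reaction id -> queried flux value.
#' @param rel_window relative half-width of the window (default 0.10, the
#'   +/-10 percent query).
#' @param abs_tol absolute window used when a query value is 0.
#' @return Integer count of matching rows (conjunctive over query entries).
#' @export
count_matching_samples <- function(samples, query, rel_window = 0.10,
                                   abs_tol = 1e-6) {
  stopifnot(inherits(samples, "flux_sample_set"))
  if (length(query) == 0) rlang::abort("query must not be empty")
  if (is.null(names(query)) || !all(names(query) %in% samples$reaction_ids)) {
    rlang::abort("query reactions must be named and present in the samples")
  }
  sum(query_mask(samples$matrix, query, rel_window, abs_tol))
}

query_mask <- function(mat, query, rel_window, abs_tol = 1e-6) {
  keep <- rep(TRUE, nrow(mat))
  for (r in names(query)) {
    q <- query[[r]]
    w <- if (q == 0) abs_tol else rel_window * abs(q)
    keep <- keep & abs(mat[, r] - q) <= w
  }
  keep
}

#' Rank fluxes by how sharply a +/-10 percent query narrows the sample set
#'
#' For every candidate reaction, each sampled value in turn is used as a
#' query against the whole sample set and the number of matching rows is
#' recorded; candidates are ranked by the mean hit count, ascending — a flux
#' whose window isolates few samples pins down the metabolic state well and
#' is therefore an informative measurement. Candidates default to the
#' exchange fluxes, which are the ones measurable in the culture medium.
#'
#' @param samples a `flux_sample_set`.
#' @param candidates character vector of reaction ids to rank.
#' @param rel_window relative query window (default 0.10).
#' @param groups optional output of [group_by_correlation()]; when given,
#'   each entry is annotated with its group id.
#' @param abs_tol absolute window for zero query values.
#' @return A tibble of class `importance_ranking` with columns `rank`,
#'   `reaction`, `group_id`, `mean_hits`, `median_hits`, sorted ascending by
#'   `mean_hits` (ties broken by median, then reaction id).
#' @export
rank_flux_importance <- function(samples, candidates = NULL, rel_window = 0.10,
                                 groups = NULL, abs_tol = 1e-6) {
  stopifnot(inherits(samples, "flux_sample_set"))
  if (is.null(candidates)) {
    candidates <- if (length(samples$exchange)) samples$exchange else samples$reaction_ids
  }
  if (length(candidates) == 0) rlang::abort("no candidate reactions")
  missing <- setdiff(candidates, samples$reaction_ids)
  if (length(missing) > 0) {
    rlang::abort(sprintf("candidate reaction(s) absent from samples: %s",
                         paste(missing, collapse = ", ")))
  }
  mat <- samples$matrix
  n <- nrow(mat)
  stats_per <- purrr::map_dfr(candidates, function(r) {
    v <- mat[, r]
    w <- ifelse(v == 0, abs_tol, rel_window * abs(v))
    # hits[i] = #rows j with |v_j - v_i| <= w_i ; O(n log n) via sorting
    o <- order(v)
    sv <- v[o]
    hi <- findInterval(v + w, sv)
    lo <- findInterval(v - w, sv, left.open = TRUE)
    hits <- hi - lo
    tibble::tibble(reaction = r, mean_hits = mean(hits),
                   median_hits = stats::median(hits))
  })
  if (!is.null(groups)) {
    gmap <- tidyr::unnest(tibble::tibble(group_id = groups$group_id,
                                         reaction = groups$members),
                          "reaction")
    stats_per <- dplyr::left_join(stats_per, gmap, by = "reaction")
  } else {
    stats_per$group_id <- NA_integer_
  }
  out <- dplyr::arrange(stats_per, .data$mean_hits, .data$median_hits, .data$reaction)
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "reaction", "group_id", "mean_hits", "median_hits")]
  structure(out, class = c("importance_ranking", class(out)),
            rel_window = rel_window, n_samples = n)
}

#' Group fluxes by pairwise correlation
#'
#' Computes Pearson correlations between all sampled flux columns and links
#' two fluxes when `|r| >= threshold` (default 0.95, the published cutoff);
#' groups are the connected components of that graph, so each group is a set
#' of mutually redundant measurements. Zero-variance (constant) fluxes have
#' no defined correlation and carry no discriminating information; they are
#' collected into a single designated constant group (`constant = TRUE`).
#'
#' @param samples a `flux_sample_set` with at least 3 rows.
#' @param threshold absolute correlation threshold (default 0.95).
#' @return A tibble of class `flux_groups` with columns `group_id`,
#'   `members` (list column), `size`, `constant`.
#' @export
group_by_correlation <- function(samples, threshold = 0.95) {
  stopifnot(inherits(samples, "flux_sample_set"))
  mat <- samples$matrix
  if (nrow(mat) < 3) rlang::abort("need at least 3 rows to estimate correlations")
  sds <- apply(mat, 2, stats::sd)
  const <- sds < 1e-12
  ids <- colnames(mat)
  groups <- list()
  if (any(!const)) {
    cc <- suppressWarnings(stats::cor(mat[, !const, drop = FALSE]))
    cc[is.na(cc)] <- 0
    adj <- abs(cc) >= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)
    ord <- order(vapply(seq_len(comp$no), function(k) min(which(comp$membership == k)),
                        integer(1)))
    groups <- lapply(ord, function(k) ids[!const][comp$membership == k])
  }
  out <- tibble::tibble(
    group_id = seq_along(groups),
    members = groups,
    size = lengths(groups),
    constant = FALSE
  )
  if (any(const)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      group_id = length(groups) + 1L,
      members = list(ids[const]),
      size = sum(const),
      constant = TRUE
    ))
  }
  structure(out, class = c("flux_groups", class(out)), threshold = threshold)
}

#' Estimate the minimum number of fluxes needed to identify one distribution
#'
#' How many flux measurements pin the metabolic state down to a single
#' sampled distribution? Each trial draws one representative flux per
#' correlation group, shuffles their order, and then, for every target row,
#' applies the representatives' values (+/- the relative window) as
#' cumulative filters until exactly one sample — the target itself — is
#' left; the number of filters used is that (row, ordering) count. The
#' published setup repeats this for 800 random orderings; `orderings =
#' "exhaustive"` instead enumerates every permutation of the groups (only
#' sensible for small group counts) so small instances can be checked
#' exactly.
#'
#' @param samples a `flux_sample_set`.
#' @param groups output of [group_by_correlation()]; the constant group is
#'   never drawn from.
#' @param n_orders number of random orderings (default 800).
#' @param rel_window relative filter window (default 0.10).
#' @param seed integer seed.
#' @param orderings `"random"` or `"exhaustive"`.
#' @param fixed_representatives if `TRUE`, representatives are drawn once
#'   and reused for every ordering instead of re-drawn per trial.
#' @param abs_tol absolute window for zero values.
#' @return A list of class `min_flux_estimate`: `per_trial_counts` (integer
#'   vector over trials x rows), `mean`, `median`, `n_orders`,
#'   `n_unresolved` (counts where even all groups left duplicates).
#' @export
min_fluxes_to_identify <- function(samples, groups, n_orders = 800L,
                                   rel_window = 0.10, seed = 1L,
                                   orderings = c("random", "exhaustive"),
                                   fixed_representatives = FALSE,
                                   abs_tol = 1e-6) {
  stopifnot(inherits(samples, "flux_sample_set"), inherits(groups, "flux_groups"))
  orderings <- match.arg(orderings)
  usable <- groups[!groups$constant, , drop = FALSE]
  if (nrow(usable) == 0) rlang::abort("no non-constant group to draw from")
  mat <- samples$matrix
  n_rows <- nrow(mat)
  g <- nrow(usable)
  set.seed(seed)
  perms <- if (orderings == "exhaustive") {
    all_permutations(g)
  } else {
    lapply(seq_len(n_orders), function(i) sample.int(g))
  }
  draw_reps <- function() {
    vapply(usable$members, function(m) m[[sample.int(length(m), 1L)]], character(1))
  }
  reps_fixed <- if (fixed_representatives) draw_reps()
  counts <- integer(0)
  unresolved <- 0L
  for (perm in perms) {
    reps <- if (fixed_representatives) reps_fixed else draw_reps()
    ordered_reps <- reps[perm]
    cols <- mat[, ordered_reps, drop = FALSE]
    wins <- ifelse(cols == 0, abs_tol, rel_window * abs(cols))
    trial_counts <- integer(n_rows)
    for (t in seq_len(n_rows)) {
      alive <- rep(TRUE, n_rows)
      used <- g
      for (k in seq_len(g)) {
        alive <- alive & abs(cols[, k] - cols[t, k]) <= wins[t, k]
        if (sum(alive) == 1L) { used <- k; break }
      }
      if (sum(alive) > 1L) unresolved <- unresolved + 1L
      trial_counts[t] <- used
    }
    counts <- c(counts, trial_counts)
  }
  structure(
    list(per_trial_counts = counts, mean = mean(counts),
         median = stats::median(counts), n_orders = length(perms),
         n_unresolved = unresolved),
    class = "min_flux_estimate"
  )
}

all_permutations <- function(g) {
  if (g == 1) return(list(1L))
  sub <- all_permutations(g - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(g)) {
      out[[length(out) + 1L]] <- append(p, g, after = pos - 1L)
    }
  }
  out
}

#' @export
print.min_flux_estimate <- function(x, ...) {
  cat(sprintf(
    "<min_flux_estimate> mean %.3f, median %.1f over %d ordering(s) (%d counts%s)\n",
    x$mean, x$median, x$n_orders, length(x$per_trial_counts),
    if (x$n_unresolved > 0) sprintf(", %d unresolved", x$n_unresolved) else ""
  ))
  invisible(x)
}

#' @method tidy min_flux_estimate
#' @export
tidy.min_flux_estimate <- function(x, ...) {
  tibble::tibble(trial = seq_along(x$per_trial_counts), count = x$per_trial_counts)
}

#' @method glance min_flux_estimate
#' @export
glance.min_flux_estimate <- function(x, ...) {
  tibble::tibble(mean = x$mean, median = x$median, n_orders = x$n_orders,
                 n_counts = length(x$per_trial_counts),
                 n_unresolved = x$n_unresolved)
}
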