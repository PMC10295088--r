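#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux importance ranking
#'
#' @param x an `importance_ranking`.
#' @param ... unused.
#' @return A plain tibble (`rank`, `reaction`, `group_id`, `mean_hits`,
#'   `median_hits`).
#' @method tidy importance_ranking
#' @export
tidy.importance_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "reaction", "group_id",
                                 "mean_hits", "median_hits")])
}

#' @method glance importance_ranking
#' @export
glance.importance_ranking <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x),
                 rel_window = attr(x, "rel_window"),
                 n_samples = attr(x, "n_samples"),
                 best_reaction = x$reaction[1],
                 best_mean_hits = x$mean_hits[1])
}

#' Tidy correlation groups into one row per member flux
#'
#' @param x a `flux_groups`.
#' @param ... unused.
#' @return A tibble with columns `group_id`, `reaction`, `size`,
#'   `constant`.
#' @method tidy flux_groups
#' @export
tidy.flux_groups <- function(x, ...) {
  tidyr::unnest(
    tibble::tibble(group_id = x$group_id, reaction = x$members,
                   size = x$size, constant = x$constant),
    "reaction"
  )
}

#' @method glance flux_groups
#' @export
glance.flux_groups <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x),
                 n_fluxes = sum(x$size),
                 threshold = attr(x, "threshold"),
                 n_constant = sum(x$size[x$constant]))
}
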