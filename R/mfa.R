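#' Read a 13C-MFA reference flux table
#'
#' The reference is a CSV with columns `reaction_id`, `reference_flux`
#' (per 100 units of substrate uptake) and optionally `direction_sign`
#' (+1/-1, applied to map literature flux directions onto the model's
#' reaction directions — the comparison keeps signs, it does not take
#' magnitudes). The package ships
#' `system.file("extdata", "mfa_reference_synthetic.csv", package =
#' "fluxpin")`, a synthetic table for format illustration and tests; real
#' validations must transcribe a published 13C-MFA table.
#'
#' @param path CSV file path.
#' @param anchor_reaction reaction id used for sample selection (e.g. the
#'   CO2 emission flux); must appear in the table.
#' @return A list of class `mfa_reference` with `fluxes` (named numeric,
#'   signs already mapped), `anchor_reaction`, `anchor_value`.
#' @export
read_mfa_reference <- function(path, anchor_reaction) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "reference_flux")
  if (!all(need %in% names(df))) {
    rlang::abort("reference CSV needs columns reaction_id, reference_flux")
  }
  sign <- if ("direction_sign" %in% names(df)) df$direction_sign else rep(1, nrow(df))
  fluxes <- stats::setNames(df$reference_flux * sign, df$reaction_id)
  mfa_reference(fluxes, anchor_reaction)
}

#' Construct an MFA reference in code
#'
#' @param fluxes named numeric vector, reaction id -> reference flux per
#'   100 substrate.
#' @param anchor_reaction reaction used by [select_by_anchor()].
#' @return An `mfa_reference`.
#' @export
mfa_reference <- function(fluxes, anchor_reaction) {
  if (anyNA(fluxes) || any(!is.finite(fluxes))) {
    rlang::abort("reference fluxes must be finite")
  }
  if (!anchor_reaction %in% names(fluxes)) {
    rlang::abort(sprintf("anchor reaction '%s' not in the reference table", anchor_reaction))
  }
  structure(
    list(fluxes = fluxes, anchor_reaction = anchor_reaction,
         anchor_value = unname(fluxes[anchor_reaction])),
    class = "mfa_reference"
  )
}

#' Select samples whose anchor flux matches a measured value
#'
#' Keeps the rows whose anchor flux lies within a relative window of the
#' measured value (default +/-10 percent, the assumed measurement error),
#' preserving provenance. An empty selection returns an empty set with a
#' warning, not an error.
#'
#' @param samples a `flux_sample_set`.
#' @param anchor anchor reaction id.
#' @param anchor_value measured value of the anchor flux.
#' @param rel_window relative window (default 0.10).
#' @param abs_tol absolute window when `anchor_value` is 0.
#' @return A `flux_sample_set` restricted to the matching rows; attribute
#'   `selected_rows` maps back to the input row indices.
#' @export
select_by_anchor <- function(samples, anchor, anchor_value, rel_window = 0.10,
                             abs_tol = 1e-6) {
  stopifnot(inherits(samples, "flux_sample_set"))
  if (!anchor %in% samples$reaction_ids) {
    rlang::abort(sprintf("anchor reaction '%s' not in samples", anchor))
  }
  keep <- which(query_mask(samples$matrix, stats::setNames(anchor_value, anchor),
                           rel_window, abs_tol))
  if (length(keep) == 0) rlang::warn("no sample within the anchor window")
  mat <- samples$matrix[keep, , drop = FALSE]
  prov <- samples$provenance[keep, , drop = FALSE]
  prov$row <- seq_len(nrow(mat))
  out <- new_sample_set(mat, list(id = samples$model_id, exchange = samples$exchange),
                        prov, samples$thinning)
  attr(out, "selected_rows") <- keep
  out
}

#' Mean absolute percentage error of one sample against the reference
#'
#' `100/n * sum(|v_r - ref_r| / |ref_r|)` over the compared reactions,
#' after normalising the sample to the reference's substrate basis (100
#' units of uptake) when `substrate` is given. Reactions with a reference
#' flux of exactly zero are excluded (the ratio is undefined) and reported
#' via the `excluded` attribute.
#'
#' @param sample_row named numeric flux vector (one sampled distribution).
#' @param reference an `mfa_reference`.
#' @param compared_reactions reactions entering the error sum; defaults to
#'   every reference reaction present in the sample.
#' @param substrate optional substrate exchange id used to rescale the
#'   sample to 100 units of uptake before comparison.
#' @param scale substrate basis (default 100).
#' @return MAPE in percent, with attribute `excluded` (zero-reference
#'   reactions dropped from the sum).
#' @export
mape <- function(sample_row, reference, compared_reactions = NULL,
                 substrate = NULL, scale = 100) {
  stopifnot(inherits(reference, "mfa_reference"))
  if (is.null(compared_reactions)) {
    compared_reactions <- intersect(names(reference$fluxes), names(sample_row))
  }
  if (length(compared_reactions) == 0) rlang::abort("no reactions to compare")
  missing <- setdiff(compared_reactions,
                     intersect(names(sample_row), names(reference$fluxes)))
  if (length(missing) > 0) {
    rlang::abort(sprintf("compared reaction(s) missing: %s",
                         paste(missing, collapse = ", ")))
  }
  v <- sample_row
  if (!is.null(substrate)) {
    sv <- abs(v[[substrate]])
    if (sv < 1e-9) rlang::abort("sample substrate flux is zero; cannot normalize")
    v <- v * (scale / sv)
  }
  ref <- reference$fluxes[compared_reactions]
  excluded <- compared_reactions[ref == 0]
  use <- compared_reactions[ref != 0]
  if (length(use) == 0) rlang::abort("all compared reference fluxes are zero")
  err <- 100 * mean(abs(v[use] - reference$fluxes[use]) / abs(reference$fluxes[use]))
  attr(err, "excluded") <- excluded
  err
}

#' Rank samples by MAPE against the reference and report the best k
#'
#' Scores every row of `samples` (typically the anchor-selected subset) by
#' [mape()] and returns the `k` best, ascending; ties are broken by row id
#' so the ordering is stable. Also emits the per-reaction comparison table
#' behind the grouped bar chart (reference versus each top sample).
#'
#' @param samples a `flux_sample_set`.
#' @param reference an `mfa_reference`.
#' @param k how many top samples to report (default 5).
#' @param compared_reactions reactions entering the MAPE sum.
#' @param substrate,scale passed to [mape()].
#' @return A list of class `mfa_validation`: `scores` (tibble `row`,
#'   `sample_id`, `mape`, ascending), `top_k` (first `k` rows),
#'   `comparison` (tibble `reaction`, `source`, `flux` for the reference
#'   and each top sample), `k`.
#' @export
top_k_by_mape <- function(samples, reference, k = 5L, compared_reactions = NULL,
                          substrate = NULL, scale = 100) {
  stopifnot(inherits(samples, "flux_sample_set"))
  n <- nrow(samples$matrix)
  if (n == 0) rlang::abort("no samples to score")
  if (k < 1) rlang::abort("k must be at least 1")
  if (k > n) {
    rlang::warn(sprintf("k = %d exceeds the %d available samples; returning all", k, n))
    k <- n
  }
  if (is.null(compared_reactions)) {
    compared_reactions <- intersect(names(reference$fluxes), samples$reaction_ids)
  }
  scores <- purrr::map_dbl(seq_len(n), function(i) {
    as.numeric(mape(samples$matrix[i, ], reference, compared_reactions,
                    substrate = substrate, scale = scale))
  })
  ord <- order(scores, seq_len(n))
  # sample ids refer to rows of the original set when this one was selected
  orig <- attr(samples, "selected_rows") %||% seq_len(n)
  score_tbl <- tibble::tibble(
    row = ord,
    sample_id = paste0("Sample", orig[ord]),
    mape = scores[ord]
  )
  top <- score_tbl[seq_len(k), , drop = FALSE]
  ref <- reference$fluxes[compared_reactions]
  use <- compared_reactions[ref != 0]
  comparison <- dplyr::bind_rows(
    tibble::tibble(reaction = use, source = "13C-MFA", flux = unname(reference$fluxes[use])),
    purrr::map_dfr(seq_len(k), function(j) {
      v <- samples$matrix[top$row[j], ]
      if (!is.null(substrate)) v <- v * (scale / abs(v[[substrate]]))
      tibble::tibble(reaction = use, source = top$sample_id[j], flux = unname(v[use]))
    })
  )
  structure(
    list(scores = score_tbl, top_k = top, comparison = comparison, k = k),
    class = "mfa_validation"
  )
}

#' @export
print.mfa_validation <- function(x, ...) {
  cat(sprintf("<mfa_validation> %d sample(s) scored; best MAPE %.4f%%\n",
              nrow(x$scores), x$top_k$mape[1]))
  print(x$top_k)
  invisible(x)
}

#' @method tidy mfa_validation
#' @export
tidy.mfa_validation <- function(x, ...) x$scores

#' @method glance mfa_validation
#' @export
glance.mfa_validation <- function(x, ...) {
  tibble::tibble(n_scored = nrow(x$scores), k = x$k,
                 best_mape = x$top_k$mape[1],
                 worst_top_mape = x$top_k$mape[x$k])
}
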