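#' Synthesize small metabolic models with known solution-space geometry
#'
#' Four topologies with analytically understood flux polytopes, used to test
#' every stage of the pipeline without downloading a genome-scale model:
#'
#' * `linear_chain` — one uptake exchange, a chain of 1:1 conversions, one
#'   export; mass balance forces all internal fluxes (and the magnitudes of
#'   the two exchanges) to be equal, so the polytope is a line segment.
#' * `diamond` — two parallel branches between inlet and outlet; at every
#'   node `v_branchA + v_branchB = v_inlet`.
#' * `box` — `n/2` metabolites each with an uptake/export exchange pair; each
#'   pair is perfectly coupled but independent of the others, so the polytope
#'   is an axis-aligned box in the export coordinates (uniform marginals,
#'   analytic centroid at the bound midpoints).
#' * `core_like` — a ~20-reaction central-metabolism caricature (substrate
#'   uptake, lumped glycolysis, pentose-phosphate-like branch, a two-step
#'   TCA with a fully coupled reaction pair, respiration, acetate overflow,
#'   a biomass-like sink and O2/NH4/Fe/CO2 exchanges) with seed-jittered
#'   exchange capacities; feasible with strictly positive optimal growth.
#'
#' @param topology one of `"linear_chain"`, `"diamond"`, `"box"`,
#'   `"core_like"`.
#' @param n_reactions total reaction count (>= 3). `linear_chain` uses it
#'   exactly; `diamond` appends chain links after the merge node beyond its
#'   4-reaction core; `box` rounds down to an even number of exchange pairs;
#'   `core_like` ignores it (fixed 20-reaction topology).
#' @param seed integer seed controlling the jittered bounds.
#' @return A `metabolic_model`.
#' @examples
#' m <- make_toy_model("linear_chain", n_reactions = 5)
#' fba(m, "EX_out", "max")$objective_value  # 10, the inlet capacity
#' @export
make_toy_model <- function(topology = c("linear_chain", "diamond", "box", "core_like"),
                           n_reactions = NULL, seed = 1L) {
  topology <- match.arg(topology)
  switch(topology,
    linear_chain = toy_linear_chain(n_reactions %||% 5L),
    diamond = toy_diamond(n_reactions %||% 4L),
    box = toy_box(n_reactions %||% 6L, seed),
    core_like = toy_core_like(seed)
  )
}

toy_linear_chain <- function(n) {
  if (n < 3) rlang::abort("linear_chain needs n_reactions >= 3")
  n_int <- n - 2L
  mets <- paste0("M", seq_len(n_int + 1L))
  rxns <- c("EX_in", paste0("R", seq_len(n_int)), "EX_out")
  S <- matrix(0, length(mets), n, dimnames = list(mets, rxns))
  S["M1", "EX_in"] <- -1
  for (i in seq_len(n_int)) {
    S[paste0("M", i), paste0("R", i)] <- -1
    S[paste0("M", i + 1L), paste0("R", i)] <- 1
  }
  S[paste0("M", n_int + 1L), "EX_out"] <- -1
  lower <- c(-10, rep(0, n_int), 0)
  upper <- c(0, rep(1000, n_int), 1000)
  metabolic_model(S, lower, upper, objective = "EX_out", id = "toy_linear_chain")
}

toy_diamond <- function(n) {
  if (n < 4) rlang::abort("diamond needs n_reactions >= 4")
  n_tail <- n - 4L  # extra chain links after the merge node
  mets <- c("Min", "Mmid", if (n_tail > 0) paste0("T", seq_len(n_tail)))
  rxns <- c("EX_in", "branchA", "branchB",
            if (n_tail > 0) paste0("R", seq_len(n_tail)), "EX_out")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["Min", "EX_in"] <- -1
  S["Min", c("branchA", "branchB")] <- -1
  S["Mmid", c("branchA", "branchB")] <- 1
  prev <- "Mmid"
  if (n_tail > 0) {
    for (i in seq_len(n_tail)) {
      S[prev, paste0("R", i)] <- -1
      S[paste0("T", i), paste0("R", i)] <- 1
      prev <- paste0("T", i)
    }
  }
  S[prev, "EX_out"] <- -1
  lower <- stats::setNames(rep(0, length(rxns)), rxns)
  upper <- stats::setNames(rep(1000, length(rxns)), rxns)
  lower["EX_in"] <- -10; upper["EX_in"] <- 0
  upper["branchA"] <- 3; upper["branchB"] <- 4
  metabolic_model(S, lower, upper, objective = "EX_out", id = "toy_diamond")
}

toy_box <- function(n, seed) {
  k <- max(1L, n %/% 2L)  # independent exchange pairs
  mets <- paste0("B", seq_len(k))
  rxns <- as.vector(rbind(paste0("EX_in_", seq_len(k)), paste0("EX_out_", seq_len(k))))
  S <- matrix(0, k, 2L * k, dimnames = list(mets, rxns))
  set.seed(seed)
  widths <- round(stats::runif(k, 4, 10), 2)
  lower <- numeric(2L * k); upper <- numeric(2L * k)
  for (i in seq_len(k)) {
    S[i, paste0("EX_in_", i)] <- -1
    S[i, paste0("EX_out_", i)] <- -1
    ci_in <- 2L * i - 1L; ci_out <- 2L * i
    lower[ci_in] <- -widths[i]; upper[ci_in] <- 0
    lower[ci_out] <- 0; upper[ci_out] <- widths[i]
  }
  metabolic_model(S, lower, upper, objective = "EX_out_1", id = "toy_box")
}

# Central-metabolism caricature. Carbon/redox bookkeeping is stylised, not
# elementally balanced; what matters is the polytope: positive optimal
# growth, a fully coupled pair (tca1/tca2 via akg), an overflow branch, and
# exchanges mimicking glucose/O2/NH4/Fe/CO2/acetate.
toy_core_like <- function(seed) {
  set.seed(seed)
  mets <- c("glc", "g6p", "pyr", "accoa", "akg", "ac", "lac",
            "co2", "o2", "nh4", "fe", "atp", "nadh", "aa")
  rxn <- function(...) {
    v <- stats::setNames(rep(0, length(mets)), mets)
    coefs <- list(...)
    for (nm in names(coefs)) v[nm] <- coefs[[nm]]
    v
  }
  cols <- list(
    EX_glc = rxn(glc = -1),
    EX_o2  = rxn(o2 = -1),
    EX_nh4 = rxn(nh4 = -1),
    EX_fe  = rxn(fe = -1),
    EX_co2 = rxn(co2 = -1),
    EX_ac  = rxn(ac = -1),
    EX_lac = rxn(lac = -1),
    EX_akg = rxn(akg = -1),
    UPT  = rxn(glc = -1, atp = -1, g6p = 1),
    GLY  = rxn(g6p = -1, pyr = 2, atp = 2, nadh = 2),
    PPP  = rxn(g6p = -1, pyr = 1, co2 = 1, nadh = 2),
    PDH  = rxn(pyr = -1, accoa = 1, co2 = 1, nadh = 1),
    TCA1 = rxn(accoa = -1, akg = 1, co2 = 1, nadh = 2),
    TCA2 = rxn(akg = -1, co2 = 2, nadh = 2, atp = 1),
    OXP  = rxn(nadh = -1, o2 = -0.5, atp = 2),
    ACK  = rxn(accoa = -1, ac = 1, atp = 1),
    LDH  = rxn(pyr = -1, nadh = -1, lac = 1),
    AAS  = rxn(pyr = -1, nh4 = -1, nadh = -1, atp = -1, aa = 1),
    BIO  = rxn(g6p = -0.2, aa = -1, atp = -3, fe = -0.01),
    ATPS = rxn(atp = -1)  # non-growth maintenance sink
  )
  S <- do.call(cbind, cols)
  rownames(S) <- mets
  rxns <- colnames(S)
  lower <- stats::setNames(rep(0, length(rxns)), rxns)
  upper <- stats::setNames(rep(1000, length(rxns)), rxns)
  lower["EX_glc"] <- -10; upper["EX_glc"] <- 0
  lower["EX_o2"] <- -round(stats::runif(1, 16, 22), 2); upper["EX_o2"] <- 0
  lower["EX_nh4"] <- -round(stats::runif(1, 10, 15), 2); upper["EX_nh4"] <- 0
  lower["EX_fe"] <- -round(stats::runif(1, 0.5, 2), 2); upper["EX_fe"] <- 0
  upper["EX_akg"] <- 2
  upper["LDH"] <- round(stats::runif(1, 5, 15), 2)
  lower["ATPS"] <- 1  # forced maintenance keeps 0 outside the polytope
  metabolic_model(S, lower, upper, objective = "BIO", id = "toy_core_like")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
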