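# Dense bounded-variable two-phase primal simplex.
#
# Solves  min/max  c'x   s.t.  A x = b,  lb <= x <= ub.
# Written for the small dense systems that arise from desk-scale metabolic
# models (tens of reactions); robustness is favoured over speed: the basis
# is refactorised at every iteration and Bland's rule kicks in after a fixed
# number of Dantzig pivots to rule out cycling. Rank-deficient A (conserved
# moieties in stoichiometric matrices) is handled by leaving the redundant
# artificials basic at zero with pinned bounds.

BIG_BOUND <- 1e7  # stand-in for an infinite bound; solutions at it => unbounded

lp_solve_bounded <- function(A, b, lb, ub, obj, sense = c("min", "max"),
                             tol = 1e-9, maxit = 20000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  cc <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  free_lo <- !is.finite(lb)
  free_hi <- !is.finite(ub)
  lb[free_lo] <- -BIG_BOUND
  ub[free_hi] <- BIG_BOUND
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  ub <- pmax(ub, lb)

  # nonbasic start: each structural variable at its bound nearest zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  x <- pmin(pmax(x, lb), ub)
  at_upper <- x == ub & lb != ub

  r <- as.numeric(b - A %*% x)
  s <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(s, m, m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(BIG_BOUND, m))
  xall <- c(x, abs(as.numeric(r)))
  atu <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)

  run_phase <- function(costs, basis, xall, atu, lball, uball) {
    N <- ncol(Aall)
    bland_after <- 200L + 10L * N
    for (it in seq_len(maxit)) {
      Bmat <- Aall[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(N), basis)
      # recompute basic values from the nonbasic bounds (keeps drift out)
      rhs <- b - Aall[, nonbasic, drop = FALSE] %*% xall[nonbasic]
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) qr.solve(Bmat, rhs))
      xall[basis] <- as.numeric(xB)

      y <- tryCatch(solve(t(Bmat), costs[basis]),
                    error = function(e) qr.solve(t(Bmat), costs[basis]))
      d <- costs[nonbasic] - as.numeric(crossprod(Aall[, nonbasic, drop = FALSE], y))
      fixed <- lball[nonbasic] == uball[nonbasic]
      improve <- ifelse(atu[nonbasic], d > tol, d < -tol) & !fixed
      if (!any(improve)) {
        return(list(status = "optimal", basis = basis, xall = xall, atu = atu))
      }
      cand <- which(improve)
      if (it <= bland_after) {
        q_rel <- cand[which.max(abs(d[cand]))]
      } else {
        q_rel <- cand[which.min(nonbasic[cand])]
      }
      q <- nonbasic[q_rel]
      dir <- if (atu[q]) -1 else 1

      w <- tryCatch(solve(Bmat, Aall[, q]), error = function(e) qr.solve(Bmat, Aall[, q]))
      wd <- dir * as.numeric(w)
      # ratio test: entering moves by t*dir >= 0, basics by -wd*t
      t_own <- uball[q] - lball[q]
      t_basic <- rep(Inf, m)
      for (i in seq_len(m)) {
        if (wd[i] > tol) {
          t_basic[i] <- max((xall[basis[i]] - lball[basis[i]]) / wd[i], 0)
        } else if (wd[i] < -tol) {
          t_basic[i] <- max((uball[basis[i]] - xall[basis[i]]) / (-wd[i]), 0)
        }
      }
      t_min <- min(t_basic)
      if (t_own <= t_min) {
        # entering variable runs to its opposite bound; basis unchanged
        if (t_own >= BIG_BOUND) {
          return(list(status = "unbounded", basis = basis, xall = xall, atu = atu))
        }
        xall[basis] <- xall[basis] - wd * t_own
        atu[q] <- !atu[q]
        xall[q] <- if (atu[q]) uball[q] else lball[q]
        next
      }
      if (!is.finite(t_min) || t_min >= BIG_BOUND) {
        return(list(status = "unbounded", basis = basis, xall = xall, atu = atu))
      }
      # leaving variable: among minimal ratios take the largest pivot magnitude
      ties <- which(t_basic <= t_min + tol)
      leave <- ties[which.max(abs(wd[ties]))]
      xall[q] <- xall[q] + dir * t_min
      xall[basis] <- xall[basis] - wd * t_min
      p <- basis[leave]
      hit_lower <- wd[leave] > 0
      atu[p] <- !hit_lower
      xall[p] <- if (hit_lower) lball[p] else uball[p]
      basis[leave] <- q
      atu[q] <- FALSE
    }
    list(status = "maxit", basis = basis, xall = xall, atu = atu)
  }

  # Phase I: drive the artificials to zero
  if (sum(xall[n + seq_len(m)]) > tol) {
    costs1 <- c(rep(0, n), rep(1, m))
    ph1 <- run_phase(costs1, basis, xall, atu, lball, uball)
    if (ph1$status == "maxit") {
      return(list(status = "error", objective = NA_real_, x = NULL))
    }
    art_sum <- sum(ph1$xall[n + seq_len(m)])
    if (art_sum > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    basis <- ph1$basis
    xall <- ph1$xall
    atu <- ph1$atu
  }
  # pin artificials for phase II
  uball[n + seq_len(m)] <- 0
  xall[n + seq_len(m)][!(n + seq_len(m)) %in% basis] <- 0

  costs2 <- c(cc, rep(0, m))
  ph2 <- run_phase(costs2, basis, xall, atu, lball, uball)
  if (ph2$status == "maxit") {
    return(list(status = "error", objective = NA_real_, x = NULL))
  }
  x <- ph2$xall[seq_len(n)]
  if (ph2$status == "unbounded" ||
      any((free_lo & x < -BIG_BOUND * (1 - 1e-6)) | (free_hi & x > BIG_BOUND * (1 - 1e-6)))) {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  objective <- sum(as.numeric(obj) * x)
  list(status = "optimal", objective = objective, x = x)
}
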