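# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package internals.

# enumerate all vertices of {A x = b, lb <= x <= ub}; only viable when the
# number of free dimensions (n - rank) is small
enum_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  n <- ncol(A)
  rk <- qr(A)$rank
  verts <- list()
  basis_sets <- if (rk == 0) list(integer(0)) else utils::combn(n, rk, simplify = FALSE)
  for (bs in basis_sets) {
    AB <- A[, bs, drop = FALSE]
    if (length(bs) > 0 && qr(AB)$rank < rk) next
    nb <- setdiff(seq_len(n), bs)
    choices <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    if (nrow(choices) == 0) choices <- data.frame(row.names = 1)
    for (g in seq_len(nrow(choices))) {
      x <- numeric(n)
      if (length(nb) > 0) {
        up <- unlist(choices[g, ])
        x[nb] <- ifelse(up, ub[nb], lb[nb])
      }
      rhs <- b - if (length(nb)) A[, nb, drop = FALSE] %*% x[nb] else b * 0
      xb <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xb) && rk > 0) next
      if (rk > 0) x[bs] <- xb
      if (all(x >= lb - tol) && all(x <= ub + tol) &&
          max(abs(A %*% x - b)) < tol) {
        verts[[length(verts) + 1L]] <- x
      }
    }
  }
  if (length(verts) == 0) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

enum_vertices_model <- function(model, fixed = NULL) {
  lower <- model$lower
  upper <- model$upper
  if (length(fixed)) {
    for (r in names(fixed)) {
      v <- fixed[[r]]
      eps <- max(1e-6 * abs(v), 1e-9)
      lower[r] <- max(lower[r], v - eps)
      upper[r] <- min(upper[r], v + eps)
    }
  }
  enum_vertices(model$S, rep(0, nrow(model$S)), lower, upper)
}

oracle_fba <- function(model, objective, sense, fixed = NULL) {
  V <- enum_vertices_model(model, fixed)
  if (nrow(V) == 0) return(NA_real_)
  vals <- V[, which(model$reaction_ids == objective)]
  if (sense == "max") max(vals) else min(vals)
}

# window helper shared by the brute-force analyses
brute_window <- function(q, rel, abs_tol = 1e-6) {
  if (q == 0) abs_tol else rel * abs(q)
}

brute_count <- function(mat, query, rel, abs_tol = 1e-6) {
  cnt <- 0L
  for (i in seq_len(nrow(mat))) {
    ok <- TRUE
    for (r in names(query)) {
      if (abs(mat[i, r] - query[[r]]) > brute_window(query[[r]], rel, abs_tol)) {
        ok <- FALSE
        break
      }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

brute_rank <- function(mat, candidates, rel, abs_tol = 1e-6) {
  res <- data.frame(reaction = candidates, mean_hits = NA_real_,
                    median_hits = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(candidates)) {
    r <- candidates[k]
    hits <- integer(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      q <- stats::setNames(mat[i, r], r)
      hits[i] <- brute_count(mat, q, rel, abs_tol)
    }
    res$mean_hits[k] <- mean(hits)
    res$median_hits[k] <- stats::median(hits)
  }
  res[order(res$mean_hits, res$median_hits, res$reaction), "reaction"]
}

# connected components over |cor| >= threshold, via repeated set expansion
brute_groups <- function(mat, threshold) {
  ids <- colnames(mat)
  keep <- apply(mat, 2, stats::sd) > 1e-12
  cc <- abs(suppressWarnings(stats::cor(mat[, keep, drop = FALSE])))
  cc[is.na(cc)] <- 0
  members <- colnames(mat)[keep]
  groups <- list()
  unassigned <- members
  while (length(unassigned) > 0) {
    grp <- unassigned[1]
    repeat {
      linked <- members[apply(cc[grp, , drop = FALSE] >= threshold, 2, any)]
      newgrp <- union(grp, linked)
      if (setequal(newgrp, grp)) break
      grp <- newgrp
    }
    groups[[length(groups) + 1L]] <- sort(grp)
    unassigned <- setdiff(unassigned, grp)
  }
  if (any(!keep)) groups[[length(groups) + 1L]] <- sort(ids[!keep])
  groups
}

# per-(ordering, target-row) filter counts, given fixed representatives
brute_minflux_counts <- function(mat, reps, perm, rel, abs_tol = 1e-6) {
  n <- nrow(mat)
  g <- length(reps)
  counts <- integer(n)
  for (t in seq_len(n)) {
    alive <- seq_len(n)
    used <- g
    for (k in seq_len(g)) {
      r <- reps[perm[k]]
      q <- mat[t, r]
      w <- brute_window(q, rel, abs_tol)
      alive <- alive[abs(mat[alive, r] - q) <= w]
      if (length(alive) == 1L) { used <- k; break }
    }
    counts[t] <- used
  }
  counts
}

all_perms <- function(g) {
  if (g == 1) return(list(1L))
  out <- list()
  for (p in all_perms(g - 1L)) {
    for (pos in 0:(g - 1L)) out[[length(out) + 1L]] <- append(p, g, after = pos)
  }
  out
}

# a small synthetic sample "matrix" with named flux columns
random_sample_matrix <- function(n_rows, n_flux, seed) {
  set.seed(seed)
  mat <- matrix(stats::rnorm(n_rows * n_flux, mean = 5, sd = 3), n_rows, n_flux)
  colnames(mat) <- paste0("v", seq_len(n_flux))
  mat
}
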