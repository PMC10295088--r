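test_that("match counts equal the brute-force double loop", {
  mat <- random_sample_matrix(50, 10, seed = 101)
  s <- flux_sample_set(mat)
  set.seed(202)
  for (trial in 1:30) {
    r <- sample(colnames(mat), 1)
    q <- stats::setNames(mat[sample(50, 1), r], r)
    expect_identical(count_matching_samples(s, q, 0.10),
                     brute_count(mat, q, 0.10))
  }
  # multi-flux conjunctive queries
  for (trial in 1:10) {
    rs <- sample(colnames(mat), 3)
    i <- sample(50, 1)
    q <- stats::setNames(mat[i, rs], rs)
    expect_identical(count_matching_samples(s, q, 0.10),
                     brute_count(mat, q, 0.10))
  }
})

test_that("match-count edge cases behave analytically", {
  mat <- random_sample_matrix(40, 4, seed = 7)
  mat[, "v4"] <- 2.5  # constant flux
  s <- flux_sample_set(mat)
  # a row's own values always match it
  for (i in c(1, 17, 40)) {
    q <- stats::setNames(mat[i, "v1"], "v1")
    expect_gte(count_matching_samples(s, q, 0.10), 1L)
  }
  # a constant flux hits every row
  expect_identical(count_matching_samples(s, c(v4 = 2.5), 0.10), 40L)
  expect_error(count_matching_samples(s, numeric(0)), "empty")
  expect_error(count_matching_samples(s, c(bogus = 1)), "query reactions")
})

test_that("widening the window never loses matches", {
  mat <- random_sample_matrix(50, 5, seed = 31)
  s <- flux_sample_set(mat)
  set.seed(17)
  for (trial in 1:20) {
    r <- sample(colnames(mat), 1)
    q <- stats::setNames(mat[sample(50, 1), r], r)
    counts <- vapply(c(0.01, 0.05, 0.10, 0.25, 0.50),
                     function(w) count_matching_samples(s, q, w), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the importance ranking matches the brute-force oracle", {
  mat <- random_sample_matrix(30, 8, seed = 55)
  s <- flux_sample_set(mat)
  ranking <- rank_flux_importance(s, candidates = colnames(mat), rel_window = 0.10)
  expect_identical(ranking$reaction, brute_rank(mat, colnames(mat), 0.10))
  expect_equal(ranking$rank, seq_len(8L))
  expect_true(all(diff(ranking$mean_hits) >= 0))
  expect_true(all(ranking$mean_hits >= 1 & ranking$mean_hits <= 30))
})

test_that("a per-row-unique flux ranks first with mean hits 1", {
  set.seed(5)
  # geometric spacing (ratio 1.3 > 1.1/0.9) keeps all +/-10% windows disjoint
  mat <- cbind(v_unique = 10 * 1.3^(0:24),
               v_noisy = stats::rnorm(25, 10, 0.1))
  s <- flux_sample_set(mat)
  ranking <- rank_flux_importance(s, candidates = colnames(mat), rel_window = 0.10)
  expect_equal(ranking$reaction[1], "v_unique")
  expect_equal(ranking$mean_hits[1], 1)
  expect_equal(ranking$median_hits[1], 1)
  expect_error(rank_flux_importance(s, candidates = "nope"), "nope")
})

test_that("correlation grouping equals the brute-force components", {
  set.seed(71)
  base <- stats::rnorm(60)
  mat <- cbind(
    a1 = base, a2 = 2 * base + 1e-3 * stats::rnorm(60),   # same group
    b1 = -3 * base + 0.0005 * stats::rnorm(60),            # |r| ~ 1, negative
    c1 = stats::rnorm(60), d1 = stats::rnorm(60),          # independent
    e1 = rep(4, 60)                                        # constant
  )
  s <- flux_sample_set(mat)
  got <- group_by_correlation(s, threshold = 0.95)
  want <- brute_groups(mat, 0.95)
  got_sets <- lapply(got$members, sort)
  expect_setequal(lapply(got_sets, paste, collapse = "+"),
                  lapply(want, paste, collapse = "+"))
  expect_true(got$constant[got$size == 1 & vapply(got$members, identical,
                                                  logical(1), "e1")])
})

test_that("grouping thresholds collapse to the analytic extremes", {
  mat <- random_sample_matrix(200, 6, seed = 91)
  s <- flux_sample_set(mat)
  all_single <- group_by_correlation(s, threshold = 1.0)
  expect_equal(nrow(all_single), 6L)
  expect_true(all(all_single$size == 1))
  one_group <- group_by_correlation(s, threshold = 0)
  expect_equal(nrow(one_group), 1L)
  expect_equal(one_group$size, 6L)
  # independent uniform columns stay singletons at 0.95 even at n = 1000
  set.seed(13)
  big <- matrix(stats::runif(1000 * 5), 1000, 5,
                dimnames = list(NULL, paste0("u", 1:5)))
  singles <- group_by_correlation(flux_sample_set(big), threshold = 0.95)
  expect_equal(nrow(singles), 5L)
  expect_error(group_by_correlation(flux_sample_set(mat[1:2, ])), "3 rows")
})

test_that("coupled chain reactions share a correlation group", {
  m <- make_toy_model("linear_chain", n_reactions = 5)
  s <- sample_fluxes(m, sampler_config(n_samples = 50, thinning = 5,
                                       n_chains = 2, seed = 3))
  g <- group_by_correlation(s, 0.95)
  internals <- grep("^R", m$reaction_ids, value = TRUE)
  holder <- which(vapply(g$members, function(mm) internals[1] %in% mm, logical(1)))
  expect_true(all(internals %in% g$members[[holder]]))
})

test_that("exhaustive min-flux counts equal enumeration over all orderings", {
  # 10 rows, 4 perfectly separated groups built from 4 independent signals
  set.seed(29)
  sig <- matrix(stats::runif(10 * 4, 1, 100), 10, 4)
  mat <- cbind(sig, sig %*% diag(4) * 2)  # duplicate each signal -> 4 groups of 2
  colnames(mat) <- c(paste0("g", 1:4, "_a"), paste0("g", 1:4, "_b"))
  s <- flux_sample_set(mat)
  groups <- group_by_correlation(s, threshold = 0.95)
  expect_equal(nrow(groups), 4L)
  est <- min_fluxes_to_identify(s, groups, rel_window = 0.10, seed = 41,
                                orderings = "exhaustive",
                                fixed_representatives = TRUE)
  expect_equal(est$n_orders, 24L)
  expect_length(est$per_trial_counts, 24L * 10L)
  # oracle: same fixed representatives, every permutation, naive loops
  set.seed(41)
  reps <- vapply(groups$members, function(m) m[[sample.int(length(m), 1)]],
                 character(1))
  oracle <- unlist(lapply(all_perms(4L), function(p)
    brute_minflux_counts(mat, reps, p, 0.10)))
  expect_equal(sort(est$per_trial_counts), sort(oracle))
  expect_equal(est$mean, mean(oracle))
  expect_equal(est$median, stats::median(oracle))
})

test_that("filter chains shrink monotonically and keep their target", {
  mat <- random_sample_matrix(40, 6, seed = 61)
  s <- flux_sample_set(mat)
  set.seed(3)
  for (trial in 1:10) {
    t <- sample(40, 1)
    order_r <- sample(colnames(mat))
    alive <- rep(TRUE, 40)
    prev <- sum(alive)
    for (r in order_r) {
      q <- stats::setNames(mat[t, r], r)
      keep <- abs(mat[, r] - q) <= 0.10 * abs(q)
      alive <- alive & keep
      expect_lte(sum(alive), prev)
      expect_true(alive[t])  # the target survives its own filters
      prev <- sum(alive)
    }
  }
})

test_that("a uniquely identifying first flux gives count 1 everywhere", {
  # geometric spacing keeps +/-10% windows disjoint, so the key flux always
  # isolates its row on the first filter
  mat <- cbind(key = 10 * 1.5^(0:11), other = rep(5, 12))
  s <- flux_sample_set(mat)
  g <- group_by_correlation(s, threshold = 0.95)
  keyg <- g[!g$constant & vapply(g$members, identical, logical(1), "key"), ]
  expect_equal(nrow(keyg), 1L)
  est <- min_fluxes_to_identify(s, g, n_orders = 5, rel_window = 0.10, seed = 1)
  expect_true(all(est$per_trial_counts == 1L))
  expect_equal(est$mean, 1)
  expect_equal(est$n_unresolved, 0L)
})
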