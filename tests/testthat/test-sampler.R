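test_that("warmup points are feasible and hit the FVA corners", {
  m <- make_toy_model("box", 6, seed = 2)
  n <- length(m$reaction_ids)
  W <- generate_warmup(m, n_warmup = 2L * n, seed = 1)
  expect_equal(nrow(W), 2L * n)
  # every point is mass-balanced and inside bounds
  for (i in seq_len(nrow(W))) {
    expect_true(check_flux_distribution(W[i, ], m)$ok)
  }
  # both bound-attaining points exist for every free flux
  for (r in m$reaction_ids) {
    expect_true(any(abs(W[, r] - m$lower[r]) < 1e-6))
    expect_true(any(abs(W[, r] - m$upper[r]) < 1e-6))
  }
})

test_that("warmup on the diamond contains the analytic vertices", {
  m <- make_toy_model("diamond")
  V <- enum_vertices_model(m)
  W <- generate_warmup(m, n_warmup = 2L * length(m$reaction_ids), seed = 1)
  for (i in seq_len(nrow(V))) {
    d <- apply(W, 1, function(w) max(abs(w - V[i, ])))
    expect_lt(min(d), 1e-6)
  }
})

test_that("sampled rows satisfy steady state and bounds on every toy", {
  for (topo in c("linear_chain", "diamond", "box", "core_like")) {
    m <- make_toy_model(topo, seed = 5)
    s <- sample_fluxes(m, sampler_config(n_samples = 500, thinning = 5,
                                         n_chains = 3, seed = 21))
    rep <- validate_samples(s, m, tolerance = 1e-6)
    expect_equal(nrow(rep$violations), 0L, info = topo)
    expect_lt(rep$max_residual, 1e-6)
  }
})

test_that("identical model and config reproduce a bit-identical sample set", {
  m <- make_toy_model("core_like", seed = 4)
  cfg <- sampler_config(n_samples = 150, thinning = 10, n_chains = 5, seed = 33)
  s1 <- sample_fluxes(m, cfg)
  s2 <- sample_fluxes(m, cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$provenance, s2$provenance)
})

test_that("provenance covers every row and chains share the total", {
  m <- make_toy_model("box", 6, seed = 2)
  s <- sample_fluxes(m, sampler_config(n_samples = 103, thinning = 3,
                                       n_chains = 4, seed = 8))
  expect_equal(nrow(s$provenance), 103L)
  expect_equal(s$provenance$row, seq_len(103L))
  expect_equal(sort(unique(s$provenance$chain)), 1:4)
  counts <- table(s$provenance$chain)
  expect_true(max(counts) - min(counts) <= 1)
})

test_that("box-polytope marginals look uniform with the analytic centroid", {
  m <- make_toy_model("box", 6, seed = 2)
  s <- sample_fluxes(m, sampler_config(n_samples = 5000, thinning = 50,
                                       n_chains = 4, seed = 11))
  ctr <- (m$lower + m$upper) / 2
  for (r in m$reaction_ids) {
    v <- s$matrix[, r]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - ctr[r]), 3 * se)
    D <- suppressWarnings(stats::ks.test(v, "punif", m$lower[r], m$upper[r])$statistic)
    expect_lt(unname(D), 0.05)
  }
})

test_that("sample extrema approach the FVA range monotonically in n", {
  m <- make_toy_model("box", 6, seed = 2)
  spans <- vapply(c(100L, 1000L, 5000L), function(n) {
    s <- sample_fluxes(m, sampler_config(n_samples = n, thinning = 5,
                                         n_chains = 2, seed = 13))
    v <- s$matrix[, "EX_out_2"]
    (max(v) - min(v)) / (m$upper["EX_out_2"] - m$lower["EX_out_2"])
  }, numeric(1))
  expect_true(all(diff(spans) >= 0))
  expect_gt(spans[3], 0.9)
})

test_that("validate_samples pinpoints a hand-corrupted row", {
  m <- make_toy_model("linear_chain", n_reactions = 4)
  s <- sample_fluxes(m, sampler_config(n_samples = 20, thinning = 2,
                                       n_chains = 1, seed = 2))
  s$matrix[7, "EX_out"] <- m$upper["EX_out"] + 1.0
  rep <- validate_samples(s, m)
  bound_rows <- rep$violations[rep$violations$type == "upper_bound", ]
  expect_equal(unique(bound_rows$row), 7)
  expect_true("EX_out" %in% bound_rows$reaction)
  expect_error(validate_samples(s, make_toy_model("diamond")), "reaction index")
})

test_that("tidy() reshapes a sample set to long form with provenance", {
  m <- make_toy_model("box", 6, seed = 1)
  s <- sample_fluxes(m, sampler_config(n_samples = 10, thinning = 2,
                                       n_chains = 2, seed = 3))
  long <- tidy(s)
  expect_equal(nrow(long), 10L * length(m$reaction_ids))
  expect_named(long, c("row", "pattern_id", "chain", "reaction", "flux"))
  expect_equal(long$flux[long$row == 4 & long$reaction == "EX_out_1"],
               unname(s$matrix[4, "EX_out_1"]))
})
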