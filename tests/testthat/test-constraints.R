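core <- make_toy_model("core_like", seed = 7)

test_that("constraint patterns honour the nested feasible ranges", {
  pats <- generate_constraint_patterns(
    core, "EX_glc", "BIO", "EX_ac", n_patterns = 25,
    substrate_interval = c(-10, -2), seed = 5)
  expect_equal(nrow(pats), 25L)
  expect_true(all(pats$feasible))
  for (i in seq_len(nrow(pats))) {
    p <- pats[i, ]
    expect_gte(p$substrate_flux, -10 - 1e-9)
    expect_lte(p$substrate_flux, -2 + 1e-9)
    gr <- flux_range(core, "BIO", fixed = c(EX_glc = p$substrate_flux))
    expect_gte(p$growth_flux, gr$min_flux - 1e-6)
    expect_lte(p$growth_flux, gr$max_flux + 1e-6)
    # the fully clamped triple admits an LP solution
    sol <- fba(core, "BIO", "max",
               fixed = c(EX_glc = p$substrate_flux, BIO = p$growth_flux,
                         EX_ac = p$product_flux))
    expect_equal(sol$status, "optimal")
  }
})

test_that("product clamped to the inlet is forced equal to it on a chain", {
  m <- make_toy_model("linear_chain", n_reactions = 4)
  pats <- generate_constraint_patterns(
    m, "EX_in", "R1", "EX_out", n_patterns = 10,
    substrate_interval = c(-10, -1), seed = 2)
  # conservation: outlet equals the uptake magnitude in every pattern
  expect_equal(pats$product_flux, abs(pats$substrate_flux), tolerance = 1e-5)
  expect_equal(pats$growth_flux, abs(pats$substrate_flux), tolerance = 1e-5)
})

test_that("an infeasible substrate interval aborts the pipeline", {
  expect_error(
    generate_constraint_patterns(core, "EX_glc", "BIO", "EX_ac",
                                 n_patterns = 5, substrate_interval = c(-50, -20),
                                 seed = 1),
    "substrate_interval"
  )
})

test_that("sequential sampling yields per_pattern rows per feasible pattern", {
  pats <- generate_constraint_patterns(
    core, "EX_glc", "BIO", "EX_ac", n_patterns = 20,
    substrate_interval = c(-10, -2), seed = 3)
  s <- sequential_sampling(core, pats, per_pattern = 5,
                           config = sampler_config(thinning = 10, n_chains = 2,
                                                   seed = 17))
  expect_equal(nrow(s$matrix), 100L)
  expect_equal(as.integer(table(s$provenance$pattern_id)),
               rep(5L, 20L), ignore_attr = TRUE)
  rep <- validate_samples(s, core)
  expect_equal(nrow(rep$violations), 0L)
  # each row sits within the clamp window of its pattern
  for (i in seq_len(nrow(s$matrix))) {
    pid <- as.integer(s$provenance$pattern_id[i])
    p <- pats[pats$pattern_id == pid, ]
    expect_lt(abs(s$matrix[i, "EX_glc"] - p$substrate_flux),
              1e-5 * abs(p$substrate_flux) + 1e-8)
    expect_lt(abs(s$matrix[i, "BIO"] - p$growth_flux),
              1e-5 * abs(p$growth_flux) + 1e-8)
    expect_lt(abs(s$matrix[i, "EX_ac"] - p$product_flux),
              1e-5 * abs(p$product_flux) + 1e-8)
  }
})

test_that("pattern scatter fills the feasible production envelope", {
  # analogue of the seed-coverage picture: every feasible cell of a 10x10
  # grid over (growth, product) holds at least one of 1000 patterns
  pats <- generate_constraint_patterns(
    core, "EX_glc", "BIO", "EX_ac", n_patterns = 1000,
    substrate_interval = c(-10, -2), seed = 11)
  gr <- range(pats$growth_flux)
  env <- production_envelope(core, "BIO", "EX_ac", n_points = 11)
  gx <- seq(env$x[1], env$x[11], length.out = 11)
  py <- range(env$y_min, env$y_max)
  gy <- seq(py[1], py[2], length.out = 11)
  for (i in 1:10) {
    xm <- (gx[i] + gx[i + 1]) / 2
    fr <- flux_range(core, "EX_ac", fixed = c(BIO = xm))
    if (fr$status != "optimal") next
    for (j in 1:10) {
      lo <- gy[j]; hi <- gy[j + 1]
      # require the whole cell inside the attainable band: boundary slivers
      # are only reachable at extreme substrate draws and may stay empty
      cell_feasible <- lo > fr$min_flux - 0.1 && hi < fr$max_flux + 0.1 &&
        hi - lo > 0.2
      if (!cell_feasible) next
      inside <- pats$growth_flux >= gx[i] & pats$growth_flux <= gx[i + 1] &
        pats$product_flux >= lo & pats$product_flux <= hi
      expect_gt(sum(inside), 0)
    }
  }
})

test_that("bind_sample_sets concatenates rows and renumbers provenance", {
  m <- make_toy_model("box", 6, seed = 1)
  a <- sample_fluxes(m, sampler_config(n_samples = 6, thinning = 2,
                                       n_chains = 2, seed = 1))
  b <- sample_fluxes(m, sampler_config(n_samples = 4, thinning = 2,
                                       n_chains = 2, seed = 2))
  both <- bind_sample_sets(a, b)
  expect_equal(nrow(both$matrix), 10L)
  expect_equal(both$provenance$row, 1:10)
  expect_error(bind_sample_sets(a, sample_fluxes(make_toy_model("diamond"),
    sampler_config(n_samples = 4, thinning = 2, n_chains = 1, seed = 1))),
    "reaction ind")
})
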