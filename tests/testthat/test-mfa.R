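ref_path <- function() system.file("extdata", "mfa_reference_synthetic.csv",
                                   package = "fluxpin")

test_that("reference CSV reader applies direction signs and finds the anchor", {
  ref <- read_mfa_reference(ref_path(), "EX_co2")
  expect_s3_class(ref, "mfa_reference")
  expect_equal(ref$anchor_value, 160)
  expect_equal(unname(ref$fluxes["EX_glc"]), -100)
  expect_error(read_mfa_reference(ref_path(), "missing_rxn"), "anchor")
  expect_error(mfa_reference(c(a = Inf), "a"), "finite")
})

test_that("anchor selection equals a brute-force filter", {
  mat <- random_sample_matrix(60, 5, seed = 19)
  s <- flux_sample_set(mat)
  av <- mat[25, "v2"]
  sel <- select_by_anchor(s, "v2", av, rel_window = 0.10)
  want <- which(abs(mat[, "v2"] - av) <= 0.10 * abs(av))
  expect_equal(attr(sel, "selected_rows"), want)
  expect_true(25 %in% attr(sel, "selected_rows"))
  # a far-out anchor selects nothing, with a warning rather than an error
  expect_warning(empty <- select_by_anchor(s, "v2", 1e6, rel_window = 0.10),
                 "no sample")
  expect_equal(nrow(empty$matrix), 0L)
})

test_that("MAPE has its closed-form values and scale consistency", {
  ref <- mfa_reference(c(rA = 10, rB = 20), "rA")
  expect_equal(as.numeric(mape(c(rA = 10, rB = 20), ref)), 0)
  expect_equal(as.numeric(mape(c(rA = 15), ref, compared_reactions = "rA")), 50)
  # scale consistency: doubling sample and reference leaves MAPE unchanged
  ref2 <- mfa_reference(c(rA = 20, rB = 40), "rA")
  v <- c(rA = 13, rB = 31)
  expect_equal(as.numeric(mape(v, ref)), as.numeric(mape(2 * v, ref2)))
  # substrate renormalization maps the sample onto the per-100 basis
  ref3 <- mfa_reference(c(EX_glc = -100, rA = 50), "rA")
  v3 <- c(EX_glc = -5, rA = 2)
  expect_equal(as.numeric(mape(v3, ref3, substrate = "EX_glc")),
               mean(c(0, 100 * abs(40 - 50) / 50)))
})

test_that("zero-reference reactions are excluded without touching the rest", {
  ref <- mfa_reference(c(rA = 10, rB = 0, rC = 40), "rA")
  v <- c(rA = 12, rB = 99, rC = 30)
  e <- mape(v, ref)
  expect_equal(attr(e, "excluded"), "rB")
  expect_equal(as.numeric(e), mean(c(20, 25)))
  # dropping rC from the comparison does not change rA's contribution
  e2 <- mape(v, ref, compared_reactions = c("rA", "rB"))
  expect_equal(as.numeric(e2), 20)
  expect_error(mape(v, mfa_reference(c(rA = 0), "rA")), "zero")
})

test_that("top-k ordering equals the brute-force sort and keeps prefixes", {
  mat <- random_sample_matrix(30, 4, seed = 77)
  colnames(mat) <- c("rA", "rB", "rC", "rD")
  ref <- mfa_reference(c(rA = 5, rB = 6, rC = 7), "rA")
  s <- flux_sample_set(mat)
  full <- top_k_by_mape(s, ref, k = 30)
  oracle <- vapply(seq_len(30), function(i) {
    mean(abs(mat[i, c("rA", "rB", "rC")] - c(5, 6, 7)) / c(5, 6, 7)) * 100
  }, numeric(1))
  expect_equal(full$scores$mape, sort(oracle), tolerance = 1e-10)
  expect_equal(full$scores$row, order(oracle))
  top3 <- top_k_by_mape(s, ref, k = 3)
  expect_equal(top3$top_k, full$scores[1:3, ], ignore_attr = TRUE)
  expect_warning(top_k_by_mape(s, ref, k = 50), "exceeds")
})

test_that("a set containing the reference itself scores MAPE 0 at the top", {
  ref <- mfa_reference(c(rA = 5, rB = 6), "rA")
  mat <- rbind(c(5, 6), c(7, 9), c(4, 2))
  colnames(mat) <- c("rA", "rB")
  v <- top_k_by_mape(flux_sample_set(mat), ref, k = 1)
  expect_equal(v$top_k$row, 1L)
  expect_equal(v$top_k$mape, 0)
  expect_equal(v$top_k$sample_id, "Sample1")
})

test_that("validation runs end to end on the core toy with the synthetic reference", {
  core <- make_toy_model("core_like", seed = 7)
  s <- sample_fluxes(core, sampler_config(n_samples = 300, thinning = 10,
                                          n_chains = 4, seed = 12))
  norm <- normalize_to_substrate(s, "EX_glc")
  ref <- read_mfa_reference(ref_path(), "EX_co2")
  sel <- select_by_anchor(norm, "EX_co2", ref$anchor_value, 0.10)
  expect_gt(nrow(sel$matrix), 0)
  v <- top_k_by_mape(sel, ref, k = min(5, nrow(sel$matrix)))
  expect_true(all(diff(v$top_k$mape) >= 0))
  expect_true(all(v$top_k$row %in% seq_len(nrow(sel$matrix))))
  # anchor flux of every selected row is within the window
  expect_true(all(abs(sel$matrix[, "EX_co2"] - ref$anchor_value)
                  <= 0.10 * ref$anchor_value + 1e-9))
  # comparison table carries the reference and each top sample
  expect_setequal(unique(v$comparison$source), c("13C-MFA", v$top_k$sample_id))
})
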