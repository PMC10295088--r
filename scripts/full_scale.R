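#!/usr/bin/env Rscript
# Full-scale case study: constrained flux sampling of E. coli iJO1366.
#
# NOT part of the routine test run: it needs the iJO1366 model file
# (download it from the BiGG models database, e.g. iJO1366.json) and hours
# of CPU at the published sampling parameters (1000 constraint patterns,
# 20 samples each, thinning 10,000, 10 chains). With those parameters the
# analysis reproduces the published headline numbers up to sampling noise:
# ~457 correlation groups at |r| >= 0.95, a minimum-flux estimate near
# mean 7.2 / median 6, and iron / O2 / CO2 / NH4 exchange fluxes at the
# top of the importance ranking.
#
#   Rscript scripts/full_scale.R --model iJO1366.json --out results/full \
#       --substrate-min -12 --substrate-max -4 [--seed 1]
#
# The substrate interval is the experimentally measured glucose uptake
# range; it must be supplied because no canonical value ships with the
# package.

suppressPackageStartupMessages({
  library(optparse)
  library(fluxpin)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--model", type = "character", help = "path to iJO1366 (JSON or SBML)"),
  make_option("--out", type = "character", default = "results/full"),
  make_option("--substrate-min", type = "double", default = -12,
              dest = "substrate_min"),
  make_option("--substrate-max", type = "double", default = -4,
              dest = "substrate_max"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--mfa-reference", type = "character", default = NULL,
              dest = "mfa_reference",
              help = "13C-MFA reference CSV (per 100 glucose) for validation"),
  make_option("--mfa-anchor", type = "character", default = "EX_co2_e",
              dest = "mfa_anchor")
)))
if (is.null(opts$model)) stop("--model is required (BiGG iJO1366 file)")

model <- load_model(opts$model)
cfg <- run_config(
  model,
  substrate = "EX_glc__D_e",
  growth = model$objective,
  product = "EX_ac_e",
  substrate_interval = c(opts$substrate_min, opts$substrate_max),
  n_patterns = 1000L, per_pattern = 20L,
  sampler = sampler_config(n_samples = 20000L, thinning = 10000L,
                           n_chains = 10L),
  n_default = 20000L,
  rel_window = 0.10, correlation_threshold = 0.95,
  n_orders = 800L, k = 5L, seed = opts$seed,
  mfa_reference = opts$mfa_reference, mfa_anchor = opts$mfa_anchor,
  output_dir = opts$out
)
man <- run_pipeline(cfg)
print(man)
print(glance(man$results$groups))
print(glance(man$results$minflux))
print(tidy(man$results$ranking), n = 20)
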