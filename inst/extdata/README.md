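# extdata

- `mfa_reference_synthetic.csv` — a SYNTHETIC 13C-MFA-style reference flux
  table (per 100 glucose) whose reaction ids match the `core_like` toy
  model. It illustrates the reference CSV format and feeds the tests; it is
  not derived from any published 13C-MFA study. Real validations must
  transcribe a literature flux table into this format (reaction_id,
  reference_flux, direction_sign), mapping literature reaction names and
  flux directions onto the model's ids and sign convention.
- `toy_run.yaml` — a desk-scale run configuration for the command-line
  interface, using the `core_like` toy model.
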