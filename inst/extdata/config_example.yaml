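# Example run configuration. All monetary inputs are year-2022 THB; the
# currency_year tag is mandatory and configurations without it are refused.
schema_version: 1
currency_year: THB-2022
strategies: [SoC, ETA, IFX, GOL, TCZ, RTX, TOF, BAR, bsIFXr, bsIFXi, bsADA, bsRTX]
settings:
  start_age: 56
  horizon_cycles: 200      # 100-year lifetime horizon at 6-month cycles
  annual_discount_rate: 0.03
  wtp_threshold: 160000    # THB per QALY gained
  switch_after: 1          # cycles of inadequate response before SoC switch
  half_cycle: false
psa:
  n_iterations: 5000
  master_seed: 20220101
# mtx_only_cost: 1870      # override the 10%-of-SoC maintenance assumption
output_dir: results
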