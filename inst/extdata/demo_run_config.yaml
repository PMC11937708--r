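# Demo pipeline configuration: calibrated breast-trial synthetic cohort,
# 1000-replicate bootstrap, default fixtures for mapping model, value set
# and ICD category map. Run with:
#   run_pipeline(system.file("extdata", "demo_run_config.yaml",
#                            package = "eprocua"), seed = 1)
trial: B_RCT
generator: {}
bootstrap_B: 1000
ci_method: percentile
exclude_rt: auto
render_planes: false
utilization_outcomes:
- outcome: n_acute_inpatient
  kind: count
- outcome: n_acute_outpatient
  kind: count
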