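# Base economics of the AI-stud case study herd.
# Maintenance: 900 USD/bull/month -> 3600 per 4-month bin.
# The discount convention is the one selected by calibrate_npv_convention()
# against the case-study replacement decomposition; see the package vignette.
maintenance_cost_per_bin_usd: 3600
replacement_cost_usd: 10000
salvage_value_usd: 850
depreciation_value_usd: 54000
depreciation_term_months: 36
interest_rate_annual: 0.06
packing_rate_cells_per_straw: 15000000
n_iterations: 330
discount_convention: per_iteration_rate
discount_exponent_offset: -1
regeneration_in_npv: true
culling_cost_grouping: cull_times_both
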