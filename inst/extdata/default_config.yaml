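# Base-case configuration: every model constant as a named key.
# All keys are optional; absent keys take exactly these defaults.

# trial arm summaries (months)
n_control: 30
n_intervention: 32
control_mean_os: 8.6
control_mean_pfs: 5.6
control_median_os: 5.5
control_median_pfs: 3.6
intervention_mean_os: 10.8
intervention_mean_pfs: 7.1
intervention_median_os: 9.5
intervention_median_pfs: 5.9

# health-state utilities
u_pfs: 0.675
u_asymptomatic_alt: 0.77

# unit costs (EUR, 2009 price level) and cost-model parameters
cetuximab_price_per_100mg: 237.20
vat_factor: 1.0
outpatient_visit_cost: 251
extra_visits_per_patient: 8
egfr_test_cost: 750
egfr_positive_fraction: 0.60
overhead_fraction: 0.355
housing_fraction: 0.065
price_index_factor: 1.0
mean_cumulative_dose_mg: 6443

# cetuximab dosing schedule
loading_mg_per_m2: 400
maintenance_mg_per_m2: 250
maintenance_interval_days: 7
cycle_length_days: 29
max_cycles: 6
bsa_m2: 1.73
pps_shape: 1

# analysis settings
psa_iterations: 1000
wtp_threshold_per_qaly: 40000
time_horizon_years: 0.9
seed: 1
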