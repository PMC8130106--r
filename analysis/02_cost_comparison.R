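#!/usr/bin/env Rscript
# Cost-minimization comparison: internalized vs outsourced provision.
#
# The outsourced arm is what the external provider would have billed for
# the same 23,046 patient-days at the contracted per-device-day rates
# (the contracted total is an exogenous input: the per-patient billing
# detail behind it was never published). Headline metrics: direct
# saving, subgroup decomposition, and cost per device-day in each arm.

suppressPackageStartupMessages(library(cpapcost))
dir.create("results", showWarnings = FALSE)

agg <- study_aggregates()
cons <- consumables_total(study_catalogue(), study_usage_quantities())
internal <- internal_total(cons$total, nursing_cost(agg$nursing_workdays,
                                                    agg$nursing_daily_wage))
cmp <- cost_comparison(internal, agg$outsourced_total, agg$patient_days,
                       agg$n_new, agg$n_prevalent, agg$subgroup_savings)
print(cmp)
rep <- comparison_report(cmp)
cat(sprintf("\nSubgroup savings: new %0.2f (%0.2f/patient), prevalent %0.2f (%0.2f/patient)\n",
            rep$subgroups$new$saving_eur, rep$subgroups$new$per_patient$eur,
            rep$subgroups$prevalent$saving_eur,
            rep$subgroups$prevalent$per_patient$eur))

jsonlite::write_json(rep, "results/cost_comparison.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/cost_comparison.json\n")
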