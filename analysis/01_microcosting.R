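#!/usr/bin/env Rscript
# Microcosting of the internalized CPAP service.
#
# Prices every device and accessory handed out over follow-up at its
# retail unit cost (VAT included, charged in full at acquisition) and
# adds the imputed nursing time, giving the total cost of running the
# service in-house for the 21-patient cohort.

suppressPackageStartupMessages(library(cpapcost))
dir.create("results", showWarnings = FALSE)

cons <- consumables_total(study_catalogue(), study_usage_quantities())
agg <- study_aggregates()
nurse <- nursing_cost(agg$nursing_workdays, agg$nursing_daily_wage)
internal <- internal_total(cons$total, nurse)

cat("Per-item direct costs:\n")
print(cons$by_item, row.names = FALSE)
cat(sprintf("\nConsumables and equipment: %s\n", format(cons$total)))
cat(sprintf("Nursing follow-up (%d workdays x %s): %s\n",
            agg$nursing_workdays, format(agg$nursing_daily_wage),
            format(nurse)))
cat(sprintf("Internalized service total: %s\n", format(internal)))

write.csv(cons$by_item, "results/microcosting_by_item.csv", row.names = FALSE)
write.csv(data.frame(component = c("consumables", "nursing", "total"),
                     cost_eur = c(eur(cons$total), eur(nurse), eur(internal))),
          "results/microcosting_totals.csv", row.names = FALSE)
cat("\nwrote results/microcosting_by_item.csv and results/microcosting_totals.csv\n")
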