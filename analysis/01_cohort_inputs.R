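#!/usr/bin/env Rscript
## Cohort admission inputs: follow-up durations and calculated total
## vascular resistances (SBP / systolic flow) for the nine-patient
## example cohort. Writes results/cohort_inputs.csv and
## results/followup_summary.json.

suppressMessages(library(aortagrowth))
dir.create("results", showWarnings = FALSE)

rec <- example_patients()
fs <- compute_followup_stats(rec)

tab <- data.frame(
  patient_id = rec$patient_id,
  sbp_mmhg = rec$sbp,
  flow_lmin = rec$flow_lmin,
  R_calculated_mmhg_min_l = round(total_resistance(rec$sbp, rec$flow_lmin), 2),
  followup_years = round(fs$years, 2),
  growth_mm_per_year = rec$growth_mm_per_year,
  thrombus_present = rec$thrombus_present)
write.csv(tab, "results/cohort_inputs.csv", row.names = FALSE)

jsonlite::write_json(list(
  median_followup_years = fs$median_years,
  iqr_followup_years = fs$iqr_years,
  median_growth_mm_per_year = fs$median_growth,
  iqr_growth_mm_per_year = fs$iqr_growth,
  flow_25lmin_in_ml_s = inlet_from_velocity(radius = 12.5, flow = 25)$flow * 1000 / 60),
  "results/followup_summary.json", auto_unbox = TRUE, digits = NA)

cat("Calculated resistances (mmHg.min/L):\n")
print(tab[, c("patient_id", "R_calculated_mmhg_min_l")], row.names = FALSE)
cat(sprintf("Median follow-up: %.2f years (IQR %.2f-%.2f)\n",
            fs$median_years, fs$iqr_years[1], fs$iqr_years[2]))
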