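#!/usr/bin/env Rscript
# Stage 3: coaching group assignment and content schedule.
#
# Each participant with at least one MS criterion goes to the management
# group owning their poorest sex/age-standardized indicator (obesity,
# blood_pressure, blood_sugar or lipid); criterion-free participants are
# managed as normal. Emits the group census, each participant's daily step
# target from their MSA stage, and the fixed thrice-weekly content schedule.

suppressPackageStartupMessages(library(msacoach))

scored <- readr::read_csv("results/scored_cohort.csv", show_col_types = FALSE)
assigned <- assign_cohort(scored)
assigned$step_target <- step_target(assigned$msa_stage)
readr::write_csv(assigned, "results/assigned_cohort.csv")

pre <- assigned[assigned$visit == "pre", ]
cat("Management groups at baseline:\n")
print(table(pre$management_group))
cat("\nStep targets by MSA stage:\n")
print(table(pre$msa_stage, pre$step_target))

schedule <- do.call(rbind, lapply(
  c("obesity", "blood_pressure", "blood_sugar", "lipid", "normal"),
  content_schedule))
readr::write_csv(schedule, "results/content_schedule.csv")
cat("\nWeekly cadence (identical for every group):\n")
print(as.data.frame(content_schedule("normal")[, c("weekday", "time", "kind")]),
      row.names = FALSE)
cat("\nWrote results/assigned_cohort.csv and results/content_schedule.csv\n")
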