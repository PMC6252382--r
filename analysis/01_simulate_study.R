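#!/usr/bin/env Rscript

# Generate the synthetic motor-imagery study analysed by the later steps.
#
# Desk-scale cohort: 2 control recordings plus 2 recordings (two sessions)
# of one patient, 43 channels (every named 10-10 position used by the
# LD-SM, LD-whole and HD-SM montages), 7 conditions x 25 trials x 6 s at
# 250 Hz. Recordings are written to the binary array container under
# scratch/ (they are large and reproducible from the seed); the study plan
# table goes to results/.

suppressPackageStartupMessages(library(midecode))

study_seed <- 20260928
cfg <- study_config(
  n_control_recordings = 2,
  n_patient_recordings = 2,
  patient_sessions = 2L,
  n_channels = 43,
  seed = study_seed
)

plan <- study_plan(cfg)
dir.create("scratch/study", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

for (i in seq_len(nrow(plan))) {
  id <- sprintf("%s.%d", plan$subject[i], plan$session[i])
  rec <- generate_recording(cfg,
    profile = plan$profile[i],
    session = plan$session[i], seed = plan$seed[i]
  )
  write_recording(rec, file.path("scratch/study", id))
  message(sprintf(
    "wrote %s (%s, session %d, seed %d)",
    id, plan$profile[i], plan$session[i], plan$seed[i]
  ))
}

plan$recording <- sprintf("%s.%d", plan$subject, plan$session)
write.csv(plan, "results/study_plan.csv", row.names = FALSE)
message(sprintf(
  "study of %d recordings written; plan in results/study_plan.csv",
  nrow(plan)
))
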