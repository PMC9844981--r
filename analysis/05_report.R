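#!/usr/bin/env Rscript
# Stage 5 - one-shot pipeline report.
# Reruns every stage under a single master seed through run_pipeline()
# and writes the combined prior/conventional/adjusted report.
library(biasbayes)

cfg <- list(
  simulate = list(),           # default study-like cohort
  experts = list(
    expert1 = list(
      list(parameter = "P1", lower = 0.025, upper = 0.095),
      list(parameter = "P0", lower = 0.01, upper = 0.06),
      list(parameter = "RR_UY", lower = 1.1, upper = 2.2)),
    expert2 = list(
      list(parameter = "P1", lower = 0.20, upper = 0.40),
      list(parameter = "P0", lower = 0.10, upper = 0.20),
      list(parameter = "RR_UY", lower = 1.1, upper = 5))),
  seed = 20260927L
)

report <- run_pipeline(cfg, out_dir = "results/report")
print(report)
cat("Wrote results/report/report.{json,md} and posterior draw CSVs\n")
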