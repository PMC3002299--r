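#!/usr/bin/env Rscript
# Stage 4: the whole study in one deterministic call, checked against the
# calibration targets.

suppressMessages(library(dggeprof))

report <- run_study(run_config(seed = 1L), out_dir = "results/study")
print(report)

check <- compare_to_targets(report, default_study_targets())
write.csv(check, "results/target_check.csv", row.names = FALSE)
message(sprintf("targets passed: %d / %d", sum(check$pass), nrow(check)))
print(check[, c("id", "target", "value", "cmp", "pass")])
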