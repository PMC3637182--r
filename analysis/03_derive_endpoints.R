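#!/usr/bin/env Rscript
# Derive the time-to-event endpoints from the simulated timelines:
# early symptom onset (two consecutive positive exams), sustained
# weight-loss onset, and the last 60-s wire hang. Writes
# results/endpoints.csv.

suppressMessages(library(sodquant))

tl <- read.csv("results/cohort/timelines.csv")
ev <- derive_endpoints(tl, drop_fraction = 0.05, onset_date = "first")
write.csv(ev, "results/endpoints.csv", row.names = FALSE)

cat("endpoint events written to results/endpoints.csv\n")
for (e in unique(ev$endpoint)) {
  sub <- ev[ev$endpoint == e & ev$observed, ]
  m <- tapply(sub$age_days, sub$arm, mean)
  cat(sprintf("  %-22s mean age: vehicle %.1f d, treated %.1f d (diff %+.1f)\n",
              e, m["vehicle"], m["treated"], m["treated"] - m["vehicle"]))
}
n_flag <- sum(ev$flag != "")
if (n_flag > 0)
  cat(sprintf("  %d degenerate event(s) flagged (never reached a 60-s hang)\n",
              n_flag))
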