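#!/usr/bin/env Rscript

# Step 1: simulate the focal-sampling study.
#
# Generates the synthetic herd (88 females with ages targeting a 9-year mean,
# 3 young males) and one year of focal-sampling records: 240 half-hour
# observation periods (12 months x 2 days x 10 steps), one activity and one
# proximity-partner set per animal per period. Writes roster.csv, records.csv
# and a manifest with the seed so every later step is reproducible.

suppressPackageStartupMessages(library(herdnet))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = seed)
sim <- simulate_herd(cfg)

write_roster(sim$roster, file.path(out, "roster.csv"))
write_records(sim$records, file.path(out, "records.csv"))

ages <- sim$roster$age
message(sprintf("herd: %d animals (%d female, %d male); female ages %.1f-%.1f y, mean %.1f y",
                nrow(sim$roster), sum(sim$roster$gender == 1),
                sum(sim$roster$gender == 2),
                min(ages[sim$roster$gender == 1]),
                max(ages[sim$roster$gender == 1]),
                mean(ages[sim$roster$gender == 1])))
message(sprintf("records: %d rows (%d periods x %d animals)",
                nrow(sim$records), cfg$n_periods, nrow(sim$roster)))
message(sprintf("activity shares: %s",
                paste(sprintf("%s %.1f%%",
                              names(table(sim$records$activity)),
                              100 * table(sim$records$activity) /
                                nrow(sim$records)),
                      collapse = ", ")))

jsonlite::write_json(list(seed = seed,
                          n_animals = nrow(sim$roster),
                          n_periods = cfg$n_periods,
                          roster_md5 = unname(tools::md5sum(file.path(out, "roster.csv"))),
                          records_md5 = unname(tools::md5sum(file.path(out, "records.csv")))),
                     file.path(out, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote results/roster.csv, results/records.csv, results/manifest.json")
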