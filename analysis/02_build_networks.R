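#!/usr/bin/env Rscript

# Step 2: build the activity-stratified proximity networks.
#
# One binary undirected network per (activity, period) over the fixed 91-vertex
# herd, including the empty networks of periods where an activity did not
# occur. As a compact artifact, the densest network of each activity is
# exported as GraphML (the ensemble itself is rebuilt on demand by later
# steps; 1680 matrices do not need to live on disk).

suppressPackageStartupMessages(library(herdnet))

roster <- read_roster("results/roster.csv")
records <- read_records("results/records.csv", roster)
ens <- build_ensemble(records, roster)

message(sprintf("ensemble: %d networks (%d activities x %d periods), %d vertices each -> %d vertex-cases",
                length(ens$networks), length(activities()), ens$n_periods,
                length(ens$vertex_ids),
                length(ens$networks) * length(ens$vertex_ids)))

dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
for (a in activities()) {
  of_a <- ens$networks[grepl(paste0("^", a, "_"), names(ens$networks))]
  edges <- vapply(of_a, function(n) sum(n$adjacency) / 2, numeric(1))
  best <- of_a[[which.max(edges)]]
  f <- file.path("results/networks",
                 sprintf("densest_%s_p%03d.graphml", a, best$period_id))
  write_network(best, f, "graphml")
  message(sprintf("%-10s: %4.0f empty of %d networks; densest has %3.0f edges (period %d)",
                  a, sum(edges == 0), length(of_a), max(edges),
                  best$period_id))
}
message("wrote results/networks/densest_<activity>_p<period>.graphml")
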