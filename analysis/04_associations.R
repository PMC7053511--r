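#!/usr/bin/env Rscript

# Step 4: Spearman associations and correlograms.
#
# Data set 1 correlates the seven activity indicators with the global indices
# (one case per network); data set 2 with the vertex centralities (one case
# per vertex-network); data set 3 correlates age and gender with the
# centralities within each activity. Writes the per-pair results and the
# three correlogram tables (rho with * p<0.05 / ** p<0.01).

suppressPackageStartupMessages(library(herdnet))

roster <- read_roster("results/roster.csv")
records <- read_records("results/records.csv", roster)
tbl <- compute_index_table(build_ensemble(records, roster))
datasets <- assemble_datasets(tbl, roster)
assoc <- run_associations(datasets)
write_associations(assoc, "results")

tabs <- correlogram_table(assoc)
for (nm in names(tabs)) {
  message(sprintf("--- correlogram: %s ---", nm))
  message(paste(utils::capture.output(print(tabs[[nm]], right = TRUE)),
                collapse = "\n"))
}
message("wrote results/associations_*.csv, results/correlogram_*.{csv,txt}")
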