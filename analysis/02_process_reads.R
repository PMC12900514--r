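#!/usr/bin/env Rscript
# Step 2 — read-level processing.
#
# For every replicate of every simulated condition: remove PCR duplicates by
# (start, end, strand, UMI), tally per-base 3'-end coverage, normalize to
# hits per million. Writes per-replicate coverage tables (scratch/cov/),
# mean/min-max bedGraph tracks (scratch/tracks/) and a dedup summary
# (results/dedup_summary.tsv). Run 01_simulate_conditions.R first.

suppressPackageStartupMessages(library(polterm))
dir.create("scratch/cov", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/tracks", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

ann <- default_annotation()
L <- unit_length(ann)
summary_rows <- list()

for (f in c("scratch/sim/reads_wt_superpol.tsv", "scratch/sim/reads_bmh21.tsv")) {
  if (!file.exists(f)) stop("missing ", f, "; run 01_simulate_conditions.R first")
  reads <- read_reads(f)
  for (cond in unique(reads$condition)) {
    rc <- reads[reads$condition == cond, ]
    for (rep in unique(rc$replicate)) {
      rr <- rc[rc$replicate == rep, ]
      dd <- dedup(rr)
      prof <- coverage_3p(dd$records, L)
      write_coverage_tsv(prof, sprintf("scratch/cov/%s_%s.tsv", cond, rep))
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        condition = cond, replicate = rep, reads_in = nrow(rr),
        unique_reads = prof$total, removed = dd$n_removed,
        removed_fraction = round(dd$n_removed / nrow(rr), 4))
    }
    profs <- process_reads(rc, L)[[cond]]
    agg <- aggregate_replicates(profs)
    # export the mean profile as a browser track
    mean_prof <- profs[[1]]; mean_prof$freq <- agg$mean
    write_bedgraph(mean_prof, sprintf("scratch/tracks/%s_mean.bedgraph", cond))
  }
}

summary_tab <- do.call(rbind, summary_rows)
write.table(summary_tab, "results/dedup_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("PCR duplicate removal summary:")
for (i in seq_len(nrow(summary_tab)))
  message(sprintf("  %-15s %s: %6d -> %6d unique (%.1f%% removed)",
                  summary_tab$condition[i], summary_tab$replicate[i],
                  summary_tab$reads_in[i], summary_tab$unique_reads[i],
                  100 * summary_tab$removed_fraction[i]))
message("Wrote scratch/cov/*.tsv, scratch/tracks/*.bedgraph, ",
        "results/dedup_summary.tsv")
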