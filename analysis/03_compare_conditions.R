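#!/usr/bin/env Rscript
# Step 3 — two-condition comparisons.
#
# WT vs SuperPol: per-region summed frequencies with Welch t-tests, the
# conservative envelope difference, the low-coverage-masked log2 ratio, and
# the CDF shift. WT vs WT+BMH-21: localization of the occupancy loss.
# Run 01 and 02 first.

suppressPackageStartupMessages(library(polterm))
dir.create("results", showWarnings = FALSE)
ann <- default_annotation()
L <- unit_length(ann)

load_cond <- function(cond) {
  files <- Sys.glob(sprintf("scratch/cov/%s_rep*.tsv", cond))
  if (!length(files)) stop("no coverage for ", cond, "; run steps 01-02 first")
  lapply(files, read_coverage_tsv, condition = cond)
}

## WT vs SuperPol ----------------------------------------------------------
wt <- load_cond("wt"); sp <- load_cond("superpol")
rs <- region_stats(wt, sp, ann)
write.table(rs[, c("region", "mean_a", "sd_a", "mean_b", "sd_b",
                   "ratio_ab", "t", "p", "stars")],
            "results/region_stats_wt_superpol.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Per-region summed frequency, WT / SuperPol:")
for (i in seq_len(nrow(rs)))
  message(sprintf("  %-6s ratio %.3f  (p = %.3g %s)",
                  rs$region[i], rs$ratio_ab[i], rs$p[i], rs$stars[i]))

agg_wt <- aggregate_replicates(wt); agg_sp <- aggregate_replicates(sp)
d <- envelope_difference(agg_wt, agg_sp)
lr <- log2_ratio(agg_wt, agg_sp, wt, sp, c_min = 5)
track <- data.frame(pos = seq_len(L), envelope_diff = round(d, 3),
                    log2_ratio = round(lr$ratio, 4), masked = lr$mask)
write.table(track[track$envelope_diff != 0 | !track$masked, ],
            "results/comparison_track_wt_superpol.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "Envelope difference nonzero at %d positions (%d above, %d below); %d/%d positions unmasked for the log2 ratio",
  sum(d != 0), sum(d > 0), sum(d < 0), sum(!lr$mask), L))

shift <- cdf_shift(cdf_profile(wt), cdf_profile(sp))
cdf_tab <- data.frame(metric = c("delta_median_nt", "signed_area"),
                      value = c(shift$delta_median, shift$signed_area))
write.table(cdf_tab, "results/cdf_shift_wt_superpol.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "CDF shift: WT median position - SuperPol median position = %d nt; signed area (WT - SuperPol) = %.4f (positive: SuperPol lies rightward, i.e. less 5'-proximal accumulation)",
  shift$delta_median, shift$signed_area))

## WT vs WT + BMH-21 -------------------------------------------------------
u <- load_cond("wt_bmh21")   # treated
untr <- wt[1:2]              # untreated duplicates, matching the drug design
lr2 <- log2_ratio(aggregate_replicates(untr), aggregate_replicates(u),
                  untr, u, c_min = 5)
peak <- which.max(abs(lr2$ratio))
message(sprintf(
  "BMH-21: max |log2 ratio| = %.2f at position %d (%s the 5'ETS pause cluster)",
  max(abs(lr2$ratio), na.rm = TRUE), peak,
  if (peak %in% ets_pause_cluster()) "inside" else "outside"))
write.table(data.frame(metric = c("peak_position", "peak_abs_log2_ratio",
                                  "peak_in_ets_cluster"),
                       value = c(peak, max(abs(lr2$ratio), na.rm = TRUE),
                                 as.integer(peak %in% ets_pause_cluster()))),
            "results/bmh21_localization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Wrote results/region_stats_wt_superpol.tsv, ",
        "results/comparison_track_wt_superpol.tsv, ",
        "results/cdf_shift_wt_superpol.tsv, results/bmh21_localization.tsv")
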