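#!/usr/bin/env Rscript
# Step 1 — simulate the four packaged conditions.
#
# Builds the WT, SuperPol and +BMH-21 pause/termination models, prints their
# closed-form expectations, and simulates CRAC-like read tables (with UMIs
# and PCR duplicates), abortive-transcript spectra and slot-blot probe
# intensity tables. Bulky read tables go to scratch/sim/ (regenerated on
# demand); small summary tables go to results/.

suppressPackageStartupMessages(library(polterm))
set.seed(20260924)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

ann <- default_annotation()
models <- list(wt = preset_model("wt"), superpol = preset_model("superpol"),
               wt_bmh21 = preset_model("wt_bmh21"),
               superpol_bmh21 = preset_model("superpol_bmh21"))

message("Closed-form expectations:")
ss <- lapply(models, steady_state)
for (cond in names(ss)) {
  message(sprintf("  %-15s full-length rate %.4f   5'ETS occupancy share %.3f",
                  cond, ss[[cond]]$full_length_rate,
                  region_occupancy(ss[[cond]], ann, "5'ETS") / sum(ss[[cond]]$O)))
}
message(sprintf("  SuperPol/WT full-length ratio: %.3f (calibrated)",
                ss$superpol$full_length_rate / ss$wt$full_length_rate))

# CRAC read tables: triplicates for WT/SuperPol, duplicates for the drug pair
cfg3 <- preset_config()
cfg2 <- preset_config(n_replicates = 2)
reads_main <- simulate_crac_experiment(models[c("wt", "superpol")], cfg3)
write_reads(reads_main, "scratch/sim/reads_wt_superpol.tsv")
reads_bmh <- simulate_crac_experiment(models[c("wt", "wt_bmh21")], cfg2)
write_reads(reads_bmh, "scratch/sim/reads_bmh21.tsv")
message(sprintf("Simulated %d + %d reads (PCR duplicates included)",
                nrow(reads_main), nrow(reads_bmh)))

# abortive-transcript spectra (needs the molecule outcomes, not the reads)
spectra <- lapply(models[c("wt", "superpol")], function(m)
  emit_abortive_spectrum(simulate_molecules(m, cfg3$n_molecules)))
spec_tab <- do.call(rbind, lapply(names(spectra), function(cond) {
  sp <- spectra[[cond]]
  data.frame(condition = cond, length = sp$length, count = sp$count)
}))
write.table(spec_tab, "results/abortive_spectra.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (cond in names(spectra)) {
  sp <- spectra[[cond]]
  message(sprintf(
    "  %s: %d abortive / %d molecules; %.0f%% of abortive lengths <= 300 nt",
    cond, sum(sp$count), attr(sp, "n_molecules"),
    100 * sum(sp$count[sp$length <= 300]) / sum(sp$count)))
}

# slot-blot style probe intensities at 10% CV, triplicate
cat5 <- default_probe_catalog()
probe_tab <- do.call(rbind, lapply(names(models), function(cond)
  emit_probe_signals(models[[cond]], cat5, noise_cv = 0.1, condition = cond)))
write.table(probe_tab, "results/probe_intensities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Wrote scratch/sim/reads_*.tsv, results/abortive_spectra.tsv, ",
        "results/probe_intensities.tsv")
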