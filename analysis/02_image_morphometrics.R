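#!/usr/bin/env Rscript
# Single-cell morphometrics recovery experiment: generate wild-type and
# scaffold-null image sets (3 replicate seeds, >= 100 cells/condition),
# run segmentation + measurement blind, and compare the recovered
# condition effects with the generating profiles.

suppressMessages(library(hippoquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

wt <- read_profile(hq_fixture("profiles", "wt.yaml"))
ko <- read_profile(hq_fixture("profiles", "ksr1_null.yaml"))

all_cells <- list()
for (r in 1:3) {
  set <- generate_condition_set(list(wt, ko), n_images = 4,
                                seed = seed * 100 + r)
  cells <- quantify_condition_set(set)
  cells$replicate_seed <- r
  all_cells[[r]] <- cells
}
cells <- do.call(rbind, all_cells)
write_tsv(cells[, setdiff(names(cells), "fiber_lengths")],
          "results/cells.tsv")
message("measured ", nrow(cells), " cells (",
        sum(cells$condition == "WT"), " WT, ",
        sum(cells$condition == "KSR1_null"), " null)")

metrics <- c("mean_nuc_intensity", "nuclear_area", "eccentricity_ratio",
             "nuclear_displacement", "pct_fiber_area", "mean_fiber_length")
eff <- do.call(rbind, lapply(metrics, function(m) {
  e <- estimate_effect(cells[cells$condition == "WT", ],
                       cells[cells$condition == "KSR1_null", ], m)
  data.frame(metric = m, mean_wt = e$mean_ref, mean_null = e$mean_alt,
             percent_change = e$percent_change, p_value = e$p_value)
}))
write_tsv(eff, "results/image_effects.tsv")
print(eff, digits = 3)
message(sprintf(
  "nuclear protein intensity changes by %.1f%% in the scaffold-null condition (generating profiles encode -38%%)",
  eff$percent_change[eff$metric == "mean_nuc_intensity"]))
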