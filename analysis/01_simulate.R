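#!/usr/bin/env Rscript
# Generate one example of every synthetic input the pipeline consumes and
# archive them under results/simulated/: three-channel images (multi-page
# TIFF + ground-truth sidecar), qPCR CT tables, an RPPA table, the signed
# network edge list, and mass-photometry event lists.

suppressMessages(library(hippoquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("== simulating with seed ", seed)

# images: one wild-type and one scaffold-null field of view
for (prof in c("wt", "ksr1_null")) {
  p <- read_profile(hq_fixture("profiles", paste0(prof, ".yaml")))
  g <- generate_cell_image(p, c(512, 512), seed = seed)
  write_cell_image(g, file.path(out, prof))
  message("  image ", prof, ": ", nrow(g$truth$cells), " cells")
}

# qPCR CT tables for the five packaged designs
for (fx in c("mef_ko_cyr61", "mef_ko_ctgf", "mef_oe_yap", "mef_ko_yap",
             "mcf7_kd_yap")) {
  des <- read_ct_design(hq_fixture("qpcr", paste0(fx, ".yaml")))
  write_tsv(generate_ct_table(des, seed = seed),
            file.path(out, paste0("ct_", fx, ".tsv")))
}
message("  wrote 5 CT tables")

# RPPA table with ten planted two-fold effects
rt <- generate_rppa_table(50, 3,
                          planted = c(STK4 = 2.5, LATS1 = -2.2, CCN1 = 2.1,
                                      CCN2 = -2.4, AMOT = 2.2, PXN = 2.3,
                                      RHOA = 2.05, CTNNB1 = -2.1,
                                      MAPK1 = 2.15, TP53BP1 = -2.6),
                          noise_sd = 0.1, seed = seed)
tab <- data.frame(protein = rownames(rt$values), rt$values)
write_tsv(tab, file.path(out, "rppa_log2.tsv"))
writeLines(paste(colnames(rt$values), rt$groups, sep = "\t"),
           file.path(out, "rppa_groups.tsv"))
message("  wrote RPPA table (", nrow(rt$values), " proteins)")

# the packaged signed network, copied alongside the simulated inputs
file.copy(hq_fixture("network", "toy_signor.tsv"),
          file.path(out, "signor_edges.tsv"), overwrite = TRUE)

# mass photometry: two single-protein samples and a mixture with a
# 30% bound complex at the summed mass
specs <- list(
  mass_a = data.frame(name = "A", mass = 102, fraction = 1),
  mass_b = data.frame(name = "B", mass = 120, fraction = 1),
  mass_mix = data.frame(name = c("A", "B", "A:B"), mass = c(102, 120, 222),
                        fraction = c(0.35, 0.35, 0.3))
)
for (nm in names(specs)) {
  ev <- generate_mass_events(mass_design(specs[[nm]], n_events = 3000,
                                         mass_sd = 8), seed = seed)
  write_tsv(ev$events, file.path(out, paste0(nm, ".csv")))
}
message("  wrote 3 mass-event lists")
message("done: ", out)
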