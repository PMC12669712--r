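#!/usr/bin/env Rscript
# RPPA differential ranking feeding signed-network route scoring: filter
# proteins by |fold| >= 2 and p < 0.05, rank by |log2FC|, then score every
# directed route from the scaffold kinase KSR1 to YAP1 in the packaged
# signed network against the ranked list and identify the hub.

suppressMessages(library(hippoquant))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

planted <- c(STK4 = 2.5, LATS1 = -2.2, CCN1 = 2.1, CCN2 = -2.4, AMOT = 2.2,
             PXN = 2.3, RHOA = 2.05, CTNNB1 = -2.1, MAPK1 = 2.15,
             TP53BP1 = -2.6)
rt <- generate_rppa_table(50, 3, planted = planted, noise_sd = 0.1,
                          seed = seed)
rr <- rppa_filter_rank(rt, top_n = 100)
write_tsv(rr$ranked, "results/rppa_ranked.tsv")
message(length(rr$differential), " of 50 proteins pass the +/-2-fold, p<0.05 filter; ",
        "top-ranked: ", paste(head(rr$ranked$protein, 3), collapse = ", "))

g <- read_signor(hq_fixture("network", "toy_signor.tsv"))
routes <- enumerate_routes(g, "KSR1", "YAP1", max_len = 4)
scores <- lapply(routes, score_route, graph = g, ranked = rr$ranked)
rk <- rank_routes_identify_hub(routes, scores, top_k = 5)
write_tsv(rk$ranked, "results/routes.tsv")
print(rk$ranked)
message("hub node(s) among top routes: ", paste(rk$hubs, collapse = ", "))
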