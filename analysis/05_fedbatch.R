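#!/usr/bin/env Rscript
# Protein production in fed-batch: with the reactor glucose held constant
# the cultures settle into exponential growth; the rate of increase of H is
# the productivity index, the instantaneous yield the efficiency index.
# Writes results/fedbatch/.

library(coculture)

out_dir <- "results/fedbatch"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

pp <- default_params(Y_h = 0.2)
run_c <- fedbatch_run(pp$producer, pp$cleaner, G_held = 20)
run_p <- fedbatch_run(pp$producer, NULL, G_held = 20)
write_trajectory_csv(run_c$traj, file.path(out_dir, "consortium_G20.csv"))
write_trajectory_csv(run_p$traj, file.path(out_dir, "producer_G20.csv"))

fb <- fedbatch_performance(run_c$stats, run_p$stats)
jsonlite::write_json(fb, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("Rate of increase of H: consortium %.3f 1/h vs producer alone %.3f 1/h.\n",
            fb$dlogH_consortium, fb$dlogH_producer))
cat(sprintf("Exponential-regime yield: consortium %.4f vs producer alone %.4f.\n",
            fb$yield_consortium, fb$yield_producer))
cat(sprintf("Product fraction H/B_totP locks to Y_h = %.3f in both runs.\n",
            run_c$stats$H_over_BtotP))
cat("As in chemostat, the consortium is faster but less substrate-efficient.\n")
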