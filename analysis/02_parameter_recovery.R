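#!/usr/bin/env Rscript
# Parameter-recovery study on the reduced 4-source chain: plant a +0.7
# log-scaling on the ITG->SPL condition modulation, invert 20 independent
# noisy subjects at 10 dB SNR, and report credible-interval coverage and
# sign accuracy of the posterior.

suppressPackageStartupMessages(library(dcmerp))
dir.create("results", showWarnings = FALSE)

rec <- recovery_benchmark(n_seeds = 20, b_true = 0.7, snr_db = 10, seed = 1)
write.csv(rec$fits, "results/parameter_recovery.csv", row.names = FALSE)
cat(sprintf("planted +0.7 on B(ITG->SPL): 90%% CI coverage %.2f, sign accuracy %.2f, mean posterior SD %.3f\n",
            rec$coverage, rec$sign_accuracy, rec$posterior_sd))
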