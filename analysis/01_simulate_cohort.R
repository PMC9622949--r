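#!/usr/bin/env Rscript
# Simulate the synthetic MSIT cohort (34 controls, 15 patients in two
# subtypes) and summarise its evoked responses: class/subtype layout,
# per-channel Positive Potential condition tests, and a down-sampled ERP
# excerpt for plotting elsewhere.

suppressPackageStartupMessages(library(dcmerp))
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = 1)
cohort <- generate_cohort(cfg)
print(cohort)

write_cohort_json(cohort, "results/cohort_ground_truth.json")

summary_df <- as.data.frame(table(label = cohort$subjects$label,
                                  subtype = addNA(factor(cohort$subjects$subtype))))
summary_df <- summary_df[summary_df$Freq > 0, ]
write.csv(summary_df, "results/cohort_summary.csv", row.names = FALSE)
cat("class/subtype layout:\n"); print(summary_df)

# Positive Potential features and paired condition tests per channel
pp <- do.call(rbind, lapply(cohort$erps, extract_pp_features))
tests <- wilcoxon_condition_test(pp)
write.csv(tests, "results/wilcoxon_condition_tests.csv", row.names = FALSE)
cat(sprintf("channels with BH-adjusted p < 0.05: amplitude %d, latency %d of %d\n",
            sum(tests$p_adj[tests$feature == "amplitude"] < 0.05),
            sum(tests$p_adj[tests$feature == "latency"] < 0.05),
            length(montage_60())))

# small ERP excerpt: 2 subjects x 2 conditions, 6 channels, every 10 ms
keep_ch <- c("Cz", "F3", "F4", "AF7", "Pz", "Oz")
excerpt <- do.call(rbind, lapply(cohort$erps[c("S01_control", "S01_interference",
                                               "S35_control", "S35_interference")],
  function(e) {
    sub <- e$data[keep_ch, seq(1, ncol(e$data), by = 10)]
    data.frame(subject = e$subject, condition = e$condition,
               channel = rep(rownames(sub), each = ncol(sub)),
               time_ms = rep(seq(0, 350, by = 10), nrow(sub)),
               amplitude_uv = as.vector(t(sub)))
  }))
write.csv(excerpt, "results/example_erps.csv", row.names = FALSE)
cat("wrote results/cohort_* and results/example_erps.csv\n")
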