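#!/usr/bin/env Rscript
# Simulate RNA-seq over the synthetic SDHB-like gene at editing levels
# spanning the range seen across tissues (from near-zero background to
# heavily edited hypoxic monocytes), tally base calls per CDS position,
# and test the c.136 site against the pooled C-position background.

suppressMessages(library(cuedit))
dir.create("results", showWarnings = FALSE)

model <- synthetic_sdhb_model()
depth <- 5000
eps <- 0.0018  # per-base error; T-at-C background ~ eps/3 = 0.06%

samples <- data.frame(
  sample = c("unedited_tissue", "whole_blood_like", "monocyte_like",
             "normoxic_culture", "hypoxic_culture"),
  true_fraction = c(0, 0.017, 0.026, 0.10, 0.49))

rows <- lapply(seq_len(nrow(samples)), function(i) {
  f <- samples$true_fraction[i]
  edits <- if (f > 0) c("136" = f) else numeric(0)
  cfg <- pileup_sim_config(model, depth = depth, error_rate = eps,
                           edits = edits, read_length = 75,
                           seed = 8100 + i)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(cfg, sam)
  tal <- tally_from_alignments(sam, model)
  call <- call_editing_site(tal, model, 136)
  data.frame(sample = samples$sample[i], true_pct = 100 * f,
             site_pct = 100 * call$site_fraction,
             site_depth = call$site_depth,
             background_pct = 100 * call$background_fraction,
             chi2 = call$chi2, p_value = call$p_value,
             snp_overlap = call$snp_overlap)
})
res <- do.call(rbind, rows)
print(res, digits = 3)
write.table(format(res, digits = 4), "results/pileup_site_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "\nbackground T-at-C rate pooled over %d C positions (unedited control): %.3f%% (error model %.2f%%/3)\n",
  count_base_positions(model, "C"),
  res$background_pct[res$sample == "unedited_tissue"], 100 * eps))
cat("note: the pooled background includes the query site itself, so it\n",
    "rises slightly in heavily edited samples.\n")
cat("sites with editing above background separate at p < 0.001;",
    "the unedited control does not.\n")
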