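#!/usr/bin/env Rscript
# Stage 3: bidirectional-best-hit ortholog detection between the two
# proteomes at the study cutoffs (identity >= 30%, coverage > 70%,
# e-value < 1e-5), and a check against the planted ortholog truth.

library(protomod)

ws <- file.path("results", "workspace")
cfg <- run_config(seed = 1)
run_stage("orthologs", ws, cfg)

orth <- read_stage_tsv(file.path(ws, "orthologs.tsv"))
truth <- read_stage_tsv(file.path(ws, "truth.tsv"))
planted <- truth[truth$group == "I", ]
got <- paste(orth$id_a, orth$id_b)
want <- paste(planted$id_a, planted$id_b)
cat(sprintf("BBH orthologs: %d (planted: %d); recall %.1f%%, precision %.1f%%\n",
            nrow(orth), nrow(planted),
            100 * mean(want %in% got), 100 * mean(got %in% want)))
cat(sprintf("Identity range among orthologs: %.2f - %.2f\n",
            min(orth$identity), max(orth$identity)))
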