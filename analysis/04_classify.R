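#!/usr/bin/env Rscript
# Stage 4: SiMax scoring of every same-function pair, three-group
# classification (I: ortholog + similar structure; II: non-ortholog +
# similar structure; III: non-ortholog + different structure), and
# metabolic-module composition with dominant groups.

library(protomod)

ws <- file.path("results", "workspace")
cfg <- run_config(seed = 1)
run_stage("compare", ws, cfg)
run_stage("classify", ws, cfg)
run_stage("modules", ws, cfg)

cls <- read_stage_tsv(file.path(ws, "classification.tsv"))
truth <- read_stage_tsv(file.path(ws, "truth.tsv"))
m <- merge(cls, truth, by = c("id_a", "id_b"))
cat(sprintf("Classified %d pairs: %s\n", nrow(cls),
            paste(names(table(cls$group)), table(cls$group),
                  sep = "=", collapse = ", ")))
cat(sprintf("Planted-label agreement: %.1f%%\n",
            100 * mean(m$group.x == m$group.y)))

comp <- read_stage_tsv(file.path(ws, "module_composition.tsv"))
cat("Module dominance:\n")
print(comp[, c("module_id", "n", "frac_I", "frac_II", "frac_III", "dominant")],
      row.names = FALSE)
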