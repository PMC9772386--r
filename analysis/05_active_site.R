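#!/usr/bin/env Rscript
# Stage 5: map the active site of a predicted structure by superposing it
# onto a ligand-bearing reference (SiMax < 6 required) and collecting the
# residues with any heavy atom within 4 Angstrom of the ligand.

library(protomod)

ws <- file.path("results", "workspace")
cfg <- run_config(seed = 1)
run_stage("active-site", ws, cfg)

site <- read_stage_tsv(file.path(ws, "active_site.tsv"))
cat(sprintf("Active site: %d residues within %g Angstrom of the ligand\n",
            nrow(site), cfg$ligand_cutoff))
print(site, row.names = FALSE)
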