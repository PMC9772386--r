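# Stage runner tying the modules into the end-to-end analysis over a
# working directory of standard-format files (PDB, FASTA, TSV).

config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}

#' Write / read a TSV with an embedded config hash
#'
#' Outputs carry a `# config <hash>` comment line so reruns are
#' auditable; [read_stage_tsv()] skips comment lines.
#'
#' @param x data frame.
#' @param path file path.
#' @param config the configuration whose hash is embedded.
#' @return The path, invisibly.
#' @export
write_stage_tsv <- function(x, path, config = run_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s", config_hash(config)), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

read_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

read_structure_dir <- function(dir) {
  if (!dir.exists(dir)) stop("missing input: ", dir)
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  out <- lapply(files, function(f)
    read_pdb(f, id = sub("\\.pdb$", "", basename(f))))
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

write_structure_dir <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in structures) write_pdb(s, file.path(dir, paste0(s$id, ".pdb")))
  invisible(dir)
}

#' Run a named pipeline stage
#'
#' Executes one stage of the analysis over a working directory,
#' reading the standard-format artifacts earlier stages wrote there and
#' writing its own. Stages: `simulate` (generate the demo proteome pair,
#' enzyme family, ligand reference and elastic scans), `features`,
#' `orthologs`, `compare`, `classify`, `modules`, `active-site`,
#' `cluster`, `resilience`. Outputs embed the configuration hash, and
#' reruns with the same config and inputs reproduce them byte for byte.
#'
#' @param stage stage name (see above).
#' @param dir working directory for inputs and outputs.
#' @param config a [run_config()] list; `config$seed` seeds `simulate`.
#' @param sasa_sample number of proteins per proteome given the full
#'   SASA/RSA treatment in the `features` stage (the remaining columns
#'   are computed for all proteins).
#' @param plan proteome-pair plan used by the `simulate` stage.
#' @return Invisible character vector of paths written.
#' @export
run_stage <- function(stage, dir, config = run_config(), sasa_sample = 40,
                      plan = demo_pair_plan()) {
  stages <- c("simulate", "features", "orthologs", "compare", "classify",
              "modules", "active-site", "cluster", "resilience")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    "simulate" = stage_simulate(dir, config, plan),
    "features" = stage_features(dir, config, sasa_sample),
    "orthologs" = stage_orthologs(dir, config),
    "compare" = stage_compare(dir, config),
    "classify" = stage_classify(dir, config),
    "modules" = stage_modules(dir, config),
    "active-site" = stage_active_site(dir, config),
    "cluster" = stage_cluster(dir, config),
    "resilience" = stage_resilience(dir, config))
  invisible(out)
}

stage_simulate <- function(dir, config, plan = demo_pair_plan()) {
  sim <- synth_proteome_pair(plan, seed = config$seed)
  write_structure_dir(sim$proteome_a, file.path(dir, "structures_a"))
  write_structure_dir(sim$proteome_b, file.path(dir, "structures_b"))
  write_fasta(sim$sequences_a, file.path(dir, "proteome_a.fasta"))
  write_fasta(sim$sequences_b, file.path(dir, "proteome_b.fasta"))
  write_stage_tsv(sim$annotations, file.path(dir, "annotations.tsv"), config)
  write_stage_tsv(sim$truth, file.path(dir, "truth.tsv"), config)

  fam <- synth_enzyme_family(seed = config$seed + 1)
  write_structure_dir(fam$structures, file.path(dir, "family"))
  write_stage_tsv(data.frame(id = names(fam$taxa), taxon = unname(fam$taxa),
                             fold = unname(fam$fold)),
                  file.path(dir, "family_taxa.tsv"), config)

  # ligand-bearing reference for the first group I pair's target
  tgt <- sim$proteome_a[[sim$truth$id_a[1]]]
  ref <- synth_reference_with_ligand(
    ideal_fold("helix", n_residues(tgt), tgt$sequence, tgt$id),
    site_residues = 10:14, seed = config$seed + 2)
  write_pdb(ref, file.path(dir, "reference.pdb"))
  writeLines(tgt$id, file.path(dir, "active_site_target.txt"))

  cond <- demo_scan_conditions()
  scans <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    sc <- synth_elastic_scan(cond$msd_intercept[i], cond$msd_slope[i],
                             temperatures = seq(cond$t_min[i], cond$t_max[i],
                                                by = 3),
                             noise = 0.001, seed = config$seed + 10 + i)
    sc$sample <- cond$sample[i]
    sc
  }))
  write_stage_tsv(scans, file.path(dir, "elastic_scans.tsv"), config)
  c(file.path(dir, c("structures_a", "structures_b", "proteome_a.fasta",
                     "proteome_b.fasta", "annotations.tsv", "truth.tsv",
                     "family", "family_taxa.tsv", "reference.pdb",
                     "elastic_scans.tsv")))
}

stage_features <- function(dir, config, sasa_sample) {
  paths <- character(0)
  for (side in c("a", "b")) {
    prot <- read_structure_dir(file.path(dir, paste0("structures_", side)))
    tab <- feature_table(prot, config, sasa = FALSE)
    sub <- head(prot, sasa_sample)
    sub_tab <- feature_table(sub, config, sasa = TRUE)
    tab$sasa <- sub_tab$sasa[match(tab$id, sub_tab$id)]
    tab$mol_surface <- sub_tab$mol_surface[match(tab$id, sub_tab$id)]
    tab$rsa <- sub_tab$rsa[match(tab$id, sub_tab$id)]
    p <- file.path(dir, sprintf("features_%s.tsv", side))
    write_stage_tsv(tab, p, config)
    paths <- c(paths, p)
  }
  fa <- read_stage_tsv(file.path(dir, "features_a.tsv"))
  fb <- read_stage_tsv(file.path(dir, "features_b.tsv"))
  cmp <- rbind(
    data.frame(feature = "hbonds_per_res",
               p_value = rank_sum_test(fa$hbonds_per_res,
                                       fb$hbonds_per_res)$p_value),
    data.frame(feature = "rsa",
               p_value = rank_sum_test(fa$rsa[!is.na(fa$rsa)],
                                       fb$rsa[!is.na(fb$rsa)])$p_value))
  p <- file.path(dir, "feature_comparison.tsv")
  write_stage_tsv(cmp, p, config)
  c(paths, p)
}

stage_orthologs <- function(dir, config) {
  sa <- read_fasta(file.path(dir, "proteome_a.fasta"))
  sb <- read_fasta(file.path(dir, "proteome_b.fasta"))
  tab <- bbh_orthologs(sa, sb, config)
  write_stage_tsv(tab, file.path(dir, "orthologs.tsv"), config)
  file.path(dir, "orthologs.tsv")
}

stage_compare <- function(dir, config) {
  pa <- read_structure_dir(file.path(dir, "structures_a"))
  pb <- read_structure_dir(file.path(dir, "structures_b"))
  ann <- read_stage_tsv(file.path(dir, "annotations.tsv"))
  fp <- build_function_pairs(ann[ann$taxon == "A", ], ann[ann$taxon == "B", ],
                             pa, pb, config = config)
  write_stage_tsv(fp$pairs, file.path(dir, "pair_scores.tsv"), config)
  file.path(dir, "pair_scores.tsv")
}

stage_classify <- function(dir, config) {
  pairs <- read_stage_tsv(file.path(dir, "pair_scores.tsv"))
  orth <- read_stage_tsv(file.path(dir, "orthologs.tsv"))
  cls <- classify_pairs(pairs, orth, config$simax_similar)
  write_stage_tsv(cls, file.path(dir, "classification.tsv"), config)
  file.path(dir, "classification.tsv")
}

stage_modules <- function(dir, config) {
  cls <- read_stage_tsv(file.path(dir, "classification.tsv"))
  comp <- module_composition(cls)
  write_stage_tsv(comp, file.path(dir, "module_composition.tsv"), config)
  file.path(dir, "module_composition.tsv")
}

stage_active_site <- function(dir, config) {
  ref <- read_pdb(file.path(dir, "reference.pdb"), id = "reference")
  tgt_id <- readLines(file.path(dir, "active_site_target.txt"))[1]
  pa <- read_structure_dir(file.path(dir, "structures_a"))
  sel <- select_reference(pa[[tgt_id]], list(reference = ref),
                          config$simax_similar)
  site <- map_active_site(pa[[tgt_id]], sel$reference, config$ligand_cutoff)
  write_stage_tsv(as.data.frame(site), file.path(dir, "active_site.tsv"),
                  config)
  file.path(dir, "active_site.tsv")
}

stage_cluster <- function(dir, config) {
  fam <- read_structure_dir(file.path(dir, "family"))
  taxa_tab <- read_stage_tsv(file.path(dir, "family_taxa.tsv"))
  taxa <- setNames(taxa_tab$taxon, taxa_tab$id)
  mats <- pairwise_matrices(fam)
  hc <- hcluster(mats$simax, "simax")
  cc <- cut_and_concord(hc, 2, taxa)
  writeLines(dendrogram_newick(hc), file.path(dir, "family_simax.nwk"))
  assign_tab <- data.frame(id = names(cc$clusters),
                           cluster = unname(cc$clusters),
                           taxon = unname(taxa[names(cc$clusters)]))
  write_stage_tsv(assign_tab, file.path(dir, "family_clusters.tsv"), config)
  write_stage_tsv(cc$concordance, file.path(dir, "family_concordance.tsv"),
                  config)
  file.path(dir, c("family_simax.nwk", "family_clusters.tsv",
                   "family_concordance.tsv"))
}

stage_resilience <- function(dir, config) {
  scans <- read_stage_tsv(file.path(dir, "elastic_scans.tsv"))
  rows <- lapply(split(scans, scans$sample), function(sc) {
    m <- msd_from_scan(sc, config$q_range)
    fit <- fit_resilience(m, constant = config$force_constant)
    data.frame(sample = sc$sample[1], k_prime = fit$k_prime,
               k_error = fit$k_error, slope = fit$slope,
               t_min = fit$t_range[1], t_max = fit$t_range[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_stage_tsv(out, file.path(dir, "resilience.tsv"), config)
  file.path(dir, "resilience.tsv")
}
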