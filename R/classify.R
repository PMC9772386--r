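# Three-group classification of same/similar-function protein pairs and
# metabolic-module composition.

#' Build candidate same/similar-function pairs between two proteomes
#'
#' Pairs proteins of A and B sharing a function label, plus any declared
#' similar-function links (same reaction, different cofactor). One-to-many
#' matches are resolved by the lowest SiMax; alternates are reported in
#' the `alternates` element. A protein carrying a module id but no
#' function label is an error.
#'
#' @param annot_a,annot_b annotation data frames with columns
#'   `protein_id`, `function_label`, optional `ec`, `module_id`.
#' @param structures_a,structures_b named lists of `protein_structure`
#'   used to score candidate pairs.
#' @param links optional data frame (`label_a`, `label_b`) declaring
#'   similar-function label pairs.
#' @param config a [run_config()] list.
#' @return List with `pairs` (data frame `id_a`, `id_b`,
#'   `function_label`, `module_id`, `simax`, `rmsd`, `n_mat`, `L1`, `L2`,
#'   `identity`), `unmatched_a`, `unmatched_b`, `alternates`.
#' @export
build_function_pairs <- function(annot_a, annot_b, structures_a, structures_b,
                                 links = NULL, config = run_config()) {
  check <- function(an) {
    bad <- !is.na(an$module_id) & (is.na(an$function_label) |
                                     !nzchar(an$function_label))
    if (any(bad))
      stop(sprintf("protein %s has a module but no function label",
                   an$protein_id[which(bad)[1]]))
  }
  check(annot_a); check(annot_b)
  cand <- merge(annot_a[, c("protein_id", "function_label", "module_id")],
                annot_b[, c("protein_id", "function_label", "module_id")],
                by = "function_label", suffixes = c("_a", "_b"))
  if (!is.null(links) && nrow(links)) {
    la <- merge(annot_a[, c("protein_id", "function_label", "module_id")],
                links, by.x = "function_label", by.y = "label_a")
    lb <- merge(la, annot_b[, c("protein_id", "function_label", "module_id")],
                by.x = "label_b", by.y = "function_label",
                suffixes = c("_a", "_b"))
    if (nrow(lb)) {
      lb$function_label <- paste(lb$function_label, lb$label_b, sep = "~")
      cand <- rbind(cand, lb[, names(cand)])
    }
  }
  if (!nrow(cand))
    return(list(pairs = data.frame(), unmatched_a = annot_a$protein_id,
                unmatched_b = annot_b$protein_id, alternates = data.frame()))
  scored <- lapply(seq_len(nrow(cand)), function(i) {
    sc <- compare_structures(structures_a[[cand$protein_id_a[i]]],
                             structures_b[[cand$protein_id_b[i]]],
                             simax_cutoff = config$simax_similar,
                             gap_open = config$gap_open,
                             gap_extend = config$gap_extend)
    data.frame(id_a = cand$protein_id_a[i], id_b = cand$protein_id_b[i],
               function_label = cand$function_label[i],
               module_id = cand$module_id_a[i],
               simax = sc$simax, rmsd = sc$rmsd, n_mat = sc$n_mat,
               L1 = sc$L1, L2 = sc$L2, identity = sc$identity,
               stringsAsFactors = FALSE)
  })
  scored <- do.call(rbind, scored)
  # best-SiMax resolution of one-to-many function matches
  scored <- scored[order(scored$simax), ]
  dup_a <- duplicated(scored$id_a); dup_b <- duplicated(scored$id_b)
  keep <- !(dup_a | dup_b)
  alternates <- scored[!keep, , drop = FALSE]
  pairs <- scored[keep, , drop = FALSE]
  pairs <- pairs[order(pairs$id_a), ]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_a = setdiff(annot_a$protein_id, pairs$id_a),
       unmatched_b = setdiff(annot_b$protein_id, pairs$id_b),
       alternates = alternates)
}

#' Classify a function pair into group I/II/III
#'
#' Group I: ortholog with similar structure (SiMax < cutoff); group II:
#' non-ortholog with similar structure; group III: non-ortholog with
#' different structure. The undefined ortholog-with-different-structure
#' combination is flagged anomalous and reported as III with a warning.
#'
#' @param is_ortholog logical vector.
#' @param simax numeric vector, Angstrom.
#' @param cutoff structural-similarity threshold (default 6).
#' @return Character vector of groups with attribute `anomalous`
#'   (logical).
#' @export
classify_pair <- function(is_ortholog, simax, cutoff = 6) {
  if (any(!is.finite(simax))) stop("simax must be finite")
  group <- ifelse(simax < cutoff, ifelse(is_ortholog, "I", "II"), "III")
  anomalous <- is_ortholog & simax >= cutoff
  if (any(anomalous))
    warning(sprintf("%d ortholog pair(s) with SiMax >= %g flagged anomalous",
                    sum(anomalous), cutoff))
  attr(group, "anomalous") <- anomalous
  group
}

#' Classify a table of function pairs
#'
#' @param pairs data frame from [build_function_pairs()]`$pairs`.
#' @param orthologs ortholog table from [bbh_orthologs()].
#' @param cutoff structural-similarity threshold, Angstrom.
#' @return `pairs` with added `is_ortholog`, `group`, `anomalous` columns.
#' @export
classify_pairs <- function(pairs, orthologs, cutoff = 6) {
  key <- paste(pairs$id_a, pairs$id_b)
  okey <- if (nrow(orthologs)) paste(orthologs$id_a, orthologs$id_b)
          else character(0)
  pairs$is_ortholog <- key %in% okey
  g <- classify_pair(pairs$is_ortholog, pairs$simax, cutoff)
  pairs$group <- as.character(g)
  pairs$anomalous <- attr(g, "anomalous")
  pairs
}

#' Metabolic-module composition by group
#'
#' Per-module counts and fractions of group I/II/III pairs; the dominant
#' group is the plurality, with ties reported as no dominant group.
#'
#' @param classified data frame from [classify_pairs()] (columns
#'   `module_id`, `group`); pairs without a module are pooled under
#'   `"unassigned"`.
#' @return Data frame: `module_id`, `n`, `n_I`, `n_II`, `n_III`,
#'   `frac_I`, `frac_II`, `frac_III`, `dominant` (NA on ties).
#' @export
module_composition <- function(classified) {
  mod <- classified$module_id
  mod[is.na(mod) | !nzchar(mod)] <- "unassigned"
  tab <- table(mod, factor(classified$group, levels = c("I", "II", "III")))
  n <- rowSums(tab)
  frac <- tab / n
  dominant <- apply(tab, 1, function(x) {
    top <- which(x == max(x))
    if (length(top) > 1) NA_character_ else c("I", "II", "III")[top]
  })
  data.frame(module_id = rownames(tab), n = as.integer(n),
             n_I = as.integer(tab[, "I"]), n_II = as.integer(tab[, "II"]),
             n_III = as.integer(tab[, "III"]),
             frac_I = as.numeric(frac[, "I"]),
             frac_II = as.numeric(frac[, "II"]),
             frac_III = as.numeric(frac[, "III"]),
             dominant = unname(dominant),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classification stability across prediction replicates
#'
#' A pair is unstable when its group label changes across replicate SiMax
#' values (the SiMax crossing the similarity threshold between replicate
#' structure predictions).
#'
#' @param simax_replicates numeric matrix (pairs x replicates) or list of
#'   per-pair replicate vectors (>= 2 replicates each).
#' @param is_ortholog logical vector per pair.
#' @param cutoff structural-similarity threshold, Angstrom.
#' @return Data frame with `stable`, `groups` (comma-joined distinct
#'   labels per pair).
#' @export
classification_stability <- function(simax_replicates, is_ortholog,
                                     cutoff = 6) {
  if (is.matrix(simax_replicates))
    simax_replicates <- split(simax_replicates, row(simax_replicates))
  if (any(lengths(simax_replicates) < 2))
    stop("need at least 2 replicates per pair")
  res <- mapply(function(sims, orth) {
    g <- suppressWarnings(
      vapply(sims, function(s) classify_pair(orth, s, cutoff)[1], ""))
    c(stable = length(unique(g)) == 1,
      groups = paste(sort(unique(g)), collapse = ","))
  }, simax_replicates, is_ortholog)
  data.frame(stable = as.logical(res["stable", ]),
             groups = unname(res["groups", ]), stringsAsFactors = FALSE)
}
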