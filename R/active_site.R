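# Active-site mapping: superpose a predicted structure onto a
# ligand-bearing reference and collect residues within the ligand shell.

LIGAND_EXCLUDE <- c("HOH", "NA", "CL", "SO4")

ligand_coords <- function(reference, exclude = LIGAND_EXCLUDE) {
  lig <- reference$ligands
  lig <- lig[!(lig$resname %in% exclude) & lig$element != "H", , drop = FALSE]
  if (!nrow(lig)) stop("reference has no usable ligand atoms")
  as.matrix(lig[, c("x", "y", "z")])
}

#' Select a ligand-bearing reference structure
#'
#' Among candidate references with a bound ligand, returns the one with
#' the smallest SiMax to the target, requiring SiMax < `cutoff`.
#'
#' @param target a `protein_structure`.
#' @param candidates named list of ligand-bearing `protein_structure`.
#' @param cutoff usable-reference SiMax threshold (default 6 Angstrom).
#' @return List with `reference`, `id`, `simax`.
#' @export
select_reference <- function(target, candidates, cutoff = 6) {
  if (!length(candidates)) stop("no candidate references")
  sims <- vapply(candidates, function(r) {
    ligand_coords(r)  # every candidate must carry a ligand
    compare_structures(target, r)$simax
  }, 0)
  usable <- sims < cutoff
  if (!any(usable))
    stop("no usable reference: all candidates have SiMax >= ", cutoff)
  best <- which.min(ifelse(usable, sims, Inf))
  list(reference = candidates[[best]],
       id = names(candidates)[best] %||% best, simax = sims[best])
}

#' Map active-site residues by ligand proximity
#'
#' Superposes the target onto the reference (sequence-guided match with
#' iterative trimming) and reports every target residue with any heavy
#' atom within `cutoff` of any reference ligand heavy atom, measured in
#' the reference frame. Waters and common buffer ions are excluded from
#' the ligand.
#'
#' @param target a `protein_structure`.
#' @param reference a ligand-bearing `protein_structure` with
#'   SiMax(target, reference) below the similarity threshold.
#' @param cutoff ligand shell radius, Angstrom (default 4).
#' @param exclude hetero codes never treated as ligand.
#' @return Data frame of class `active_site`: `resno`, `name3`,
#'   `min_dist`, sorted by `resno`; attributes `target_id`,
#'   `reference_id`, `cutoff`.
#' @export
map_active_site <- function(target, reference, cutoff = 4,
                            exclude = LIGAND_EXCLUDE) {
  lig <- ligand_coords(reference, exclude)
  m <- sequence_guided_match(reference, target)
  tr <- iterative_trim(m$ca_a, m$ca_b)
  heavy <- target$atoms[target$atoms$element != "H", , drop = FALSE]
  xyz <- apply_transform(as.matrix(heavy[, c("x", "y", "z")]), tr$fit)
  d <- pair_dist(xyz, lig)
  min_by_atom <- apply(d, 1, min)
  min_by_res <- tapply(min_by_atom, heavy$resno, min)
  resno <- as.numeric(names(min_by_res))
  hit <- min_by_res <= cutoff
  out <- data.frame(resno = resno[hit],
                    name3 = target$residues$name3[
                      match(resno[hit], target$residues$resno)],
                    min_dist = as.numeric(min_by_res[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$resno), ]
  rownames(out) <- NULL
  attr(out, "target_id") <- target$id
  attr(out, "reference_id") <- reference$id
  attr(out, "cutoff") <- cutoff
  class(out) <- c("active_site", class(out))
  out
}

#' Compare two active sites
#'
#' Uses the sequence-guided correspondence between the two structures to
#' pair site residues, reports the fraction with identical amino-acid
#' type, and the per-residue CA deviation after a superposition
#' restricted to the corresponding site residues (local frame).
#'
#' @param site_a,site_b `active_site` tables from [map_active_site()].
#' @param struct_a,struct_b the parent `protein_structure` objects.
#' @return List with `n_corresponding`, `conservation`, `deviations`
#'   (named by residue pair).
#' @export
compare_active_sites <- function(site_a, site_b, struct_a, struct_b) {
  if (!nrow(site_a) || !nrow(site_b)) stop("empty active site")
  m <- sequence_guided_match(struct_a, struct_b)
  ra <- struct_a$residues$resno[m$pairs[, "a"]]
  rb <- struct_b$residues$resno[m$pairs[, "b"]]
  in_site <- ra %in% site_a$resno & rb %in% site_b$resno
  if (sum(in_site) < 1) stop("no corresponding site residues")
  aa_a <- struct_a$residues$aa1[m$pairs[in_site, "a"]]
  aa_b <- struct_b$residues$aa1[m$pairs[in_site, "b"]]
  conservation <- mean(aa_a == aa_b)
  idx <- which(in_site)
  if (length(idx) >= 3) {
    fit <- kabsch_superpose(m$ca_a[idx, , drop = FALSE],
                            m$ca_b[idx, , drop = FALSE])
    dev <- fit$residuals
  } else {
    fit <- iterative_trim(m$ca_a, m$ca_b)$fit
    dev <- sqrt(rowSums((m$ca_a[idx, , drop = FALSE] -
                           apply_transform(m$ca_b[idx, , drop = FALSE],
                                           fit))^2))
  }
  list(n_corresponding = length(idx), conservation = conservation,
       deviations = setNames(dev, paste(ra[idx], rb[idx], sep = ":")))
}
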