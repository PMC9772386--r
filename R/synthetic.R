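# Seeded generators for every input the pipeline consumes: idealized
# helix/strand proteins with controlled sequence identity and coordinate
# noise, planted module/group structure, ligand-bearing references, and
# elastic scans with linear-in-temperature MSD ground truth.

# memoizes the deterministic strand-register search per strand-length pair
.fold_cache <- new.env(parent = emptyenv())

# NeRF internal-coordinate placement: returns D bonded to C with bond length
# r, angle(B,C,D) = theta and dihedral(A,B,C,D) = chi (degrees).
place_atom <- function(a, b, c, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- r * (-bc * cos(theta) + m * sin(theta) * cos(chi) -
              n * sin(theta) * sin(chi))
  c + d
}

# Dihedral angle (degrees) over four points, IUPAC sign convention.
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an idealized backbone
#'
#' Constructs N/CA/C/O (and a CB stub) from standard bond lengths and
#' angles with repeated (phi, psi) torsions: (-57, -47) degrees for an
#' alpha helix, (-139, 135) for a beta strand. Consecutive CA-CA distances
#' come out near 3.8 Angstrom and an ideal helix forms the i -> i+4
#' backbone hydrogen-bond pattern.
#'
#' @param kind `"helix"`, `"strand"`, or `"strand21"` (a strand with an
#'   exact two-fold screw repeat, used for sheet assembly).
#' @param n number of residues (at least 4).
#' @param sequence optional 1-letter sequence of length `n` (default
#'   poly-alanine).
#' @param id structure identifier.
#' @param plddt per-residue confidence written to the B-factor field;
#'   scalar or length-`n` vector.
#' @param cb add CB stubs (skipped for glycine).
#' @return A `protein_structure`.
#' @examples
#' h <- ideal_backbone("helix", 12)
#' table(assign_secondary_structure(h))
#' @export
ideal_backbone <- function(kind = c("helix", "strand", "strand21"), n,
                           sequence = NULL,
                           id = NULL, plddt = 90, cb = TRUE) {
  kind <- match.arg(kind)
  if (n < 4) stop("need at least 4 residues")
  tor <- switch(kind, helix = c(-57, -47), strand = c(-139, 135),
                strand21 = c(-129, 126))
  phi <- rep(tor[1], n); psi <- rep(tor[2], n)
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n) stop("sequence length must equal n")
  if (length(plddt) == 1) plddt <- rep(plddt, n)

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                            1.329, 116.2, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                            1.525, 111.2, phi[i])
    }
    O[i, ]  <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.521, 110.5, -122.6)
  }

  rows <- list()
  for (i in seq_len(n)) {
    name3 <- unname(AA1[aa[i]])
    if (is.na(name3)) name3 <- "UNK"
    at <- data.frame(name = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     resno = i, resname = name3,
                     x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
                     y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
                     z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
                     b = plddt[i], stringsAsFactors = FALSE)
    if (cb && aa[i] != "G")
      at <- rbind(at, data.frame(name = "CB", element = "C", resno = i,
                                 resname = name3, x = CB[i, 1], y = CB[i, 2],
                                 z = CB[i, 3], b = plddt[i],
                                 stringsAsFactors = FALSE))
    rows[[i]] <- at
  }
  atoms <- do.call(rbind, rows)
  lig <- atoms[0, , drop = FALSE]; lig$group <- character(0)
  new_protein_structure(id %||% kind, atoms, lig)
}

#' Build an idealized fold
#'
#' `"helix"` is a single alpha helix; `"hairpin"` is a two-stranded
#' antiparallel beta sheet whose strand register is chosen by a small
#' deterministic grid search maximizing inter-strand O...N contacts in the
#' hydrogen-bonding window, so the sheet ladder is detectable. The two
#' layouts serve as distinct folds for planted group III pairs.
#'
#' @inheritParams ideal_backbone
#' @param layout `"helix"` or `"hairpin"`.
#' @return A `protein_structure`.
#' @export
ideal_fold <- function(layout = c("helix", "hairpin"), n, sequence = NULL,
                       id = NULL, plddt = 90) {
  layout <- match.arg(layout)
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (layout == "helix")
    return(ideal_backbone("helix", n, sequence, id %||% "helix", plddt))
  m1 <- ceiling(n / 2); m2 <- n - m1
  if (m2 < 4) stop("hairpin needs at least 8 residues")
  aa <- strsplit(sequence, "")[[1]]
  if (length(plddt) == 1) plddt <- rep(plddt, n)
  s1 <- ideal_backbone("strand21", m1, paste(aa[1:m1], collapse = ""),
                       "s1", plddt[1:m1])
  s2 <- ideal_backbone("strand21", m2, paste(aa[(m1 + 1):n], collapse = ""),
                       "s2", plddt[(m1 + 1):n])
  # place strand 2 antiparallel to strand 1: try the two direction-reversing
  # 180-degree rotations and grid-search the translation, scoring candidate
  # placements by the number of inter-strand Kabsch-Sander hydrogen bonds
  # (mutual i<->j bonds, the antiparallel ladder signature, weighted up)
  frame_atoms <- function(s) {
    a <- s$atoms
    get <- function(nm) as.matrix(a[a$name == nm, c("x", "y", "z")])
    N <- get("N"); C <- get("C"); O <- get("O")
    m <- nrow(N)
    H <- matrix(NA_real_, m, 3)
    for (j in 2:m)
      H[j, ] <- N[j, ] + 1.01 * unit(unit(N[j, ] - C[j - 1, ]) +
                                       unit(N[j, ] - O[j - 1, ]))
    list(N = N, C = C, O = O, H = H)
  }
  ks_bonds <- function(acc, don) {
    okH <- !is.na(don$H[, 1])
    E <- 0.084 * 332 * (1 / pair_dist(acc$O, don$N[okH, , drop = FALSE]) +
                          1 / pair_dist(acc$C, don$H[okH, , drop = FALSE]) -
                          1 / pair_dist(acc$O, don$H[okH, , drop = FALSE]) -
                          1 / pair_dist(acc$C, don$N[okH, , drop = FALSE]))
    E < -0.5
  }
  f1 <- frame_atoms(s1)
  f2 <- frame_atoms(s2)
  # search translations about the configuration with both CA centroids
  # coincident, so the strands overlap along their length
  cen1 <- colMeans(coords(s1, "CA"))
  cen2 <- colMeans(coords(s2, "CA"))
  rots <- list(diag(c(-1, -1, 1)), diag(c(-1, 1, -1)))
  tf <- function(f, R, t0) lapply(f, function(m) {
    out <- m %*% t(R); sweep(out, 2, t0, "+")
  })
  score_placement <- function(R, offset) {
    t0 <- cen1 - drop(R %*% cen2) + offset
    f2t <- tf(f2, R, t0)
    # b12[i, j-1]: C=O of strand-1 residue i accepts from N-H of
    # strand-2 residue j; b21[j, i-1] is the reverse direction
    b12 <- ks_bonds(f1, f2t); b21 <- ks_bonds(f2t, f1)
    M1 <- b12[2:m1, , drop = FALSE]
    M2 <- t(b21[2:m2, , drop = FALSE])
    sum(b12) + sum(b21) + 3 * sum(M1 & M2)
  }
  cache_key <- sprintf("hairpin_%d_%d", m1, m2)
  best <- .fold_cache[[cache_key]]
  if (is.null(best)) {
    # coarse grid over both direction-reversing rotations, then local
    # refinement around the best coarse placement
    best_score <- -Inf
    for (R in rots) for (dz0 in seq(-1.5, 1.5, by = 1.0))
      for (dy0 in seq(3.8, 5.8, by = 0.2)) for (dx0 in seq(-4, 4, by = 0.5)) {
        sc <- score_placement(R, c(dx0, dy0, dz0))
        if (sc > best_score) {
          best_score <- sc; best <- list(R = R, off = c(dx0, dy0, dz0))
        }
      }
    ctr <- best$off
    for (dz0 in ctr[3] + seq(-0.5, 0.5, by = 0.25))
      for (dy0 in ctr[2] + seq(-0.15, 0.15, by = 0.05))
        for (dx0 in ctr[1] + seq(-0.4, 0.4, by = 0.1)) {
          sc <- score_placement(best$R, c(dx0, dy0, dz0))
          if (sc > best_score) {
            best_score <- sc; best$off <- c(dx0, dy0, dz0)
          }
        }
    best$t <- cen1 - drop(best$R %*% cen2) + best$off
    .fold_cache[[cache_key]] <- best
  }
  a2 <- s2$atoms
  xyz2 <- as.matrix(a2[, c("x", "y", "z")]) %*% t(best$R)
  xyz2 <- sweep(xyz2, 2, best$t, "+")
  a2$x <- xyz2[, 1]; a2$y <- xyz2[, 2]; a2$z <- xyz2[, 3]
  a2$resno <- a2$resno + m1
  atoms <- rbind(s1$atoms, a2)
  lig <- atoms[0, , drop = FALSE]; lig$group <- character(0)
  new_protein_structure(id %||% "hairpin", atoms, lig)
}

#' Uniformly random rotation matrix
#'
#' @param seed optional RNG seed.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Perturb a structure with coordinate noise and a rigid motion
#'
#' Adds isotropic Gaussian noise (standard deviation `sigma` per
#' coordinate) to every atom, then applies a rigid rotation and
#' translation. Ligand atoms are transformed along with the chain.
#'
#' @param s a `protein_structure`.
#' @param sigma noise standard deviation per coordinate, Angstrom.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 vector (default zero).
#' @param seed optional RNG seed for reproducibility.
#' @return The perturbed `protein_structure`.
#' @export
perturb_structure <- function(s, sigma = 0, rotation = NULL,
                              translation = c(0, 0, 0), seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  R <- rotation %||% diag(3)
  tf <- function(df) {
    if (!nrow(df)) return(df)
    xyz <- as.matrix(df[, c("x", "y", "z")])
    if (sigma > 0) xyz <- xyz + matrix(rnorm(length(xyz), 0, sigma), ncol = 3)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, translation, "+")
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  s$atoms <- tf(s$atoms)
  s$ligands <- tf(s$ligands)
  s
}

#' Random amino-acid sequence
#' @param n length.
#' @param seed optional RNG seed.
#' @return 1-letter string over the 20 standard residues.
#' @export
random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(AA1), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Substitutes residues at uniformly chosen positions (never to the same
#' letter) so the position-wise identity to the input is within 0.02 of
#' the target.
#'
#' @param seq 1-letter sequence.
#' @param target_identity target fraction in (0, 1].
#' @param seed optional RNG seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, target_identity, seed = NULL) {
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  k <- round((1 - target_identity) * L)
  if (abs((1 - k / L) - target_identity) > 0.02)
    stop("target identity not achievable within 0.02 on a sequence this short")
  if (k > 0) {
    pos <- sample.int(L, k)
    aa[pos] <- vapply(aa[pos], function(x)
      sample(setdiff(names(AA1), x), 1), "")
  }
  paste(aa, collapse = "")
}

#' Demonstration proteome-pair plan
#'
#' Sixteen metabolic modules totalling 137 same-function pairs, with the
#' planted dominant group of each module following the observed pattern:
#' central-metabolism and biosynthesis modules dominated by group I
#' orthologs, the glycolysis-lipid link and NAD(P)+ biosynthesis by group
#' II, up/downstream glycolysis and the pentose phosphate pathway by group
#' III, and the membrane-bound hydrogenase (MBH) mixed 5 I / 7 II — the one
#' module without a clear single dominant category. Module sizes not
#' printed in the study are this package's choice.
#'
#' @return Data frame with columns `module_id`, `module_name`, `group`,
#'   `n_pairs` (one module may span several rows).
#' @export
demo_pair_plan <- function() {
  p <- function(id, name, group, n)
    data.frame(module_id = id, module_name = name, group = group,
               n_pairs = n, stringsAsFactors = FALSE)
  rbind(
    p("M01", "middle_glycolysis",        "I",   12),
    p("M02", "partial_tca",              "I",   10),
    p("M03", "purine_biosynthesis",      "I",   12),
    p("M04", "pyrimidine_biosynthesis",  "I",   11),
    p("M05", "amino_acid_biosynthesis",  "I",   19),
    p("M06", "nicotinate_biosynthesis",  "I",    5),
    p("M07", "coa_biosynthesis",         "I",    6),
    p("M08", "glycolysis_lipid_link",    "II",   4),
    p("M09", "nadp_biosynthesis",        "II",   3),
    p("M10", "upstream_glycolysis",      "III",  5),
    p("M11", "downstream_glycolysis",    "III",  9),
    p("M12", "pentose_phosphate",        "III", 10),
    p("M13", "mbh_complex",              "I",    5),
    p("M13", "mbh_complex",              "II",   7),
    p("M14", "mbs_complex",              "I",   10),
    p("M14", "mbs_complex",              "II",   3),
    p("M15", "sh1_hydrogenase",          "I",    4),
    p("M16", "nfn2_oxidoreductase",      "I",    2)
  )
}

#' Generate a synthetic proteome pair with planted pair groups
#'
#' Emulates the statistical structure of a cross-domain proteome
#' comparison: group I pairs share a fold at ~50% sequence identity, group
#' II share a fold at ~15% identity (below the 30% ortholog cutoff), and
#' group III pairs place the two partners on distinct folds (helix vs
#' beta hairpin) at ~15% identity. Partner-B coordinates get isotropic
#' noise plus a random rigid motion; pLDDT fields are filled with
#' high-confidence values (mean 90, sd 5) unless overridden.
#'
#' @param plan plan data frame as from [demo_pair_plan()].
#' @param seed RNG seed; the plan fixes the planted structure, the seed
#'   only changes noise realizations.
#' @param length_range residue-count range proteins are drawn from.
#' @param identity_targets named identity targets per group.
#' @param sigma named coordinate-noise sd (Angstrom) per group.
#' @param plddt_mean,plddt_sd per-residue confidence distribution.
#' @return List with `proteome_a`, `proteome_b` (named lists of
#'   `protein_structure`), `sequences_a`, `sequences_b` (named character),
#'   `annotations` (protein_id, function_label, ec, module_id, taxon), and
#'   `truth` (id_a, id_b, function_label, module_id, group).
#' @export
synth_proteome_pair <- function(plan = demo_pair_plan(), seed = 1,
                                length_range = c(60, 90),
                                identity_targets = c(I = 0.5, II = 0.15, III = 0.15),
                                sigma = c(I = 1, II = 1, III = 1),
                                plddt_mean = 90, plddt_sd = 5) {
  set.seed(seed)
  rows <- plan[rep(seq_len(nrow(plan)), plan$n_pairs), ]
  n_pair <- nrow(rows)
  pa <- pb <- list(); sa <- sb <- character(0)
  ann <- truth <- list()
  clip <- function(x) pmin(100, pmax(0, x))
  for (i in seq_len(n_pair)) {
    grp <- rows$group[i]; mod <- rows$module_id[i]
    L <- sample(length_range[1]:length_range[2], 1)
    ida <- sprintf("A_%s_p%03d", mod, i)
    idb <- sprintf("B_%s_p%03d", mod, i)
    fun <- sprintf("%s_f%03d", mod, i)
    seqA <- random_sequence(L)
    seqB <- mutate_sequence(seqA, identity_targets[[grp]])
    foldA <- "helix"
    foldB <- if (grp == "III") "hairpin" else "helix"
    strA <- ideal_fold(foldA, L, seqA, ida, clip(rnorm(L, plddt_mean, plddt_sd)))
    strB <- ideal_fold(foldB, L, seqB, idb, clip(rnorm(L, plddt_mean, plddt_sd)))
    strB <- perturb_structure(strB, sigma = sigma[[grp]],
                              rotation = random_rotation(),
                              translation = runif(3, -20, 20))
    pa[[ida]] <- strA; pb[[idb]] <- strB
    sa[ida] <- seqA; sb[idb] <- seqB
    ann[[length(ann) + 1]] <- data.frame(
      protein_id = c(ida, idb), function_label = fun, ec = NA_character_,
      module_id = mod, taxon = c("A", "B"), stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      id_a = ida, id_b = idb, function_label = fun, module_id = mod,
      group = grp, stringsAsFactors = FALSE)
  }
  list(proteome_a = pa, proteome_b = pb, sequences_a = sa, sequences_b = sb,
       annotations = do.call(rbind, ann), truth = do.call(rbind, truth))
}

#' Synthetic ligand-bearing reference structure
#'
#' Copies a fold and plants a small hetero (ligand) group near the CA
#' centroid of chosen site residues, emulating a co-crystal reference
#' whose bound substrate defines the active site.
#'
#' @param fold a `protein_structure` to use as the reference fold.
#' @param site_residues residue indices the ligand is placed against.
#' @param ligand_name 3-letter hetero code (default `"SUB"`).
#' @param n_atoms number of ligand atoms.
#' @param jitter spread (Angstrom) of ligand atoms about the site centroid.
#' @param seed optional RNG seed.
#' @return The reference `protein_structure` with populated `ligands`.
#' @export
synth_reference_with_ligand <- function(fold, site_residues,
                                        ligand_name = "SUB", n_atoms = 3,
                                        jitter = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ca <- coords(fold, "CA")
  idx <- match(site_residues, fold$residues$resno)
  if (anyNA(idx)) stop("site residues not present in fold")
  cen <- colMeans(ca[idx, , drop = FALSE])
  xyz <- sweep(matrix(rnorm(3 * n_atoms, 0, jitter), ncol = 3), 2, cen, "+")
  lig <- data.frame(name = paste0("C", seq_len(n_atoms)), element = "C",
                    resno = max(fold$residues$resno) + 1,
                    resname = ligand_name,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0,
                    stringsAsFactors = FALSE)
  lig$group <- paste(ligand_name, lig$resno[1], sep = "_")
  fold$ligands <- lig
  fold$id <- paste0(fold$id, "_ref")
  fold
}

#' Synthetic two-fold enzyme family
#'
#' Builds a family whose members come from two distinct folds (helix vs
#' beta hairpin) with independently drawn sequences, so pairwise sequence
#' identities are uniformly low and uninformative while the structural
#' (SiMax) matrix carries a clean two-block signal. Taxon labels follow
#' the folds (fold 1 archaea, fold 2 bacteria).
#'
#' @param n_per_fold members per fold.
#' @param n_res residues per member.
#' @param sigma within-fold coordinate noise sd, Angstrom.
#' @param seed RNG seed.
#' @return List with `structures`, `sequences`, `taxa`, `fold` (truth).
#' @export
synth_enzyme_family <- function(n_per_fold = 13, n_res = 50, sigma = 0.5,
                                seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("arc%02d", seq_len(n_per_fold)),
           sprintf("bac%02d", seq_len(n_per_fold)))
  fold <- rep(c("helix", "hairpin"), each = n_per_fold)
  taxa <- setNames(rep(c("archaea", "bacteria"), each = n_per_fold), ids)
  structures <- list(); seqs <- character(0)
  for (i in seq_along(ids)) {
    sq <- random_sequence(n_res)
    s <- ideal_fold(fold[i], n_res, sq, ids[i])
    s <- perturb_structure(s, sigma = sigma, rotation = random_rotation(),
                           translation = runif(3, -10, 10))
    structures[[ids[i]]] <- s
    seqs[ids[i]] <- sq
  }
  list(structures = structures, sequences = seqs, taxa = taxa,
       fold = setNames(fold, ids))
}

#' Synthetic elastic neutron-scattering scan
#'
#' Generates elastic intensities from the Gaussian model
#' S(q, T) = exp(-q^2 msd(T) / 6) with msd(T) = `intercept` + `slope` * T,
#' plus multiplicative Gaussian noise. The recorded uncertainty column is
#' `noise * S`.
#'
#' @param intercept,slope linear MSD ground truth (Angstrom^2, per K).
#' @param temperatures temperature grid, K.
#' @param q q grid, 1/Angstrom.
#' @param noise relative noise level (0 for a noiseless scan).
#' @param seed optional RNG seed.
#' @return Data frame of class `elastic_scan`: `temperature`, `q`, `S`,
#'   `sigma_S`, with the ground truth in attributes `msd_intercept`,
#'   `msd_slope`.
#' @export
synth_elastic_scan <- function(intercept, slope,
                               temperatures = seq(277, 360, by = 3),
                               q = seq(0.27, 1.97, length.out = 18),
                               noise = 0, seed = NULL) {
  if (slope <= 0) stop("MSD slope must be positive")
  msd <- intercept + slope * temperatures
  if (any(msd < 0)) stop("ground-truth MSD negative on the temperature grid")
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(temperature = temperatures, q = q)
  S0 <- exp(-g$q^2 * (intercept + slope * g$temperature) / 6)
  eps <- if (noise > 0) rnorm(nrow(g), 0, noise) else 0
  out <- data.frame(temperature = g$temperature, q = g$q,
                    S = S0 * (1 + eps), sigma_S = noise * S0)
  attr(out, "msd_intercept") <- intercept
  attr(out, "msd_slope") <- slope
  class(out) <- c("elastic_scan", class(out))
  out
}

#' Study-condition elastic scans
#'
#' The three measurement conditions emulated by the generator: resilience
#' ground truths 0.78, 0.67 and 0.31 N/m over heating ranges 277-310,
#' 277-350 and 277-360 K respectively, on the 0.27-1.97 1/Angstrom q
#' grid. The MSD baseline at 277 K is 0.3 Angstrom^2.
#'
#' @return Data frame with `sample`, `k_prime`, `t_min`, `t_max`,
#'   `msd_slope`, `msd_intercept`.
#' @export
demo_scan_conditions <- function() {
  k <- c(A501 = 0.78, `3DAC` = 0.67, E.coli = 0.31)
  tmax <- c(310, 350, 360)
  slope <- 0.00276 / k
  data.frame(sample = names(k), k_prime = unname(k), t_min = 277,
             t_max = tmax, msd_slope = unname(slope),
             msd_intercept = 0.3 - unname(slope) * 277,
             stringsAsFactors = FALSE)
}
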