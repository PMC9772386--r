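# Per-protein geometric features: polar contacts, salt bridges,
# disulfides, Shrake-Rupley SASA, relative surface area, secondary
# structure, and the rank-sum comparison between proteomes.

pair_dist <- function(p, q) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
  sqrt(pmax(d2, 0))
}

#' Detect hydrogen bonds as polar contacts
#'
#' Counts unordered N/O-N/O atom pairs from different residues within the
#' polar-contact cutoff (default 3.5 Angstrom), excluding the covalent
#' peptide-neighbor pair O(i)/C(i)-N(i+1). No angle criterion is applied.
#'
#' @param s a `protein_structure`.
#' @param cutoff distance cutoff, Angstrom.
#' @return List with `count` and `pairs` (data frame of atom indices,
#'   residue numbers and distances).
#' @export
detect_hbonds <- function(s, cutoff = 3.5) {
  a <- s$atoms
  pol <- which(a$element %in% c("N", "O"))
  empty <- data.frame(resno_i = integer(0), name_i = character(0),
                      resno_j = integer(0), name_j = character(0),
                      dist = numeric(0))
  if (length(pol) < 2) return(list(count = 0L, pairs = empty))
  p <- as.matrix(a[pol, c("x", "y", "z")])
  d <- pair_dist(p, p)
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(list(count = 0L, pairs = empty))
  i <- pol[hit[, 1]]; j <- pol[hit[, 2]]
  ri <- a$resno[i]; rj <- a$resno[j]
  keep <- ri != rj
  # covalently adjacent backbone pair: N of residue k+1 against C/O of k
  pep <- (a$name[i] == "N" & a$name[j] %in% c("C", "O") & ri == rj + 1) |
         (a$name[j] == "N" & a$name[i] %in% c("C", "O") & rj == ri + 1)
  keep <- keep & !pep
  i <- i[keep]; j <- j[keep]
  pairs <- data.frame(resno_i = a$resno[i], name_i = a$name[i],
                      resno_j = a$resno[j], name_j = a$name[j],
                      dist = d[cbind(match(i, pol), match(j, pol))])
  list(count = nrow(pairs), pairs = pairs)
}

#' Detect salt bridges
#'
#' Pairs a side-chain oxygen of Asp/Glu with a side-chain nitrogen of
#' Lys/Arg/His within the cutoff (default 4 Angstrom, inclusive). By
#' default multiple atom contacts between one residue pair count once.
#'
#' @param s a `protein_structure`.
#' @param cutoff distance cutoff, Angstrom.
#' @param per_atom count atom pairs instead of residue pairs.
#' @return List with `count` and `pairs` (residue-pair data frame).
#' @export
detect_salt_bridges <- function(s, cutoff = 4, per_atom = FALSE) {
  a <- s$atoms
  acid <- which(a$resname %in% c("ASP", "GLU") & a$element == "O" &
                  grepl("^O[DE]", a$name))
  base <- which((a$resname == "LYS" & a$name == "NZ") |
                (a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
                (a$resname == "HIS" & a$name %in% c("ND1", "NE2")))
  empty <- data.frame(resno_acid = integer(0), resno_base = integer(0),
                      dist = numeric(0))
  if (!length(acid) || !length(base)) return(list(count = 0L, pairs = empty))
  d <- pair_dist(as.matrix(a[acid, c("x", "y", "z")]),
                 as.matrix(a[base, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(list(count = 0L, pairs = empty))
  pairs <- data.frame(resno_acid = a$resno[acid[hit[, 1]]],
                      resno_base = a$resno[base[hit[, 2]]],
                      dist = d[hit])
  if (!per_atom) {
    key <- paste(pairs$resno_acid, pairs$resno_base)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  list(count = nrow(pairs), pairs = pairs)
}

#' Detect disulfide bonds
#'
#' Counts SG-SG pairs of distinct cysteine residues with distance strictly
#' below the cutoff (default 2.1 Angstrom).
#'
#' @param s a `protein_structure`.
#' @param cutoff distance bound, Angstrom (strict `<`).
#' @return Integer count.
#' @export
detect_disulfides <- function(s, cutoff = 2.1) {
  a <- s$atoms
  sg <- which(a$resname == "CYS" & a$name == "SG")
  if (length(sg) < 2) return(0L)
  d <- pair_dist(as.matrix(a[sg, c("x", "y", "z")]),
                 as.matrix(a[sg, c("x", "y", "z")]))
  sum(upper.tri(d) & d < cutoff & a$resno[sg[row(d)]] != a$resno[sg[col(d)]])
}

# Deterministic Fibonacci sphere lattice (unit vectors).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(cos(ga * i) * r, sin(ga * i) * r, z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Numerical SASA by deterministic sphere-point sampling on a Fibonacci
#' lattice (default 960 points per atom), over the chain's non-hydrogen
#' atoms with the fixed van der Waals radius table (C 1.7, N 1.55, O 1.52,
#' S 1.8, H 1.2, P 1.8 Angstrom). Bit-stable for a fixed point count.
#'
#' @param s a `protein_structure`.
#' @param probe probe radius, Angstrom (1.4 for solvent accessibility, 0
#'   for the bare molecular envelope).
#' @param n_points lattice points per atom.
#' @return List with `total` (Angstrom^2), `per_atom` and `per_residue`.
#' @export
shrake_rupley_sasa <- function(s, probe = 1.4, n_points = 960) {
  a <- s$atoms[s$atoms$element != "H", , drop = FALSE]
  if (!nrow(a)) return(list(total = 0, per_atom = numeric(0),
                            per_residue = numeric(0)))
  rad <- VDW_RADII[a$element]
  if (anyNA(rad)) {
    bad <- which(is.na(rad))[1]
    stop(sprintf("no van der Waals radius for atom %s (%s %d, element '%s')",
                 a$name[bad], a$resname[bad], a$resno[bad], a$element[bad]))
  }
  rad <- unname(rad) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  dirs <- fibonacci_sphere(n_points)
  d <- pair_dist(xyz, xyz)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    pts <- sweep(dirs * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      dn <- pair_dist(pts, xyz[nb, , drop = FALSE])
      buried <- rowSums(dn < rep(rad[nb], each = n_points)) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    per_atom[i] <- acc / n_points * 4 * pi * rad[i]^2
  }
  per_res <- tapply(per_atom, a$resno, sum)
  list(total = sum(per_atom), per_atom = per_atom,
       per_residue = per_res[as.character(s$residues$resno)])
}

#' Relative surface area
#'
#' RSA = SASA(probe 1.4) / molecular surface area, the latter computed
#' with the same sphere-point algorithm at probe radius 0.
#'
#' @param s a `protein_structure`.
#' @param probe solvent probe radius, Angstrom.
#' @param n_points lattice points per atom.
#' @return Dimensionless ratio.
#' @export
relative_surface_area <- function(s, probe = 1.4, n_points = 960) {
  sasa <- shrake_rupley_sasa(s, probe, n_points)$total
  mol <- shrake_rupley_sasa(s, 0, n_points)$total
  if (mol <= 0) stop("zero molecular surface area")
  sasa / mol
}

# Kabsch-Sander backbone hydrogen-bond energies. H is placed on N along
# the bisector of the previous residue's C=O frame; bond if E < -0.5
# kcal/mol. Returns an n x n logical matrix: hb[i, j] means the N-H of
# residue j donates to the C=O of residue i.
ks_hbond_matrix <- function(s) {
  n <- n_residues(s)
  get_atom <- function(name) {
    a <- s$atoms[s$atoms$name == name, , drop = FALSE]
    m <- as.matrix(a[match(s$residues$resno, a$resno), c("x", "y", "z")])
    m
  }
  Nx <- get_atom("N"); CAx <- get_atom("CA"); Cx <- get_atom("C")
  Ox <- get_atom("O")
  ok <- !is.na(Nx[, 1]) & !is.na(CAx[, 1]) & !is.na(Cx[, 1]) & !is.na(Ox[, 1])
  H <- matrix(NA_real_, n, 3)
  for (j in 2:n) {
    if (!ok[j] || !ok[j - 1]) next
    v <- unit(unit(Nx[j, ] - Cx[j - 1, ]) + unit(Nx[j, ] - Ox[j - 1, ]))
    H[j, ] <- Nx[j, ] + 1.01 * v
  }
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !ok[j] || is.na(H[j, 1])) next
      if (vnorm(CAx[i, ] - CAx[j, ]) > 9) next
      rON <- vnorm(Ox[i, ] - Nx[j, ]); rCH <- vnorm(Cx[i, ] - H[j, ])
      rOH <- vnorm(Ox[i, ] - H[j, ]); rCN <- vnorm(Cx[i, ] - Nx[j, ])
      E <- 0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
      if (E < -0.5) hb[i, j] <- TRUE
    }
  }
  attr(hb, "ok") <- ok
  hb
}

#' Assign secondary structure (H/E/C)
#'
#' Kabsch-Sander-style assignment collapsed to three states: backbone
#' hydrogen bonds are scored with the electrostatic energy
#' E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) x 332 kcal/mol (threshold
#' -0.5) with a placed amide hydrogen; runs of i -> i+4 bonds give H,
#' parallel/antiparallel ladder patterns give E, everything else C.
#' Residues missing backbone atoms are labeled C with a warning.
#'
#' @param s a `protein_structure` with backbone N, CA, C, O atoms.
#' @return Character vector of per-residue labels in `{"H","E","C"}`.
#' @export
assign_secondary_structure <- function(s) {
  n <- n_residues(s)
  if (!n) return(character(0))
  hb <- ks_hbond_matrix(s)
  ok <- attr(hb, "ok")
  if (any(!ok)) warning("residues with missing backbone atoms labeled C")
  lab <- rep("C", n)
  bond <- function(i, j) i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  # sheet ladders first, helix overrides
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    par <- (bond(i - 1, j) && bond(j, i + 1)) ||
           (bond(j - 1, i) && bond(i, j + 1))
    anti <- (bond(i, j) && bond(j, i)) ||
            (bond(i - 1, j + 1) && bond(j - 1, i + 1))
    if (par || anti) lab[c(i, j)] <- "E"
  }
  turn4 <- vapply(seq_len(n), function(i) bond(i, i + 4), TRUE)
  for (i in 2:n)
    if (turn4[i - 1] && turn4[i]) lab[i:min(i + 3, n)] <- "H"
  lab[!ok] <- "C"
  lab
}

#' Secondary-structure fractions
#' @param labels output of [assign_secondary_structure()].
#' @return Named numeric vector `helix`, `sheet`, `loop` summing to 1.
#' @export
ss_fractions <- function(labels) {
  n <- length(labels)
  if (!n) return(c(helix = NA_real_, sheet = NA_real_, loop = NA_real_))
  c(helix = sum(labels == "H") / n, sheet = sum(labels == "E") / n,
    loop = sum(labels == "C") / n)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Midrank-tie rank-sum test. For n1 + n2 <= `exact_max` (default 12) the
#' p-value is computed by exhaustive enumeration of all group splits
#' (valid under ties); otherwise the normal approximation with continuity
#' and tie correction is used.
#'
#' @param a,b numeric samples.
#' @param exact_max largest combined size for exact enumeration.
#' @return List with `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  x <- c(a, b)
  r <- rank(x)
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  if (stats::var(x) == 0)
    return(list(statistic = W, p_value = 1, method = "degenerate"))
  if (n <= exact_max) {
    splits <- combn(n, n1)
    Ws <- colSums(matrix(r[splits], nrow = n1))
    p <- mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  ties <- table(r)
  vW <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (W - EW - sign(W - EW) * 0.5) / sqrt(vW)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = W, p_value = p, method = "normal")
}

#' Per-protein feature table
#'
#' Applies every structural-feature detector to each protein: residue
#' count, hydrogen bonds, salt bridges and disulfides (raw and per
#' residue), SASA, molecular surface area, RSA, secondary-structure
#' fractions, amino-acid composition and mean pLDDT. Proteins that fail a
#' detector are skipped with a warning.
#'
#' @param proteome named list of `protein_structure`.
#' @param config a [run_config()] list supplying the cutoffs.
#' @param sasa compute SASA/RSA columns (the slow step); when `FALSE`
#'   those columns are `NA`.
#' @return Data frame, one row per protein.
#' @export
feature_table <- function(proteome, config = run_config(), sasa = TRUE) {
  aa_letters <- names(AA1)
  rows <- lapply(names(proteome) %||% seq_along(proteome), function(nm) {
    s <- proteome[[nm]]
    tryCatch({
      nres <- n_residues(s)
      hb <- detect_hbonds(s, config$hbond_max)$count
      sb <- detect_salt_bridges(s, config$salt_bridge_max)$count
      ds <- detect_disulfides(s, config$disulfide_max)
      if (sasa) {
        sa <- shrake_rupley_sasa(s, config$sasa_probe, config$sasa_points)$total
        mol <- shrake_rupley_sasa(s, 0, config$sasa_points)$total
        rsa <- sa / mol
      } else sa <- mol <- rsa <- NA_real_
      ss <- ss_fractions(assign_secondary_structure(s))
      comp <- table(factor(strsplit(s$sequence, "")[[1]], levels = aa_letters))
      comp <- as.numeric(comp) / nres
      out <- data.frame(id = s$id %||% nm, n_res = nres, hbonds = hb,
                        hbonds_per_res = hb / nres, salt_bridges = sb,
                        salt_bridges_per_res = sb / nres, disulfides = ds,
                        sasa = sa, mol_surface = mol, rsa = rsa,
                        helix_frac = ss["helix"], sheet_frac = ss["sheet"],
                        loop_frac = ss["loop"],
                        mean_plddt = mean_plddt(s),
                        stringsAsFactors = FALSE)
      out[paste0("aa_", aa_letters)] <- as.list(comp)
      rownames(out) <- NULL
      out
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", nm, conditionMessage(e)))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(id = character(0), n_res = integer(0)))
  }
  do.call(rbind, rows)
}
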