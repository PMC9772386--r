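# Shared fixtures and independent oracles used across the suite.

# single-atom "structure" builders for crafted geometry tests
make_structure <- function(atoms_df, id = "toy") {
  lig <- atoms_df[0, , drop = FALSE]
  lig$group <- character(0)
  protomod:::new_protein_structure(id, atoms_df, lig)
}

atom_row <- function(name, element, resno, resname, x, y, z, b = 90) {
  data.frame(name = name, element = element, resno = resno,
             resname = resname, x = x, y = y, z = z, b = b,
             stringsAsFactors = FALSE)
}

# independent Gotoh affine-gap Smith-Waterman, plain dynamic programming
bf_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- Ix <- Iy <- matrix(0, n + 1, m + 1)
  neg <- -1e9
  Ix[1, ] <- neg; Iy[, 1] <- neg
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1],
                   Iy[i - 1, j - 1]) + s
    M[i, j] <- max(M[i, j], 0)
    Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                    Ix[i - 1, j] - gap_extend)
    Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                    Iy[i, j - 1] - gap_extend)
    best <- max(best, M[i, j])
  }
  best
}

# exposed accessible area of sphere 1 (radius R1 incl. probe) partially
# buried by sphere 2 at center distance d: spherical-cap closed form
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  cos_a <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  cap <- 2 * pi * R1^2 * (1 - cos_a)
  4 * pi * R1^2 - cap
}

# brute-force polar-contact count following the stated rule directly
bf_polar_contacts <- function(s, cutoff = 3.5) {
  a <- s$atoms
  pol <- a[a$element %in% c("N", "O"), , drop = FALSE]
  cnt <- 0
  if (nrow(pol) < 2) return(0)
  for (i in seq_len(nrow(pol) - 1)) for (j in (i + 1):nrow(pol)) {
    if (pol$resno[i] == pol$resno[j]) next
    peptide <- (pol$name[i] == "N" && pol$name[j] %in% c("C", "O") &&
                  pol$resno[i] == pol$resno[j] + 1) ||
               (pol$name[j] == "N" && pol$name[i] %in% c("C", "O") &&
                  pol$resno[j] == pol$resno[i] + 1)
    if (peptide) next
    d <- sqrt(sum((c(pol$x[i], pol$y[i], pol$z[i]) -
                     c(pol$x[j], pol$y[j], pol$z[j]))^2))
    if (d <= cutoff) cnt <- cnt + 1
  }
  cnt
}

fixture_helix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- ideal_backbone("helix", 20, plddt = 85)
    cache
  }
})

fixture_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      plan <- data.frame(module_id = c("M1", "M2", "M3"),
                         module_name = c("a", "b", "c"),
                         group = c("I", "II", "III"), n_pairs = 3,
                         stringsAsFactors = FALSE)
      cache <<- synth_proteome_pair(plan, seed = 101)
    }
    cache
  }
})
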