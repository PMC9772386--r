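# Structural correspondence, optimal rigid superposition and the SiMax
# length-normalized RMSD score.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the rotation R (det +1, reflections excluded) and translation t
#' minimizing RMSD between `P` and `Q %*% t(R) + t`, i.e. moves `Q` onto
#' `P`, via singular value decomposition of the covariance of the centered
#' point sets.
#'
#' @param P,Q n x 3 coordinate matrices in 1:1 correspondence, n >= 3.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`,
#'   `n` and `residuals` (per-pair distances after superposition).
#' @examples
#' P <- matrix(rnorm(24), ncol = 3)
#' fit <- kabsch_superpose(P, P)
#' fit$rmsd
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("P and Q must be n x 3 matrices in correspondence")
  n <- nrow(P)
  if (n < 3) stop("need at least 3 point pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(svd(Pc)$d[1], 1) ||
      svd(Qc)$d[2] < 1e-8 * max(svd(Qc)$d[1], 1))
    stop("degenerate (collinear) point set")
  M <- crossprod(Qc, Pc)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Qr <- Qc %*% R
  res <- sqrt(rowSums((Pc - Qr)^2))
  list(rotation = R, translation = cp - drop(cq %*% R),
       rmsd = sqrt(mean(res^2)), n = n, residuals = res)
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix.
#' @param fit result of [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}

# Global alignment of two sequences; returns matched position indices and
# identity/coverage statistics. Biostrings supplies the aligner; the
# shipped BLOSUM62 copy is patched so X scores 0 against everything.
scoring_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0; m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

align_pair <- function(a, b, type = "global", gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = type,
    substitutionMatrix = scoring_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  ib <- Biostrings::start(Biostrings::subject(aln)) - 1L
  idx_a <- idx_b <- integer(length(pa))
  k <- 0L
  for (j in seq_along(pa)) {
    ga <- pa[j] == "-"; gb <- sa[j] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) { k <- k + 1L; idx_a[k] <- ia; idx_b[k] <- ib }
  }
  idx_a <- idx_a[seq_len(k)]; idx_b <- idx_b[seq_len(k)]
  ident <- if (k) sum(pa[pa != "-" & sa != "-"] ==
                        sa[pa != "-" & sa != "-"]) / k else 0
  span_a <- if (k) idx_a[k] - idx_a[1] + 1L else 0L
  span_b <- if (k) idx_b[k] - idx_b[1] + 1L else 0L
  list(score = Biostrings::score(aln),
       idx_a = idx_a, idx_b = idx_b, n_aligned = k,
       identity = ident,
       coverage_a = span_a / nchar(a), coverage_b = span_b / nchar(b))
}

#' Sequence-guided residue correspondence between two structures
#'
#' Globally aligns the two sequences (BLOSUM62, affine gaps) and returns
#' the CA atoms of aligned non-gap columns as the coordinate
#' correspondence used for superposition.
#'
#' @param a,b `protein_structure` objects with nonempty sequences.
#' @param gap_open,gap_extend affine gap penalties.
#' @return List with `pairs` (matrix of residue indices into `a` and `b`),
#'   `ca_a`, `ca_b` (matched CA coordinate matrices), and the alignment
#'   `identity`.
#' @export
sequence_guided_match <- function(a, b, gap_open = 20, gap_extend = 4) {
  aln <- align_pair(a$sequence, b$sequence, "global", gap_open, gap_extend)
  if (aln$n_aligned < 3) stop("fewer than 3 aligned columns")
  ca_a <- coords(a, "CA"); ca_b <- coords(b, "CA")
  if (nrow(ca_a) != n_residues(a) || nrow(ca_b) != n_residues(b))
    stop("structures must have one CA per residue for matching")
  list(pairs = cbind(a = aln$idx_a, b = aln$idx_b),
       ca_a = ca_a[aln$idx_a, , drop = FALSE],
       ca_b = ca_b[aln$idx_b, , drop = FALSE],
       identity = aln$identity)
}

#' Iteratively trimmed superposition
#'
#' Superposes the matched coordinates, drops pairs whose residual exceeds
#' max(2 x current RMSD, 3 Angstrom), and repeats to a fixed point. Never
#' retains fewer than max(0.3 x initial, 3) pairs; the retained count is
#' the operational N_mat. This trimming rule is this package's operational
#' definition of "aligned residues".
#'
#' @param ca_a,ca_b matched n x 3 coordinate matrices (n >= 3).
#' @param max_iter iteration cap.
#' @return List with `fit` (final [kabsch_superpose()] result), `keep`
#'   (logical vector over the initial pairs), `n_mat`, `iterations`.
#' @export
iterative_trim <- function(ca_a, ca_b, max_iter = 50) {
  n0 <- nrow(ca_a)
  if (n0 < 3) stop("need at least 3 matched pairs")
  floor_n <- max(ceiling(0.3 * n0), 3)
  keep <- rep(TRUE, n0)
  fit <- kabsch_superpose(ca_a, ca_b)
  it <- 0
  repeat {
    it <- it + 1
    thr <- max(2 * fit$rmsd, 3)
    drop_idx <- which(keep)[fit$residuals > thr]
    if (!length(drop_idx) || sum(keep) - length(drop_idx) < floor_n ||
        it >= max_iter)
      break
    keep[drop_idx] <- FALSE
    fit <- kabsch_superpose(ca_a[keep, , drop = FALSE],
                            ca_b[keep, , drop = FALSE])
  }
  list(fit = fit, keep = keep, n_mat = sum(keep), iterations = it)
}

#' SiMax length-normalized structural dissimilarity
#'
#' SiMax = max(L1, L2) * RMSD / N_mat: the superposition RMSD scaled up by
#' the fraction of the longer chain left unmatched, so partial matches of
#' long chains are penalized. Values below 6 Angstrom denote similar
#' structures.
#'
#' @param rmsd superposition RMSD, Angstrom.
#' @param n_mat number of matched residue pairs (>= 1).
#' @param L1,L2 chain lengths.
#' @return SiMax, Angstrom.
#' @export
simax_score <- function(rmsd, n_mat, L1, L2) {
  if (any(n_mat < 1)) stop("n_mat must be at least 1")
  if (any(L1 < 1) || any(L2 < 1)) stop("lengths must be at least 1")
  pmax(L1, L2) * rmsd / n_mat
}

#' Compare two structures: correspondence, trimmed superposition, SiMax
#'
#' Composes [sequence_guided_match()], [iterative_trim()] and
#' [simax_score()]. The similarity flag uses strict `SiMax < cutoff`
#' (default 6 Angstrom). RMSD is computed over matched CA atoms by
#' default; `rmsd_mode = "heavy"` recomputes it over all shared heavy
#' atoms of the retained residue pairs.
#'
#' @param a,b `protein_structure` objects (>= 3 residues each).
#' @param simax_cutoff structural-similarity threshold, Angstrom.
#' @param rmsd_mode `"CA"` (default) or `"heavy"`.
#' @param gap_open,gap_extend affine gap penalties for the correspondence.
#' @return One-row data frame: `id_a`, `id_b`, `L1`, `L2`, `n_mat`,
#'   `rmsd`, `simax`, `similar`, `identity`.
#' @export
compare_structures <- function(a, b, simax_cutoff = 6,
                               rmsd_mode = c("CA", "heavy"),
                               gap_open = 20, gap_extend = 4) {
  rmsd_mode <- match.arg(rmsd_mode)
  if (n_residues(a) < 3 || n_residues(b) < 3)
    stop("structures must have at least 3 residues")
  m <- sequence_guided_match(a, b, gap_open, gap_extend)
  tr <- iterative_trim(m$ca_a, m$ca_b)
  rmsd <- tr$fit$rmsd
  if (rmsd_mode == "heavy") {
    pairs <- m$pairs[tr$keep, , drop = FALSE]
    ha <- hb <- NULL
    for (r in seq_len(nrow(pairs))) {
      ra <- a$atoms[a$atoms$resno == a$residues$resno[pairs[r, 1]] &
                      a$atoms$element != "H", , drop = FALSE]
      rb <- b$atoms[b$atoms$resno == b$residues$resno[pairs[r, 2]] &
                      b$atoms$element != "H", , drop = FALSE]
      shared <- intersect(ra$name, rb$name)
      ha <- rbind(ha, as.matrix(ra[match(shared, ra$name), c("x", "y", "z")]))
      hb <- rbind(hb, as.matrix(rb[match(shared, rb$name), c("x", "y", "z")]))
    }
    rmsd <- kabsch_superpose(ha, hb)$rmsd
  }
  L1 <- n_residues(a); L2 <- n_residues(b)
  sim <- simax_score(rmsd, tr$n_mat, L1, L2)
  data.frame(id_a = a$id, id_b = b$id, L1 = L1, L2 = L2,
             n_mat = tr$n_mat, rmsd = rmsd, simax = sim,
             similar = sim < simax_cutoff, identity = m$identity,
             stringsAsFactors = FALSE)
}
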