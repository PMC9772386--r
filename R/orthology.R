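# Local alignment statistics and bidirectional-best-hit ortholog mapping
# at the study cutoffs (identity >= 0.30, coverage > 0.70 on both sides,
# e-value < 1e-5).

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps, X scored 0)
#' with deterministic traceback, via Biostrings.
#'
#' @param a,b sequences over the 20-letter alphabet (X allowed).
#' @param gap_open,gap_extend affine gap penalties.
#' @return List with `score`, `idx_a`, `idx_b` (aligned positions),
#'   `n_aligned`, `identity`, `coverage_a`, `coverage_b`.
#' @export
local_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  align_pair(a, b, "local", gap_open, gap_extend)
}

#' Identity and coverage of an alignment
#'
#' Identity is identical columns over aligned (gap-free) columns;
#' coverage is the aligned span over the full sequence length, per side.
#'
#' @param aln result of [local_align()] or the internal global aligner.
#' @return Named vector `identity`, `coverage_a`, `coverage_b`.
#' @export
identity_coverage <- function(aln) {
  if (!aln$n_aligned) stop("empty alignment")
  c(identity = aln$identity, coverage_a = aln$coverage_a,
    coverage_b = aln$coverage_b)
}

#' Karlin-Altschul e-value
#'
#' E = K m n exp(-lambda S) with fixed ungapped parameters for the shipped
#' scoring matrix (lambda 0.267, K 0.041); monotone decreasing in the
#' score.
#'
#' @param score alignment score (>= 0).
#' @param m,n query and database lengths.
#' @param lambda,K Karlin-Altschul parameters.
#' @return E-value.
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(score < 0)) stop("score must be non-negative")
  K * m * n * exp(-lambda * score)
}

#' Bidirectional-best-hit orthologs
#'
#' For every protein the best-scoring local-alignment hit in the other
#' proteome is found; a pair is kept iff it is a mutual best hit and
#' passes identity >= `identity_min`, coverage > `coverage_min` on both
#' sequences, and e-value < `evalue_max` (cutoff defaults from
#' [run_config()]). Best-hit ties are broken by lexicographic partner id.
#'
#' @param seqs_a,seqs_b named character vectors of sequences.
#' @param config a [run_config()] list.
#' @return Data frame: `id_a`, `id_b`, `score`, `identity`, `coverage_a`,
#'   `coverage_b`, `evalue`. Zero rows when nothing passes.
#' @export
bbh_orthologs <- function(seqs_a, seqs_b, config = run_config()) {
  if (!length(seqs_a) || !length(seqs_b)) stop("both proteomes must be nonempty")
  mat <- scoring_matrix()
  setA <- Biostrings::AAStringSet(seqs_a)
  setB <- Biostrings::AAStringSet(seqs_b)
  # score matrix |A| x |B|, one vectorized call per B sequence
  scores <- matrix(NA_real_, length(seqs_a), length(seqs_b),
                   dimnames = list(names(seqs_a), names(seqs_b)))
  for (j in seq_along(seqs_b)) {
    scores[, j] <- Biostrings::pairwiseAlignment(
      setA, setB[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  best_of <- function(v, ids) {
    top <- which(v == max(v))
    ids[top[order(ids[top])[1]]]
  }
  best_ab <- vapply(seq_len(nrow(scores)), function(i)
    best_of(scores[i, ], colnames(scores)), "")
  best_ba <- vapply(seq_len(ncol(scores)), function(j)
    best_of(scores[, j], rownames(scores)), "")
  names(best_ab) <- rownames(scores); names(best_ba) <- colnames(scores)
  mutual <- names(best_ab)[best_ba[best_ab] == names(best_ab)]
  m_total <- sum(nchar(seqs_a)); n_total <- sum(nchar(seqs_b))
  rows <- lapply(mutual, function(ida) {
    idb <- best_ab[[ida]]
    aln <- local_align(seqs_a[[ida]], seqs_b[[idb]])
    ev <- karlin_altschul_evalue(aln$score, nchar(seqs_a[[ida]]), n_total,
                                 config$ka_lambda, config$ka_K)
    data.frame(id_a = ida, id_b = idb, score = aln$score,
               identity = aln$identity, coverage_a = aln$coverage_a,
               coverage_b = aln$coverage_b, evalue = ev,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows) %||%
    data.frame(id_a = character(0), id_b = character(0))
  if (!nrow(tab)) return(tab)
  keep <- tab$identity >= config$identity_min &
    tab$coverage_a > config$coverage_min &
    tab$coverage_b > config$coverage_min &
    tab$evalue < config$evalue_max
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
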