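# All-vs-all SiMax and identity matrices for an enzyme family,
# hierarchical clustering, cluster cuts and taxon concordance.

#' Pairwise SiMax and sequence-identity matrices
#'
#' Scores every unordered member pair with [compare_structures()] (SiMax)
#' and global-alignment identity; matrices are symmetric by construction
#' with SiMax diagonal 0 and identity diagonal 1. Members whose structure
#' fails to score are dropped with a warning.
#'
#' @param structures named list of `protein_structure` (>= 2).
#' @param sequences optional named character vector; defaults to the
#'   structures' own sequences.
#' @return List with `simax` and `identity` matrices and `labels`.
#' @export
pairwise_matrices <- function(structures, sequences = NULL) {
  if (length(structures) < 2) stop("need at least 2 family members")
  ids <- names(structures)
  if (is.null(sequences))
    sequences <- vapply(structures, `[[`, "", "sequence")
  n <- length(ids)
  simax <- matrix(0, n, n, dimnames = list(ids, ids))
  ident <- matrix(1, n, n, dimnames = list(ids, ids))
  failed <- logical(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sc <- tryCatch(compare_structures(structures[[i]], structures[[j]]),
                   error = function(e) NULL)
    if (is.null(sc)) { failed[c(i, j)] <- NA; next }
    simax[i, j] <- simax[j, i] <- sc$simax
    g <- align_pair(sequences[[i]], sequences[[j]], "global")
    ident[i, j] <- ident[j, i] <- g$identity
  }
  drop <- which(is.na(failed))
  if (length(drop)) {
    warning("dropping members that failed to score: ",
            paste(ids[drop], collapse = ", "))
    keep <- setdiff(seq_len(n), drop)
    simax <- simax[keep, keep]; ident <- ident[keep, keep]; ids <- ids[keep]
  }
  list(simax = simax, identity = ident, labels = ids)
}

#' Hierarchical clustering of a similarity matrix
#'
#' SiMax matrices are used raw as distances; identity matrices are
#' converted with 1 - identity. Average linkage (UPGMA) by default.
#'
#' @param m square symmetric matrix.
#' @param kind `"simax"` (distance as-is) or `"identity"` (1 - value).
#' @param linkage linkage method passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
hcluster <- function(m, kind = c("simax", "identity"), linkage = "average") {
  kind <- match.arg(kind)
  if (any(!is.finite(m))) stop("similarity matrix contains non-finite entries")
  d <- if (kind == "identity") 1 - m else m
  hclust(as.dist(d), method = linkage)
}

#' Cut a dendrogram and score taxon concordance
#'
#' Cuts the tree into `k` clusters and reports, per cluster, the fraction
#' of members carrying the cluster's majority taxon.
#'
#' @param hc an `hclust` object.
#' @param k number of clusters (1..n).
#' @param taxa named character vector of taxon labels.
#' @return List with `clusters` (named integer vector) and `concordance`
#'   (data frame `cluster`, `n`, `majority_taxon`, `concordance`).
#' @export
cut_and_concord <- function(hc, k, taxa) {
  cl <- cutree(hc, k = k)
  taxa <- taxa[names(cl)]
  conc <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    tx <- taxa[cl == g]
    tt <- sort(table(tx), decreasing = TRUE)
    data.frame(cluster = g, n = length(tx), majority_taxon = names(tt)[1],
               concordance = as.numeric(tt[1]) / length(tx),
               stringsAsFactors = FALSE)
  }))
  list(clusters = cl, concordance = conc)
}

#' Dendrogram as a Newick string
#' @param hc an `hclust` object.
#' @return Newick text.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
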