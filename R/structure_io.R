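#' Read a protein structure from PDB-format text
#'
#' Parses fixed-column ATOM/HETATM records into a `protein_structure`:
#' ATOM records become ordered residues of the first chain, HETATM records
#' become ligand groups, and the B-factor column is preserved so predicted
#' structures carry per-residue pLDDT (taken from the CA atom). Only the
#' first model of a multi-model file is read.
#'
#' @param text PDB-format content: a single string, a character vector of
#'   lines, or a path to an existing file.
#' @param id identifier for the structure; defaults to `"structure"`.
#' @return An object of class `protein_structure` with elements `id`,
#'   `atoms` (data frame: `name`, `element`, `resno`, `resname`, `x`, `y`,
#'   `z`, `b`), `ligands` (same layout plus `group`), `sequence`, `plddt`
#'   (per residue, from CA) and `residues` (data frame `resno`, `name3`,
#'   `aa1`).
#' @examples
#' s <- ideal_backbone("helix", 12)
#' s2 <- read_pdb(write_pdb(s), id = s$id)
#' identical(s2$sequence, s$sequence)
#' @seealso [write_pdb()], [mean_plddt()]
#' @export
read_pdb <- function(text, id = "structure") {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty PDB input")
  rec <- substr(lines, 1, 6)
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) stop("no ATOM or HETATM records in PDB input")

  parse_num <- function(x, lineno, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(trimws(x)))
    bad2 <- which(!nzchar(trimws(x)))
    if (length(c(bad, bad2)))
      stop(sprintf("malformed PDB record at line %d: unreadable %s field",
                   lineno[c(bad, bad2)][1], what))
    v
  }
  ln <- lines[keep]
  short <- which(nchar(ln) < 54)
  if (length(short))
    stop(sprintf("malformed PDB record at line %d: line shorter than coordinate fields",
                 keep[short[1]]))
  icode <- substr(ln, 27, 27)
  if (any(icode != " "))
    stop(sprintf("insertion codes are not supported (line %d)",
                 keep[which(icode != " ")[1]]))
  name    <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 20))
  chain   <- substr(ln, 22, 22)
  resno   <- parse_num(substr(ln, 23, 26), keep, "residue number")
  x <- parse_num(substr(ln, 31, 38), keep, "x")
  y <- parse_num(substr(ln, 39, 46), keep, "y")
  z <- parse_num(substr(ln, 47, 54), keep, "z")
  braw <- substr(ln, 61, 66)
  b <- suppressWarnings(as.numeric(braw))
  b[is.na(b)] <- 0
  el <- trimws(substr(ln, 77, 78))
  noel <- !nzchar(el)
  el[noel] <- substr(gsub("[0-9']", "", name[noel]), 1, 1)
  het <- substr(ln, 1, 6) == "HETATM"

  atoms <- data.frame(name = name, element = el, resno = resno,
                      resname = resname, x = x, y = y, z = z, b = b,
                      stringsAsFactors = FALSE)
  prot <- atoms[!het, , drop = FALSE]
  lig  <- atoms[het, , drop = FALSE]
  if (nrow(prot)) {
    first_chain <- chain[!het][1]
    prot <- prot[chain[!het] == first_chain, , drop = FALSE]
  }
  if (nrow(lig)) {
    lig$group <- paste(lig$resname, lig$resno, sep = "_")
  } else {
    lig$group <- character(0)
  }
  new_protein_structure(id, prot, lig)
}

#' @noRd
new_protein_structure <- function(id, atoms, ligands) {
  rownames(atoms) <- NULL
  rownames(ligands) <- NULL
  if (nrow(atoms)) {
    resno <- unique(atoms$resno)
    if (is.unsorted(resno, strictly = TRUE))
      stop("residue numbering must be strictly increasing within the chain")
    name3 <- atoms$resname[match(resno, atoms$resno)]
    aa1 <- unname(AA3[name3])
    aa1[is.na(aa1)] <- "X"
    ca <- atoms[atoms$name == "CA", , drop = FALSE]
    plddt <- ca$b[match(resno, ca$resno)]
    residues <- data.frame(resno = resno, name3 = name3, aa1 = aa1,
                           stringsAsFactors = FALSE)
    sequence <- paste(aa1, collapse = "")
  } else {
    residues <- data.frame(resno = integer(0), name3 = character(0),
                           aa1 = character(0), stringsAsFactors = FALSE)
    plddt <- numeric(0)
    sequence <- ""
  }
  structure(list(id = id, atoms = atoms, ligands = ligands,
                 residues = residues, sequence = sequence, plddt = plddt),
            class = "protein_structure")
}

#' Number of residues in a structure
#' @param s a `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) nrow(s$residues)

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d residues, %d atoms, %d ligand atoms\n",
              x$id, n_residues(x), nrow(x$atoms), nrow(x$ligands)))
  if (length(x$plddt) && any(!is.na(x$plddt)))
    cat(sprintf("  mean pLDDT %.2f\n", mean(x$plddt, na.rm = TRUE)))
  invisible(x)
}

#' Write a structure as PDB-format text
#'
#' Inverse of [read_pdb()]: emits fixed-column ATOM records for the chain,
#' HETATM records for ligand groups, TER and END. Round-tripping preserves
#' coordinates to the printed precision (3 decimals), residue order and
#' B-factors.
#'
#' @param s a `protein_structure`.
#' @param path optional file path; when given, text is written there.
#' @return The PDB text (invisibly when `path` is given).
#' @export
write_pdb <- function(s, path = NULL) {
  fmt <- function(i, rectype, a, serial) {
    nm <- a$name[i]
    nmf <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rectype, serial[i], nmf, "", a$resname[i], "A", a$resno[i], "",
            a$x[i], a$y[i], a$z[i], 1, a$b[i], a$element[i])
  }
  out <- character(0)
  na <- nrow(s$atoms)
  if (na)
    out <- vapply(seq_len(na), fmt, "", rectype = "ATOM", a = s$atoms,
                  serial = seq_len(na))
  if (na) out <- c(out, "TER")
  nl <- nrow(s$ligands)
  if (nl)
    out <- c(out, vapply(seq_len(nl), fmt, "", rectype = "HETATM",
                         a = s$ligands, serial = na + seq_len(nl)))
  out <- c(out, "END")
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Coordinate matrix of selected atoms
#'
#' @param s a `protein_structure`.
#' @param atoms `"CA"` (default), `"heavy"` (all non-hydrogen atoms), or
#'   `"backbone"` (N, CA, C, O).
#' @return Numeric matrix with 3 columns; row names are
#'   `resno` for CA selections.
#' @export
coords <- function(s, atoms = c("CA", "heavy", "backbone")) {
  atoms <- match.arg(atoms)
  a <- s$atoms
  a <- switch(atoms,
    CA = a[a$name == "CA", , drop = FALSE],
    heavy = a[a$element != "H", , drop = FALSE],
    backbone = a[a$name %in% c("N", "CA", "C", "O"), , drop = FALSE])
  m <- as.matrix(a[, c("x", "y", "z")])
  if (atoms == "CA") rownames(m) <- a$resno
  m
}

#' Mean per-residue pLDDT of a structure
#'
#' Per-residue confidence is read from the CA atom's B-factor (predicted
#' structures write the same value to every atom of a residue; CA is the
#' canonical carrier). The mean is over residues.
#'
#' @param s a `protein_structure`.
#' @return Mean pLDDT (scalar).
#' @export
mean_plddt <- function(s) {
  if (!length(s$plddt) || all(is.na(s$plddt)))
    stop("structure has no CA atoms carrying confidence values")
  mean(s$plddt, na.rm = TRUE)
}

#' Is a structure high-confidence?
#'
#' A structure is high-confidence when its mean pLDDT is at or above the
#' threshold (70 by default, the conventional confidence boundary).
#'
#' @param s a `protein_structure`.
#' @param threshold pLDDT threshold (default 70).
#' @return Logical.
#' @export
is_high_confidence <- function(s, threshold = 70) mean_plddt(s) >= threshold

#' Confidence summary over a proteome
#'
#' Summarizes prediction confidence: proteome-average pLDDT and the
#' count/fraction of proteins whose mean pLDDT exceeds a threshold
#' (strict `>`, matching "proteins having pLDDT scores above 70").
#'
#' @param proteome list of `protein_structure`.
#' @param threshold pLDDT threshold (default 70).
#' @param average `"per_protein"` (default) averages per-protein means;
#'   `"pooled"` averages over all residues of the proteome.
#' @return List with `mean_plddt`, `n`, `n_above`, `fraction_above`,
#'   `threshold`.
#' @export
confidence_summary <- function(proteome, threshold = 70,
                               average = c("per_protein", "pooled")) {
  average <- match.arg(average)
  if (!length(proteome)) stop("empty proteome")
  means <- vapply(proteome, mean_plddt, 0)
  overall <- if (average == "per_protein") mean(means)
             else mean(unlist(lapply(proteome, `[[`, "plddt")), na.rm = TRUE)
  n_above <- sum(means > threshold)
  list(mean_plddt = overall, n = length(proteome), n_above = n_above,
       fraction_above = n_above / length(proteome), threshold = threshold)
}
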