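test_that("PDB round-trip preserves coordinates, order and B-factors", {
  s <- ideal_backbone("helix", 20, sequence = random_sequence(20, 1),
                      plddt = round(runif(20, 60, 100), 2))
  s2 <- read_pdb(write_pdb(s), id = s$id)
  expect_equal(s2$residues$name3, s$residues$name3)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  expect_equal(s2$plddt, s$plddt, tolerance = 1e-2)
  expect_identical(s2$sequence, s$sequence)
  # second round trip is exact (printed precision is a fixed point)
  s3 <- read_pdb(write_pdb(s2), id = s$id)
  expect_identical(s3$atoms, s2$atoms)
})

test_that("written PDB agrees with an independent reader", {
  s <- ideal_backbone("helix", 12, plddt = 77.5)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f))
  expect_equal(nrow(pdb$atom), nrow(s$atoms))
  expect_equal(pdb$atom$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(unique(pdb$atom$b), 77.5)
  expect_equal(sum(pdb$calpha), 12)
})

test_that("generator file parses with expected residue and atom counts", {
  s <- ideal_backbone("helix", 20, cb = FALSE)
  s2 <- read_pdb(write_pdb(s))
  expect_equal(n_residues(s2), 20)
  expect_true(all(table(s2$atoms$resno) == 4))
  expect_true(all(c("N", "CA", "C", "O") %in%
                    s2$atoms$name[s2$atoms$resno == 5]))
})

test_that("HETATM-only input yields ligands and no residues", {
  txt <- paste(
    "HETATM    1  C1  SUB A 101      1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    2  C2  SUB A 101      2.000   2.000   3.000  1.00  0.00           C",
    "END", sep = "\n")
  s <- read_pdb(txt)
  expect_equal(n_residues(s), 0)
  expect_equal(nrow(s$ligands), 2)
  expect_equal(unique(s$ligands$resname), "SUB")
})

test_that("malformed and degenerate inputs raise informative errors", {
  expect_error(read_pdb(""), "empty")
  expect_error(read_pdb("REMARK nothing here"), "no ATOM")
  good <- write_pdb(ideal_backbone("helix", 4))
  lines <- strsplit(good, "\n")[[1]]
  lines[3] <- substr(lines[3], 1, 40)
  expect_error(read_pdb(paste(lines, collapse = "\n")), "line 3")
  bad <- lines <- strsplit(good, "\n")[[1]]
  substr(bad[2], 27, 27) <- "A"
  expect_error(read_pdb(paste(bad, collapse = "\n")), "nsertion")
})

test_that("only the first model of a multi-model file is read", {
  one <- write_pdb(ideal_backbone("helix", 5))
  two <- paste("MODEL     1", one, "ENDMDL", "MODEL     2", one, "ENDMDL",
               sep = "\n")
  expect_equal(n_residues(read_pdb(two)), 5)
})

test_that("non-standard residues map to X in the sequence", {
  at <- rbind(atom_row("CA", "C", 1, "ALA", 0, 0, 0),
              atom_row("CA", "C", 2, "MSE", 3.8, 0, 0),
              atom_row("CA", "C", 3, "GLY", 7.6, 0, 0))
  s <- make_structure(at)
  expect_identical(s$sequence, "AXG")
})

test_that("mean pLDDT averages residues and is order-invariant", {
  at <- rbind(atom_row("N", "N", 1, "ALA", 0, 0, 0, b = 60),
              atom_row("CA", "C", 1, "ALA", 1.4, 0, 0, b = 60),
              atom_row("CA", "C", 2, "ALA", 5, 0, 0, b = 80),
              atom_row("N", "N", 2, "ALA", 4, 0, 0, b = 80))
  s <- make_structure(at)
  expect_equal(mean_plddt(s), 70)
  expect_equal(mean_plddt(make_structure(at[c(2, 1, 4, 3), ])), 70)
  expect_true(is_high_confidence(make_structure(at), threshold = 70))
  s85 <- ideal_backbone("helix", 7, plddt = 85)
  expect_equal(mean_plddt(s85), 85)
  expect_error(mean_plddt(make_structure(atom_row("N", "N", 1, "ALA", 0, 0, 0))),
               "CA")
})

test_that("confidence summary counts strictly-above-threshold proteins", {
  prot <- c(lapply(1:9, function(i) ideal_backbone("helix", 5, plddt = 80)),
            list(ideal_backbone("helix", 5, plddt = 60)))
  cs <- confidence_summary(prot, 70)
  expect_equal(cs$fraction_above, 0.9)
  expect_equal(cs$n_above + sum(vapply(prot, mean_plddt, 0) <= 70), cs$n)
  # boundary: a protein at exactly the threshold does not count as above
  cs70 <- confidence_summary(list(ideal_backbone("helix", 5, plddt = 70)), 70)
  expect_equal(cs70$fraction_above, 0)
  expect_error(confidence_summary(list()), "empty")
})

test_that("pooled confidence average equals brute-force over all residues", {
  set.seed(5)
  prot <- lapply(1:10, function(i)
    ideal_backbone("helix", sample(5:15, 1), plddt = runif(1, 50, 100)))
  cs <- confidence_summary(prot, 70, average = "pooled")
  allres <- unlist(lapply(prot, `[[`, "plddt"))
  expect_equal(cs$mean_plddt, mean(allres))
  cs2 <- confidence_summary(prot, 70)
  expect_equal(cs2$mean_plddt, mean(vapply(prot, mean_plddt, 0)))
})
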