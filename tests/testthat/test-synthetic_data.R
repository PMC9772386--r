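test_that("ideal backbones have protein-like geometry", {
  h <- ideal_backbone("helix", 12)
  ca <- coords(h, "CA")
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  expect_true(all(assign_secondary_structure(h)[3:9] == "H"))
  s <- ideal_backbone("strand", 12)
  steps_s <- sqrt(rowSums(diff(coords(s, "CA"))^2))
  expect_true(all(steps_s > 3.1))
  expect_error(ideal_backbone("helix", 3), "at least 4")
  # torsions are reproduced by the construction
  at <- h$atoms
  get <- function(nm, i) unlist(at[at$name == nm & at$resno == i,
                                   c("x", "y", "z")])
  phi3 <- protomod:::dihedral(get("C", 2), get("N", 3), get("CA", 3),
                              get("C", 3))
  expect_equal(phi3, -57, tolerance = 1e-6)
})

test_that("perturbation is exact at sigma zero and rigid-motion safe", {
  h <- ideal_fold("helix", 30, random_sequence(30, 141), "h")
  same <- perturb_structure(h, sigma = 0)
  expect_equal(same$atoms, h$atoms)
  moved <- perturb_structure(h, sigma = 0, rotation = random_rotation(142),
                             translation = c(4, 4, 4))
  moved$id <- "m"
  expect_equal(compare_structures(h, moved)$rmsd, 0, tolerance = 1e-8)
})

test_that("noise level sets the superposition RMSD scale", {
  h <- ideal_fold("helix", 100, random_sequence(100, 143), "h")
  ca <- coords(h, "CA")
  expected <- sqrt(3)  # per-coordinate sigma 1
  ratios <- vapply(1:20, function(seed) {
    p <- perturb_structure(h, sigma = 1, seed = seed)
    kabsch_superpose(ca, coords(p, "CA"))$rmsd / expected
  }, 0)
  expect_true(all(ratios > 0.8 & ratios < 1.2))
})

test_that("sequence mutation hits the identity target", {
  sq <- random_sequence(200, 151)
  expect_identical(mutate_sequence(sq, 1), sq)
  mut <- mutate_sequence(sq, 0.5, 152)
  realized <- mean(strsplit(sq, "")[[1]] == strsplit(mut, "")[[1]])
  expect_true(realized >= 0.48 && realized <= 0.52)
  # the global aligner sees the same identity (no indels introduced;
  # stiff gap penalties keep the alignment gapless)
  aln <- protomod:::align_pair(sq, mut, "global", 20, 4)
  expect_equal(aln$identity, realized, tolerance = 0.02)
  expect_error(mutate_sequence("AC", 0.7), "not achievable")
  expect_error(mutate_sequence(sq, 0), "target_identity")
})

test_that("proteome-pair generation is seeded and bookkept", {
  plan <- data.frame(module_id = rep("M1", 2), module_name = "x",
                     group = c("I", "III"), n_pairs = c(2, 1))
  s1 <- synth_proteome_pair(plan, seed = 161)
  s2 <- synth_proteome_pair(plan, seed = 161)
  s3 <- synth_proteome_pair(plan, seed = 162)
  expect_equal(nrow(s1$truth), 3)
  expect_equal(length(s1$proteome_a), 3)
  expect_equal(nrow(s1$annotations), 6)
  expect_identical(s1$sequences_a, s2$sequences_a)
  expect_equal(s1$proteome_b[[1]]$atoms, s2$proteome_b[[1]]$atoms)
  # different seed: same planted design, different realizations
  expect_equal(s3$truth$group, s1$truth$group)
  expect_false(identical(s1$sequences_a, s3$sequences_a))
  # pLDDT fields are high-confidence by default
  expect_gt(min(vapply(s1$proteome_a, mean_plddt, 0)), 70)
})

test_that("inflated noise pushes planted group II pairs over the cutoff", {
  plan <- data.frame(module_id = "M1", module_name = "x", group = "II",
                     n_pairs = 3)
  calm <- synth_proteome_pair(plan, seed = 163)
  wild <- synth_proteome_pair(plan, seed = 163, sigma = c(I = 1, II = 8, III = 1))
  for (i in 1:3) {
    sc_calm <- compare_structures(calm$proteome_a[[i]], calm$proteome_b[[i]])
    sc_wild <- compare_structures(wild$proteome_a[[i]], wild$proteome_b[[i]])
    expect_true(sc_calm$similar)
    expect_false(sc_wild$similar)
  }
})

test_that("elastic-scan generator matches its stated model", {
  sc <- synth_elastic_scan(0.3, 0.002, temperatures = c(280, 300),
                           q = c(0.3, 0.8, 1.5))
  expect_equal(sc$S[sc$temperature == 280],
               exp(-c(0.3, 0.8, 1.5)^2 * (0.3 + 0.002 * 280) / 6),
               tolerance = 1e-12)
  expect_error(synth_elastic_scan(0.3, -0.001, temperatures = c(280, 300)),
               "positive")
  expect_error(synth_elastic_scan(-2, 0.002, temperatures = c(280, 300)),
               "negative")
  s1 <- synth_elastic_scan(0.3, 0.002, noise = 0.02, seed = 5)
  s2 <- synth_elastic_scan(0.3, 0.002, noise = 0.02, seed = 5)
  expect_identical(s1$S, s2$S)
})

test_that("ligand-bearing references place the ligand at the site", {
  fold <- ideal_fold("helix", 30, random_sequence(30, 171), "t")
  ref <- synth_reference_with_ligand(fold, 10:14, seed = 172)
  expect_equal(nrow(ref$ligands), 3)
  ca <- coords(fold, "CA")
  d <- sqrt(rowSums((sweep(as.matrix(ref$ligands[, c("x", "y", "z")]), 2,
                           ca[12, ]))^2))
  expect_true(all(d < 6))
  expect_error(synth_reference_with_ligand(fold, 100:104), "not present")
})
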