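test_that("helix backbone polar contacts match brute-force enumeration", {
  h <- fixture_helix()
  res <- detect_hbonds(h)
  expect_equal(res$count, bf_polar_contacts(h))
  # the i -> i+4 backbone bond of the helix is present
  expect_true(any(res$pairs$name_i == "O" & res$pairs$name_j == "N" &
                    res$pairs$resno_j - res$pairs$resno_i == 4))
})

test_that("polar-contact cutoff and exclusions behave as specified", {
  at <- rbind(atom_row("O", "O", 1, "SER", 0, 0, 0),
              atom_row("N", "N", 3, "SER", 3.6, 0, 0))
  expect_equal(detect_hbonds(make_structure(at))$count, 0)
  at2 <- rbind(atom_row("O", "O", 1, "SER", 0, 0, 0),
               atom_row("OG", "O", 1, "SER", 2.8, 0, 0))
  expect_equal(detect_hbonds(make_structure(at2))$count, 0)  # same residue
  at3 <- rbind(atom_row("O", "O", 1, "SER", 0, 0, 0),
               atom_row("N", "N", 2, "SER", 2.2, 0, 0))
  expect_equal(detect_hbonds(make_structure(at3))$count, 0)  # peptide pair
  at4 <- rbind(atom_row("O", "O", 1, "SER", 0, 0, 0),
               atom_row("N", "N", 3, "SER", 2.9, 0, 0))
  expect_equal(detect_hbonds(make_structure(at4))$count, 1)
  expect_equal(detect_hbonds(make_structure(at4[0, ]))$count, 0)
})

test_that("salt bridges pair acidic oxygens with basic nitrogens within 4 A", {
  at <- rbind(atom_row("OD1", "O", 1, "ASP", 0, 0, 0),
              atom_row("NZ", "N", 5, "LYS", 3.5, 0, 0))
  expect_equal(detect_salt_bridges(make_structure(at))$count, 1)
  at$x[2] <- 4.5
  expect_equal(detect_salt_bridges(make_structure(at))$count, 0)
  # bidentate contact counts once per residue pair, twice per atom pair
  at2 <- rbind(atom_row("OD1", "O", 1, "ASP", 0, 0, 0),
               atom_row("OD2", "O", 1, "ASP", 1.0, 0, 0),
               atom_row("NZ", "N", 5, "LYS", 3.0, 0, 0))
  expect_equal(detect_salt_bridges(make_structure(at2))$count, 1)
  expect_equal(detect_salt_bridges(make_structure(at2), per_atom = TRUE)$count, 2)
})

test_that("salt-bridge count equals exhaustive O-N pair enumeration", {
  set.seed(3)
  rows <- list()
  for (i in 1:3)
    rows[[i]] <- atom_row("OE1", "O", i, "GLU", runif(1, 0, 8), runif(1, 0, 8), 0)
  for (i in 4:6)
    rows[[i]] <- atom_row("NH1", "N", i, "ARG", runif(1, 0, 8), runif(1, 0, 8), 0)
  s <- make_structure(do.call(rbind, rows))
  a <- s$atoms
  manual <- 0
  for (i in 1:3) for (j in 4:6)
    if (sqrt(sum((c(a$x[i], a$y[i]) - c(a$x[j], a$y[j]))^2)) <= 4)
      manual <- manual + 1
  expect_equal(detect_salt_bridges(s)$count, manual)
})

test_that("disulfide detection uses a strict 2.1 A bound on SG pairs", {
  at <- rbind(atom_row("SG", "S", 1, "CYS", 0, 0, 0),
              atom_row("SG", "S", 8, "CYS", 2.05, 0, 0))
  expect_equal(detect_disulfides(make_structure(at)), 1)
  at$x[2] <- 2.10
  expect_equal(detect_disulfides(make_structure(at)), 0)
  expect_equal(detect_disulfides(fixture_helix()), 0)  # no cysteines
})

test_that("Shrake-Rupley SASA matches closed forms within 1%", {
  one <- make_structure(atom_row("C", "C", 1, "ALA", 0, 0, 0))
  got <- shrake_rupley_sasa(one, probe = 1.4, n_points = 960)$total
  expect_lt(abs(got / (4 * pi * (1.7 + 1.4)^2) - 1), 0.01)
  # distant atoms are additive
  two_far <- make_structure(rbind(atom_row("C", "C", 1, "ALA", 0, 0, 0),
                                  atom_row("O", "O", 2, "ALA", 50, 0, 0)))
  exp_far <- 4 * pi * ((1.7 + 1.4)^2 + (1.52 + 1.4)^2)
  expect_lt(abs(shrake_rupley_sasa(two_far)$total / exp_far - 1), 0.01)
  # overlapping pair against the spherical-cap formula
  d <- 2.5
  two <- make_structure(rbind(atom_row("C", "C", 1, "ALA", 0, 0, 0),
                              atom_row("O", "O", 2, "ALA", d, 0, 0)))
  R1 <- 1.7 + 1.4; R2 <- 1.52 + 1.4
  analytic <- two_sphere_exposed(R1, R2, d) + two_sphere_exposed(R2, R1, d)
  expect_lt(abs(shrake_rupley_sasa(two)$total / analytic - 1), 0.01)
})

test_that("adding an atom never increases another atom's exposed area", {
  base <- rbind(atom_row("C", "C", 1, "ALA", 0, 0, 0),
                atom_row("O", "O", 2, "ALA", 3, 0, 0))
  before <- shrake_rupley_sasa(make_structure(base))$per_atom
  added <- rbind(base, atom_row("N", "N", 3, "ALA", 1.5, 2, 0))
  after <- shrake_rupley_sasa(make_structure(added))$per_atom
  expect_true(all(after[1:2] <= before + 1e-9))
  expect_error(
    shrake_rupley_sasa(make_structure(atom_row("FE", "FE", 1, "HEM", 0, 0, 0))),
    "radius")
})

test_that("relative surface area follows the two-probe closed form", {
  one <- make_structure(atom_row("C", "C", 1, "ALA", 0, 0, 0))
  expect_equal(relative_surface_area(one), (1.7 + 1.4)^2 / 1.7^2,
               tolerance = 1e-6)
  # burial decreases RSA
  open_s <- make_structure(rbind(atom_row("C", "C", 1, "ALA", 0, 0, 0),
                                 atom_row("C", "C", 2, "ALA", 8, 0, 0)))
  buried <- make_structure(rbind(atom_row("C", "C", 1, "ALA", 0, 0, 0),
                                 atom_row("C", "C", 2, "ALA", 2.2, 0, 0)))
  expect_lt(relative_surface_area(buried), relative_surface_area(open_s))
})

test_that("secondary structure labels helix, sheet and coil correctly", {
  ssh <- assign_secondary_structure(ideal_backbone("helix", 14))
  expect_true(all(ssh[3:11] == "H"))
  hp <- ideal_fold("hairpin", 20)
  sse <- assign_secondary_structure(hp)
  expect_gt(sum(sse == "E"), 8)
  lone <- assign_secondary_structure(ideal_backbone("strand", 14))
  expect_true(all(lone == "C"))
  fr <- ss_fractions(sse)
  expect_equal(sum(fr), 1)
})

test_that("rank-sum test matches the exact permutation distribution", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
  expect_equal(r$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  # tied data, by hand: ranks of {1,1,2,2} are {1.5,1.5,3.5,3.5}; W = 3,
  # E[W] = 5; only the two extreme splits reach |W - 5| >= 2 -> p = 1/3
  rt <- rank_sum_test(c(1, 1), c(2, 2))
  expect_equal(rt$p_value, 2 / 6, tolerance = 1e-12)
  # large samples: normal approximation close to the reference implementation
  set.seed(9)
  a <- rnorm(40); b <- rnorm(45, 0.5)
  ours <- rank_sum_test(a, b)$p_value
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 1e-6)
  expect_equal(rank_sum_test(rep(2, 5), rep(2, 7))$p_value, 1)
})

test_that("p-value decreases monotonically with shift", {
  set.seed(4)
  a <- rnorm(60)
  ps <- vapply(c(0.2, 0.6, 1.2), function(sh)
    rank_sum_test(a, a + sh)$p_value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("feature table composes the per-protein detectors", {
  expect_equal(nrow(feature_table(list())), 0)
  h <- fixture_helix()
  tab <- feature_table(list(h1 = h), sasa = TRUE)
  expect_equal(tab$hbonds, detect_hbonds(h)$count)
  expect_equal(tab$rsa, relative_surface_area(h), tolerance = 1e-9)
  expect_equal(tab$n_res, 20)
  expect_equal(sum(tab[paste0("aa_", names(protomod:::AA1))]), 1)
  expect_equal(tab$helix_frac + tab$sheet_frac + tab$loop_frac, 1)
})
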