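test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Q <- sweep(P %*% t(Rz), 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  expect_equal(apply_transform(Q, fit), P, tolerance = 1e-8)
})

test_that("Kabsch RMSD is optimal against random rotations", {
  set.seed(2)
  P <- matrix(rnorm(24), ncol = 3)
  Q <- P + matrix(rnorm(24, 0, 0.5), ncol = 3)
  best <- kabsch_superpose(P, Q)$rmsd
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  worse <- vapply(1:500, function(i) {
    R <- random_rotation()
    sqrt(mean(rowSums((Pc - Qc %*% R)^2)))
  }, 0)
  expect_true(all(worse >= best - 1e-10))
})

test_that("Kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("sequence-guided matching handles indels deterministically", {
  sq <- random_sequence(40, 7)
  a <- ideal_fold("helix", 40, sq, "a")
  m <- sequence_guided_match(a, a)
  expect_equal(nrow(m$pairs), 40)
  expect_equal(m$pairs[, "a"], m$pairs[, "b"])
  # leading deletion: matched pairs skip the first 5 residues
  b <- ideal_fold("helix", 35, substr(sq, 6, 40), "b")
  m2 <- sequence_guided_match(a, b)
  expect_true(all(m2$pairs[, "a"] - m2$pairs[, "b"] == 5))
  expect_false(any(m2$pairs[, "a"] %in% 1:5))
  # internal insertion in b
  sq_ins <- paste0(substr(sq, 1, 20), "GGGG", substr(sq, 21, 40))
  b2 <- ideal_fold("helix", 44, sq_ins, "b2")
  m3 <- sequence_guided_match(a, b2)
  off <- m3$pairs[, "b"] - m3$pairs[, "a"]
  expect_setequal(unique(off), c(0, 4))
  expect_error(sequence_guided_match(
    ideal_fold("helix", 40, strrep("W", 40)),
    ideal_fold("helix", 40, strrep("P", 40))), NA)
})

test_that("iterative trimming removes constructed outliers only", {
  set.seed(11)
  ca <- coords(ideal_fold("helix", 50), "CA")
  tr0 <- iterative_trim(ca, ca)
  expect_equal(tr0$n_mat, 50)
  moved <- ca
  moved[25, ] <- moved[25, ] + c(20, 0, 0)
  tr <- iterative_trim(ca, moved)
  expect_equal(which(!tr$keep), 25)
  expect_lt(tr$fit$rmsd, 0.5)
})

test_that("trimming under pure noise converges fast and keeps most pairs", {
  for (seed in 1:5) {
    set.seed(seed)
    ca <- coords(ideal_fold("helix", 60), "CA")
    noisy <- ca + matrix(rnorm(length(ca), 0, 0.2), ncol = 3)
    tr <- iterative_trim(ca, noisy)
    expect_lte(tr$iterations, 5)
    expect_gte(tr$n_mat, 0.95 * 60)
  }
})

test_that("SiMax arithmetic follows the defining formula", {
  expect_equal(simax_score(0, 50, 100, 80), 0)
  expect_equal(simax_score(3, 100, 100, 100), 3)
  expect_equal(simax_score(4, 80, 120, 100), 6)
  expect_error(simax_score(1, 0, 10, 10), "n_mat")
})

test_that("structure comparison is symmetric with SiMax >= RMSD", {
  sq <- random_sequence(50, 21)
  a <- ideal_fold("helix", 50, sq, "a")
  b <- perturb_structure(ideal_fold("helix", 50, mutate_sequence(sq, 0.5, 22), "b"),
                         sigma = 1, rotation = random_rotation(23),
                         translation = c(3, -2, 8), seed = 24)
  self <- compare_structures(a, a)
  expect_equal(self$simax, 0, tolerance = 1e-9)
  expect_true(self$similar)
  ab <- compare_structures(a, b); ba <- compare_structures(b, a)
  expect_equal(ab$simax, ba$simax, tolerance = 1e-6)
  expect_equal(ab$rmsd, ba$rmsd, tolerance = 1e-6)
  expect_equal(ab$n_mat, ba$n_mat)
  expect_gte(ab$simax, ab$rmsd)
  # strictness of the similarity flag at the cutoff
  at_cut <- compare_structures(a, b, simax_cutoff = ab$simax)
  expect_false(at_cut$similar)
})

test_that("superposition RMSD is invariant to rigid pre-transforms", {
  sq <- random_sequence(40, 31)
  a <- ideal_fold("helix", 40, sq, "a")
  b <- perturb_structure(a, sigma = 0.8, seed = 32)
  b$id <- "b"
  base <- compare_structures(a, b)$rmsd
  b2 <- perturb_structure(b, sigma = 0, rotation = random_rotation(33),
                          translation = c(-4, 9, 1))
  expect_equal(compare_structures(a, b2)$rmsd, base, tolerance = 1e-6)
})

test_that("SiMax grows monotonically with coordinate noise", {
  sigmas <- c(0.5, 1, 2, 4)
  sq <- random_sequence(60, 41)
  a <- ideal_fold("helix", 60, sq, "a")
  sims <- sig <- numeric(0)
  for (s in sigmas) for (rep in 1:5) {
    b <- perturb_structure(a, sigma = s, seed = 1000 * s + rep)
    b$id <- "b"
    sims <- c(sims, compare_structures(a, b)$simax)
    sig <- c(sig, s)
  }
  rho <- cor(sig, sims, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("heavy-atom RMSD mode agrees with CA mode on clean copies", {
  a <- ideal_fold("helix", 30, random_sequence(30, 51), "a")
  b <- perturb_structure(a, sigma = 0, rotation = random_rotation(52),
                         translation = c(1, 1, 1))
  b$id <- "b"
  expect_equal(compare_structures(a, b, rmsd_mode = "heavy")$rmsd, 0,
               tolerance = 1e-8)
})
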