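tbo <- tbo_it2_mature()
tbo_pairs <- data.frame(res_i = c(1, 8, 14, 17, 22), res_j = c(15, 20, 31, 39, 29))

test_that("disulfide detection is greedy, one bond per cysteine", {
  # two SG at canonical bond length
  m <- gen_toy_structure("ACAACAA", data.frame(res_i = 2, res_j = 5), seed = 1)
  b <- detect_disulfides(m)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$res_i, b$res_j), c(2L, 5L))
  expect_equal(b$distance, 2.03, tolerance = 0.05)

  # pinned scaffold recovers exactly the five bonds
  toy <- gen_toy_structure(tbo, tbo_pairs, seed = 4)
  bonds <- detect_disulfides(toy)
  expect_equal(bonds$res_i, c(1L, 8L, 14L, 17L, 22L))
  expect_equal(bonds$res_j, c(15L, 20L, 31L, 39L, 29L))

  # no pairs pinned: all SG far apart, nothing detected
  free <- gen_toy_structure("ACAACAA", NULL, seed = 2)
  expect_equal(nrow(detect_disulfides(free)), 0L)
})

test_that("toy scaffolds recover pinned pairs across many seeds", {
  ok <- vapply(1:50, function(s) {
    toy <- gen_toy_structure(tbo, tbo_pairs, seed = s)
    b <- detect_disulfides(toy)
    nrow(b) == 5 &&
      all(paste(b$res_i, b$res_j) %in% paste(tbo_pairs$res_i, tbo_pairs$res_j))
  }, logical(1))
  expect_true(all(ok))
})

test_that("turn classification matches canonical dihedral definitions", {
  # ideal type I at residues 2-5 of a hexapeptide
  m1 <- build_backbone("AAAAAA", c(NA, -150, -60, -90, -150, -150),
                       c(120, 120, -30, 0, 120, NA))
  t1 <- classify_turns(m1)
  expect_true(any(t1$kind == "beta" & t1$start == 2 & t1$type == "I"))

  m8 <- build_backbone("AAAAAA", c(NA, -150, -60, -120, -150, -150),
                       c(120, 120, -30, 120, 120, NA))
  t8 <- classify_turns(m8)
  expect_true(any(t8$kind == "beta" & t8$start == 2 & t8$type == "VIII"))

  # compact turn whose dihedrals fit no canonical type: reported as IV
  m4 <- build_backbone("AAAAAA", c(NA, -150, -60, -30, -150, -150),
                       c(120, 120, -30, -60, 120, NA))
  ca <- function(m, i) unlist(m$atoms[m$atoms$resno == i & m$atoms$atom == "CA",
                                      c("x", "y", "z")])
  expect_lt(sqrt(sum((ca(m4, 2) - ca(m4, 5))^2)), 7)
  t4 <- classify_turns(m4)
  expect_true(any(t4$kind == "beta" & t4$start == 2 & t4$type == "IV"))

  # classic gamma turn at i+1
  mg <- build_backbone("AAAA", c(NA, 75, -150, -150), c(120, -64, 120, NA))
  tg <- classify_turns(mg)
  expect_true(any(tg$kind == "gamma" & tg$type == "gamma" & tg$start == 1))
  expect_error(classify_turns(build_backbone("AA", c(NA, -60), c(120, NA))),
               "3 consecutive")
})

test_that("the Q score reproduces published-style alignment values", {
  # (Nres1, Nalgn, RMSD) -> Q at 2 dp, with the reference chain at 39 residues
  cases <- list(
    list(34, 33, 1.68, 0.63), list(42, 38, 2.06, 0.60),
    list(35, 30, 1.43, 0.54), list(35, 31, 1.72, 0.53),
    list(40, 33, 1.77, 0.52), list(40, 34, 2.52, 0.43),
    list(46, 33, 1.92, 0.43), list(46, 31, 2.24, 0.34)
  )
  for (cs in cases) {
    expect_equal(round(q_score(cs[[1]], 39, cs[[2]], cs[[3]]), 2), cs[[4]])
  }
  expect_equal(q_score(20, 20, 20, 0), 1.0)
  expect_error(q_score(0, 39, 10, 1), "positive")
  expect_error(q_score(10, 39, 12, 1), "exceeds")
})

test_that("Kabsch superposition is optimal and rigid-invariant", {
  set.seed(33)
  A <- matrix(rnorm(30), ncol = 3)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-12)

  # random rigid transform of A must superpose to zero
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  B <- A %*% (Rx %*% Rz) + matrix(rep(c(5, -3, 2), each = 10), ncol = 3)
  expect_equal(superpose(A, B)$rmsd, 0, tolerance = 1e-9)

  # RMSD against any rigid transform of either input is unchanged
  C <- A + matrix(rnorm(30, sd = 0.5), ncol = 3)
  base <- superpose(A, C)$rmsd
  expect_equal(superpose(A, C %*% Rx + 7)$rmsd, base, tolerance = 1e-9)

  # optimality on 4-point toys versus a random rotation search
  for (i in 1:3) {
    P <- matrix(rnorm(12), ncol = 3)
    Q <- matrix(rnorm(12), ncol = 3)
    kr <- superpose(P, Q)$rmsd
    ub <- oracle_superpose_rmsd(P, Q)
    expect_lte(kr, ub + 1e-9)
    expect_lt(ub - kr, 0.05 * max(ub, 0.1))
  }
  expect_error(superpose(matrix(c(0, 1, 2, 0, 0, 0, 0, 0, 0), 3),
                         matrix(rnorm(9), 3)), "degenerate")
})

test_that("ICK topology classification identifies core and extra-bond roles", {
  bonds <- data.frame(res_i = c(1, 8, 14, 17, 22), res_j = c(15, 20, 31, 39, 29))
  cys <- c(1, 8, 14, 15, 17, 20, 22, 29, 31, 39)
  res <- classify_ick(bonds, cys)
  expect_true(res$has_core)
  expect_equal(res$core, data.frame(res_i = c(1, 8, 14), res_j = c(15, 20, 31)))
  expect_equal(res$extras$role[res$extras$res_j == 39], "C-terminal clamp")
  expect_equal(res$extras$role[res$extras$res_j == 29], "hairpin staple")

  # classic 3-bond knottin: core, no extras
  classic <- data.frame(res_i = c(1, 5, 10), res_j = c(16, 20, 25))
  res2 <- classify_ick(classic, sort(unlist(classic)))
  expect_true(res2$has_core)
  expect_equal(nrow(res2$extras), 0L)

  # ladder topology has no abcabc subset
  ladder <- data.frame(res_i = c(1, 10, 20), res_j = c(5, 15, 25))
  expect_false(classify_ick(ladder, sort(unlist(ladder)))$has_core)

  dup <- data.frame(res_i = c(1, 1), res_j = c(5, 9))
  expect_error(classify_ick(dup, c(1, 5, 9)), "duplicate")
})

test_that("ICK core detection equals the brute-force oracle on random topologies", {
  set.seed(71)
  for (rep in 1:500) {
    nb <- sample(4:6, 1)
    pos <- sort(sample(1:60, 2 * nb))
    perm <- sample(2 * nb)
    bonds <- data.frame(res_i = pmin(pos[perm[seq_len(nb)]],
                                     pos[perm[nb + seq_len(nb)]]),
                        res_j = pmax(pos[perm[seq_len(nb)]],
                                     pos[perm[nb + seq_len(nb)]]))
    expect_equal(classify_ick(bonds, pos)$has_core, oracle_has_ick_core(bonds))
  }
})

test_that("NOE calibration follows the r^-6 law with clipping", {
  expect_equal(noe_calibrate(100, 100, 3.0), 3.0)
  expect_equal(noe_calibrate(100 / 64, 100, 2.5), 5.0)  # 64^(1/6) = 2
  # clipped at 6 A
  expect_equal(noe_calibrate(1, 1e6, 3.0), 6.0)
  d <- noe_calibrate(c(10, 20, 40, 80), 100, 3.0)
  expect_true(all(diff(d) < 0))   # strictly decreasing in intensity
  expect_error(noe_calibrate(-1, 100, 3), "positive")
})

test_that("disulfide restraints follow the 3-per-bond convention", {
  bonds5 <- data.frame(res_i = c(1, 8, 14, 17, 22), res_j = c(15, 20, 31, 39, 29))
  rs <- disulfide_restraints(bonds5)
  expect_equal(nrow(rs), 15L)                 # 15 upper and 15 lower bounds
  expect_true(all(rs$lower <= rs$upper))
  rs1 <- disulfide_restraints(data.frame(res_i = 1, res_j = 9))
  expect_equal(nrow(rs1), 3L)
  expect_error(disulfide_restraints(data.frame()), "non-empty")
  tmp <- tempfile()
  write_restraints(rs1, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(grepl("^#", lines)), 2L)
  expect_equal(length(lines), 8L)             # 3 upper + 3 lower + 2 headers
})

test_that("hydrophobicity profiles respect the scale bounds and symmetry", {
  g <- hydrophobicity_profile(strrep("G", 11), window = 5)
  expect_equal(g, rep(venomtk:::.WIMLEY_WHITE_INTERFACE[["G"]], 11))
  p <- hydrophobicity_profile(tbo, window = 5)
  rev_p <- hydrophobicity_profile(paste(rev(strsplit(tbo, "")[[1]]), collapse = ""),
                                  window = 5)
  expect_equal(rev_p, rev(p), tolerance = 1e-12)
  expect_true(all(p >= min(venomtk:::.WIMLEY_WHITE_INTERFACE)))
  expect_true(all(p <= max(venomtk:::.WIMLEY_WHITE_INTERFACE)))
  expect_error(hydrophobicity_profile(tbo, window = 4), "odd")
})

test_that("PDB round-trip preserves coordinates, sequence and disulfides", {
  toy <- gen_toy_structure(tbo, tbo_pairs, seed = 9)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb_model(toy, tmp)
  back <- read_pdb_model(tmp)
  expect_equal(paste(back$residues$aa, collapse = ""), tbo)
  expect_equal(nrow(back$atoms), nrow(toy$atoms))
  b0 <- detect_disulfides(toy)
  b1 <- detect_disulfides(back)
  expect_equal(b1$res_i, b0$res_i)
  expect_equal(b1$res_j, b0$res_j)
  m <- merge(toy$atoms, back$atoms, by = c("resno", "atom"))
  expect_equal(m$x.x, m$x.y, tolerance = 1e-3)
})
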