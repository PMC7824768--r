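tbo <- tbo_it2_mature()

test_that("tryptic and GluC digests reproduce the expected toxin peptides", {
  d <- digest(tbo, "trypsin", max_missed = 1)
  hit1 <- d[d$sequence == "KSSECCGCSVCQCNLFGQNCQCK", ]
  expect_equal(nrow(hit1), 1L)
  expect_equal(c(hit1$start, hit1$end, hit1$missed_cleavages), c(10L, 32L, 1L))
  hit0 <- d[d$sequence == "SSECCGCSVCQCNLFGQNCQCK", ]
  expect_equal(c(hit0$start, hit0$end, hit0$missed_cleavages), c(11L, 32L, 0L))

  dg <- digest(proteoform(tbo, c_amidated = TRUE), "gluc", max_missed = 0)
  cterm <- dg[dg$end == 39, ]
  expect_equal(cterm$sequence, "CCGCSVCQCNLFGQNCQCKSGGLIAC")
  expect_equal(cterm$start, 14L)
  expect_equal(cterm$missed_cleavages, 0L)
  expect_true(cterm$c_amidated)
  # non-terminal peptides never inherit the amide
  expect_false(any(dg$c_amidated[dg$end != 39]))
})

test_that("digestion edge cases and invariants hold", {
  # no cleavage sites: whole sequence, zero missed
  d <- digest("ACACACAC", "trypsin", max_missed = 2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$missed_cleavages, 0L)
  expect_error(digest("ACAC", "pepsin"), "trypsin, gluc")

  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(venomtk:::.AA_LETTERS, 40, replace = TRUE), collapse = "")
    enz <- sample(c("trypsin", "gluc"), 1)
    # max_missed = 0 peptides tile the parent exactly
    d0 <- digest(s, enz, max_missed = 0)
    expect_equal(paste(d0$sequence, collapse = ""), s)
    # stored missed-cleavage counts equal a rescan of internal sites
    d4 <- digest(s, enz, max_missed = 4)
    resid <- venomtk:::.ENZYMES[[enz]]$residues
    recount <- vapply(seq_len(nrow(d4)), function(k) {
      chars <- strsplit(d4$sequence[k], "")[[1]]
      internal <- chars[-length(chars)]
      sum(internal %in% resid)
    }, integer(1))
    expect_equal(d4$missed_cleavages, recount)
  }
})

test_that("the proline rule is available but off by default", {
  s <- "AKPAKA"
  expect_equal(nrow(digest(s, "trypsin", 0)), 3L)
  expect_equal(nrow(digest(s, "trypsin", 0, proline_rule = TRUE)), 2L)
})

test_that("modification enumeration counts follow the binomial identity", {
  # fixed CAM on both Cys: a single form with 2 x 57.02146
  forms <- apply_modifications("ACC", fixed = list(mod_carbamidomethyl()))
  expect_equal(length(forms), 1L)
  expect_equal(forms[[1]]$delta_mass, 2 * 57.02146, tolerance = 1e-9)

  # 3 variable sites, max 2: 1 + C(3,1) + C(3,2) = 7 forms
  forms <- apply_modifications(
    "HKH", variable = list(mod_carbamidomethyl(c("M", "H", "K", "W"))),
    max_variable = 2)
  expect_equal(length(forms), 7L)

  # general count identity on random peptides
  set.seed(9)
  for (i in 1:5) {
    s <- paste(sample(venomtk:::.AA_LETTERS, 12, replace = TRUE), collapse = "")
    maxv <- sample(0:3, 1)
    forms <- apply_modifications(
      s, fixed = list(mod_carbamidomethyl()),
      variable = list(mod_carbamidomethyl(c("M", "H", "K", "W"))),
      max_variable = maxv)
    nsites <- sum(strsplit(s, "")[[1]] %in% c("M", "H", "K", "W"))
    expect_equal(length(forms),
                 sum(choose(nsites, 0:min(maxv, nsites))))
  }

  # no modifiable sites: exactly the unmodified form
  forms <- apply_modifications("GAGA", fixed = list(mod_carbamidomethyl()),
                               variable = list(mod_carbamidomethyl("M")))
  expect_equal(length(forms), 1L)
  expect_equal(forms[[1]]$delta_mass, 0)
})

test_that("fixed modifications exclude their sites from variable enumeration", {
  # C carries fixed CAM; variable CAM on C must not double-modify it
  forms <- apply_modifications(
    "ACA", fixed = list(mod_carbamidomethyl()),
    variable = list(mod_carbamidomethyl("C")), max_variable = 2)
  expect_equal(length(forms), 1L)
})

test_that("b/y fragment ions satisfy arithmetic and complementarity", {
  fi <- fragment_ions("GG")
  expect_equal(fi$mz[fi$series == "b" & fi$index == 1], 58.0287, tolerance = 1e-3)
  expect_equal(fi$mz[fi$series == "y" & fi$index == 1], 76.0393, tolerance = 1e-3)

  set.seed(13)
  for (i in 1:6) {
    s <- paste(sample(venomtk:::.AA_LETTERS, sample(5:15, 1), replace = TRUE),
               collapse = "")
    pf <- apply_modifications(s, fixed = list(mod_carbamidomethyl()))[[1]]
    fi <- fragment_ions(pf, charges = 1L)
    L <- nchar(s)
    expect_equal(nrow(fi), 2L * (L - 1L))
    prec <- peptidoform_mass(pf)
    for (k in seq_len(L - 1L)) {
      b <- fi$mz[fi$series == "b" & fi$index == k]
      y <- fi$mz[fi$series == "y" & fi$index == L - k]
      # neutral(b_k) + neutral(y_{L-k}) = precursor neutral + water-accounting
      expect_equal((b - venomtk:::PROTON_MASS) + (y - venomtk:::PROTON_MASS),
                   prec, tolerance = 1e-8)
    }
  }
})

test_that("amidation shifts only C-terminus-containing y ions", {
  pfs_free <- apply_modifications("CCGCSVCQCNLFGQNCQCKSGGLIAC",
                                  fixed = list(mod_carbamidomethyl()))[[1]]
  pfs_amide <- apply_modifications("CCGCSVCQCNLFGQNCQCKSGGLIAC",
                                   fixed = list(mod_carbamidomethyl()),
                                   c_amidated = TRUE)[[1]]
  fr_free <- fragment_ions(pfs_free)
  fr_amide <- fragment_ions(pfs_amide)
  b_free <- fr_free$mz[fr_free$series == "b"]
  b_amide <- fr_amide$mz[fr_amide$series == "b"]
  y_free <- fr_free$mz[fr_free$series == "y"]
  y_amide <- fr_amide$mz[fr_amide$series == "y"]
  expect_equal(b_free, b_amide, tolerance = 1e-10)
  expect_equal(y_amide - y_free, rep(-0.9840, length(y_free)), tolerance = 1e-3)
})
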