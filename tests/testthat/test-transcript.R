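test_that("minimal start/stop ORFs are found with correct coordinates", {
  o <- find_orfs("ATGGCATAA", min_aa_len = 1)
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_sequence, "MA")
  expect_equal(o$frame, 0L)
  expect_equal(c(o$start_nt, o$end_nt), c(1L, 6L))

  o2 <- find_orfs("TATGGCATAA", min_aa_len = 1)
  expect_equal(nrow(o2), 1L)
  expect_equal(o2$frame, 1L)
  expect_equal(o2$aa_sequence, "MA")

  expect_error(find_orfs("ATGQ"), "non-DNA")
  # N inside the candidate ORF excludes it
  expect_equal(nrow(find_orfs("ATGGNATAA", min_aa_len = 1)), 0L)
})

test_that("find_orfs agrees with the brute-force substring oracle", {
  set.seed(101)
  for (i in 1:20) {
    tx <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    got <- find_orfs(tx, min_aa_len = 1)
    want <- oracle_orfs(tx, min_aa_len = 1)
    got <- got[order(got$start_nt), ]
    want <- want[order(want$start_nt), ]
    expect_equal(got$start_nt, want$start_nt)
    expect_equal(got$end_nt, want$end_nt)
    expect_equal(got$aa_sequence, want$aa_sequence)
  }
})

test_that("generated precursor ORFs are recovered exactly from transcripts", {
  lib <- gen_precursor_library(10, seed = 7)
  for (i in 1:10) {
    o <- find_orfs(lib$transcripts[[i]], min_aa_len = 40, id = lib$truth$id[i])
    expect_equal(nrow(o), 1L)
    expect_equal(o$aa_sequence, lib$truth$aa_sequence[i])
    expect_equal(o$start_nt, lib$truth$orf_start_nt[i])
    expect_equal(o$end_nt, lib$truth$orf_end_nt[i])
  }
})

test_that("segmentation recovers generator ground truth and partitions the precursor", {
  lib <- gen_precursor_library(30, seed = 23)
  for (i in seq_len(nrow(lib$truth))) {
    r <- lib$truth[i, ]
    m <- segment_precursor(r$aa_sequence)
    expect_equal(m$signal, c(1L, r$signal_end))
    expect_equal(m$propeptide, c(r$pro_start, r$pro_end))
    expect_equal(m$mature, c(r$mature_start, r$mature_end))
    expect_equal(m$amidated, r$amidated)
    # the four intervals partition the sequence
    ivs <- rbind(m$signal, m$propeptide, m$mature, m$amidation_tail)
    ivs <- ivs[!is.na(ivs[, 1]), , drop = FALSE]
    covered <- unlist(apply(ivs, 1, function(v) v[1]:v[2], simplify = FALSE))
    expect_equal(sort(covered), seq_len(nchar(r$aa_sequence)))
  }
})

test_that("segmentation handles missing motifs and rejects implausible signals", {
  # no Arg after the signal region: propeptide empty, mature is the rest
  sig <- "MLLLLVIFFLLIVAFALA"          # 18 aa, h-core + A at -1/-3
  mature <- "CTTQQNNCTTTQQQNNCTT"
  m <- segment_precursor(paste0(sig, mature))
  expect_true(anyNA(m$propeptide))
  expect_equal(m$mature, c(19L, 37L))
  # all-polar sequence has no plausible signal region
  expect_error(segment_precursor(paste0("M", strrep("QNDE", 12))), "signal")
  expect_error(segment_precursor("MAAA"), "short")
})

test_that("amidation tail detection matches the processing rule", {
  t1 <- detect_amidation_tail("NLFGQNSGGLIACGKR")
  expect_equal(t1$sequence, "NLFGQNSGGLIAC")
  expect_true(t1$amidated)
  expect_equal(t1$tail_length, 3L)

  t2 <- detect_amidation_tail("NLFGQNSGGLIAC")
  expect_equal(t2$sequence, "NLFGQNSGGLIAC")
  expect_false(t2$amidated)
  expect_equal(t2$tail_length, 0L)

  t3 <- detect_amidation_tail("QNCAG")
  expect_equal(t3$sequence, "QNCA")
  expect_true(t3$amidated)
  expect_equal(t3$tail_length, 1L)

  # single basic after the Gly donor
  t4 <- detect_amidation_tail("QQNCAGK")
  expect_equal(t4$sequence, "QQNCA")
  expect_equal(t4$tail_length, 2L)
})

test_that("amidation trimming is idempotent on framework matures", {
  lib <- gen_precursor_library(40, seed = 31)
  for (s in lib$truth$mature_seq) {
    once <- detect_amidation_tail(paste0(s, "GKR"))
    twice <- detect_amidation_tail(once$sequence)
    expect_equal(twice$sequence, once$sequence)
    expect_false(twice$amidated)
  }
})

test_that("cysteine frameworks round-trip through the spacing pattern", {
  fw <- cys_framework("CC")
  expect_equal(fw$positions, c(1L, 2L))
  expect_equal(diff(fw$positions) - 1L, 0L)

  lin <- cys_framework("ACA")
  expect_true(lin$linear)
  expect_equal(lin$positions, 2L)
  expect_equal(lin$pattern, "")

  set.seed(55)
  for (i in 1:10) {
    s <- random_mature()
    fw <- cys_framework(s)
    expect_equal(parse_cys_pattern(fw$pattern), fw$positions)
  }
})

test_that("family grouping honours identity and the cysteine-count guard", {
  # identical pair collapses
  fams <- group_families(c("CACACACAC", "CACACACAC"))
  expect_equal(length(fams), 1L)
  expect_equal(length(fams[[1]]$members), 2L)

  # different cysteine counts never link, whatever the identity
  six <- "ACACACACACACA"   # 6 Cys
  ten <- "CACACACACACACACACACAC"
  expect_equal(length(group_families(c(six, ten), identity_threshold = 0.05)), 2L)

  # 3 families x 5 mutated members (<= 10% substitutions, Cys preserved)
  set.seed(77)
  base <- replicate(3, random_mature())
  members <- unlist(lapply(base, function(b) {
    c(b, replicate(4, mutate_mature(b, max_sub = 3)))
  }))
  members <- sample(members)   # order must not matter
  fams <- group_families(members, identity_threshold = 0.7)
  expect_equal(length(fams), 3L)
  expect_equal(sort(vapply(fams, function(f) length(f$members), integer(1))),
               c(5L, 5L, 5L))
  # each family contains exactly the mutants of one base
  for (f in fams) {
    origin <- vapply(f$members, function(m) {
      which.max(vapply(base, function(b) venomtk:::.pairwise_identity(m, b),
                       numeric(1)))
    }, integer(1))
    expect_equal(length(unique(origin)), 1L)
  }
  expect_equal(group_families(character(0)), list())
})
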