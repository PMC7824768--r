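# Independent oracles used to freeze expected values.  These deliberately
# use different algorithms from the package implementation.

# Brute-force ORF enumeration: every ATG...stop substring in the three
# forward frames, translated codon-wise, first in-frame stop.
oracle_orfs <- function(sequence, min_aa_len) {
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(sequence)
  out <- list()
  for (s in seq_len(max(0, n - 5L))) {
    if (substr(sequence, s, s + 2L) != "ATG") next
    p <- s
    repeat {
      p <- p + 3L
      if (p + 2L > n) break
      codon <- substr(sequence, p, p + 2L)
      if (codon %in% stops) {
        len_aa <- (p - s) / 3L
        if (len_aa >= min_aa_len) {
          codons <- substring(sequence, seq(s, p - 3L, 3L), seq(s, p - 3L, 3L) + 2L)
          if (!any(grepl("N", codons))) {
            out[[length(out) + 1L]] <- data.frame(
              start_nt = s, end_nt = p - 1L, frame = (s - 1L) %% 3L,
              aa_sequence = paste(code[codons], collapse = ""))
          }
        }
        break
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_nt = integer(0), end_nt = integer(0),
                      frame = integer(0), aa_sequence = character(0)))
  }
  do.call(rbind, out)
}

# Exhaustive isotopologue enumeration for small compositions (<= 8 atoms):
# every assignment of an isotope to every atom, aggregated by nominal
# offset.
oracle_envelope <- function(comp, floor = 1e-9) {
  iso <- venomtk:::.ELEMENT_ISOTOPES
  counts <- unclass(comp)
  atoms <- rep(names(counts), counts)
  stopifnot(length(atoms) <= 8)
  choices <- lapply(atoms, function(el) seq_len(nrow(iso[[el]])))
  grid <- expand.grid(choices)
  offs <- numeric(nrow(grid)); mass <- numeric(nrow(grid)); ab <- rep(1, nrow(grid))
  for (j in seq_along(atoms)) {
    d <- iso[[atoms[j]]]
    offs <- offs + d$offset[grid[[j]]]
    mass <- mass + d$mass[grid[[j]]]
    ab <- ab * d$abundance[grid[[j]]]
  }
  tot <- tapply(ab, offs, sum)
  wm <- tapply(ab * mass, offs, sum) / tot
  res <- data.frame(offset = as.integer(names(tot)), mass = as.numeric(wm),
                    abundance = as.numeric(tot))
  res <- res[res$abundance >= floor, ]
  res[order(res$offset), ]
}

# ICK-core oracle: over all orderings of three bonds, test whether ranking
# the six cysteines yields the 1-4/2-5/3-6 pairing, using a pairing-matrix
# formulation rather than string keys.
oracle_has_ick_core <- function(bonds) {
  nb <- nrow(bonds)
  if (nb < 3) return(FALSE)
  for (sub in utils::combn(nb, 3, simplify = FALSE)) {
    res <- c(bonds$res_i[sub], bonds$res_j[sub])
    rk <- rank(res)
    partner <- c(rk[4:6], rk[1:3])   # partner rank of each of the six, bond-wise
    names(partner) <- rk
    ok <- all(vapply(1:3, function(r) {
      unname(partner[as.character(r)]) == r + 3
    }, logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

# Brute-force rigid superposition via random rotation sampling: an upper
# bound on the optimal RMSD that Kabsch must not exceed.
oracle_superpose_rmsd <- function(A, B, n_try = 4000, seed = 99) {
  set.seed(seed)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  best <- Inf
  for (i in seq_len(n_try)) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
    r <- sqrt(mean(rowSums((B0 %*% R - A0)^2)))
    if (r < best) best <- r
  }
  best
}

# Random mature peptide on a framework template, for clustering fixtures.
random_mature <- function(pattern = tbo_it2_framework()) {
  pos <- venomtk:::parse_cys_pattern(pattern)
  n <- max(pos) # frameworks used here end in C
  chars <- sample(setdiff(venomtk:::.AA_LETTERS, "C"), n, replace = TRUE)
  chars[pos] <- "C"
  paste(chars, collapse = "")
}

# Mutate a mature peptide at up to `max_sub` non-Cys positions.
mutate_mature <- function(seq, max_sub = 3) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  free <- which(chars != "C")
  k <- sample(seq_len(max_sub), 1)
  at <- sample(free, min(k, length(free)))
  for (i in at) {
    chars[i] <- sample(setdiff(venomtk:::.AA_LETTERS, c("C", chars[i])), 1)
  }
  paste(chars, collapse = "")
}

# Precursor models straight from generator ground truth (bypasses the
# segmentation heuristic where a test needs known-correct models).
models_from_truth <- function(truth) {
  models <- lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    n <- nchar(r$aa_sequence)
    structure(list(
      aa_sequence = r$aa_sequence,
      signal = c(1L, r$signal_end),
      propeptide = c(r$pro_start, r$pro_end),
      mature = c(r$mature_start, r$mature_end),
      amidation_tail = if (r$amidated) c(r$mature_end + 1L, n) else c(NA_integer_, NA_integer_),
      amidated = r$amidated,
      mature_seq = r$mature_seq
    ), class = "precursor_model")
  })
  names(models) <- truth$id
  models
}

# Minimal mzML writer (64-bit little-endian, optional zlib) used to test
# the subset reader against files we control.
write_test_mzml <- function(path, ms1 = NULL, ms2 = list(), compress = FALSE) {
  enc <- function(v) {
    bytes <- writeBin(as.double(v), raw(), size = 8L, endian = "little")
    if (compress) bytes <- memCompress(bytes, type = "gzip")
    jsonlite::base64_enc(bytes)
  }
  comp_cv <- if (compress) {
    '<cvParam accession="MS:1000574" name="zlib compression" value=""/>'
  } else {
    '<cvParam accession="MS:1000576" name="no compression" value=""/>'
  }
  bda <- function(v, acc, name) {
    paste0('<binaryDataArray><cvParam accession="MS:1000523" name="64-bit float" value=""/>',
           comp_cv,
           sprintf('<cvParam accession="%s" name="%s" value=""/>', acc, name),
           "<binary>", enc(v), "</binary></binaryDataArray>")
  }
  specs <- character(0)
  if (!is.null(ms1)) {
    for (sc in unique(ms1$scan)) {
      pk <- ms1[ms1$scan == sc, ]
      specs <- c(specs, paste0(
        sprintf('<spectrum id="scan=%d" defaultArrayLength="%d">', sc, nrow(pk)),
        '<cvParam accession="MS:1000511" name="ms level" value="1"/>',
        bda(pk$mz, "MS:1000514", "m/z array"),
        bda(pk$intensity, "MS:1000515", "intensity array"),
        "</spectrum>"))
    }
  }
  for (s in ms2) {
    specs <- c(specs, paste0(
      sprintf('<spectrum id="%s" defaultArrayLength="%d">', s$id, nrow(s$peaks)),
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      "<precursorList><precursor><selectedIonList><selectedIon>",
      sprintf('<cvParam accession="MS:1000744" name="selected ion m/z" value="%.6f"/>', s$precursor_mz),
      sprintf('<cvParam accession="MS:1000041" name="charge state" value="%d"/>', s$precursor_charge),
      "</selectedIon></selectedIonList></precursor></precursorList>",
      bda(s$peaks$mz, "MS:1000514", "m/z array"),
      bda(s$peaks$intensity, "MS:1000515", "intensity array"),
      "</spectrum>"))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    "<run><spectrumList>", specs, "</spectrumList></run></mzML>"), path)
  invisible(path)
}
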