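# Synthetic-data generators.  Every generator is a pure function of
# (parameters, seed): each seeds its own RNG stream locally (withr-style
# save/restore) so fixtures for one stage are stable under changes to
# another.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.sample_chars <- function(pool, n) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Residue pools chosen so that segmentation ground truth is unambiguous:
# the signal body is strongly hydrophobic and contains no A/G/S/C outside
# the -1/-3 positions; the propeptide avoids Arg, hydrophobics and small
# residues so that neither a spurious -1/-3 site nor a spurious quadruplet
# Arg can arise downstream of the true boundaries.
.SIGNAL_BODY_POOL <- c("L", "I", "V", "F")
.PROPEPTIDE_POOL <- c("D", "E", "N", "Q", "T", "H", "K", "P")
# Met-free, like many mature spider toxins (Tbo-IT2 has no Met), so the
# initiator ATG is the only in-frame start codon of the transcript
.LOOP_POOL <- setdiff(.AA_LETTERS, c("C", "M"))

.random_signal <- function() {
  k <- sample(15:30, 1)
  body <- strsplit(.sample_chars(.SIGNAL_BODY_POOL, k - 1L), "")[[1]]
  # full signal is M + body, so body[i] sits at signal position i + 1
  body[k - 3L] <- "A"            # -3 position, small
  body[k - 2L] <- "L"
  body[k - 1L] <- "A"            # -1 position, small
  paste0("M", paste(body[seq_len(k - 1L)], collapse = ""))
}

.random_propeptide <- function() {
  len <- sample(5:25, 1)
  if (len < 4) len <- 4L
  body <- .sample_chars(.PROPEPTIDE_POOL, len - 4L)
  motif <- paste0("E", "E", sample(.PROPEPTIDE_POOL, 1), "R")
  paste0(body, motif)
}

.mature_from_framework <- function(pattern) {
  pos <- parse_cys_pattern(pattern)
  gaps <- as.integer(strsplit(pattern, "C", fixed = TRUE)[[1]])
  parts <- character(0)
  for (i in seq_along(gaps)) {
    parts <- c(parts, .sample_chars(.LOOP_POOL, gaps[i]))
    if (i < length(gaps)) parts <- c(parts, "C")
  }
  paste(parts, collapse = "")
}

#' Cysteine framework pattern of the Tbo-IT2 type
#'
#' Ten cysteines with spacing `0C6C5C0C1C2C1C6C1C7C0` over a 39-residue
#' mature peptide.
#'
#' @return pattern string usable as a generator template
#' @export
tbo_it2_framework <- function() "0C6C5C0C1C2C1C6C1C7C0"

#' Reverse-translate a protein with a fixed codon table
#'
#' One representative codon per residue; no codon optimisation.
#'
#' @param aa protein sequence
#' @return DNA string
#' @export
reverse_translate <- function(aa) {
  chars <- .validate_protein(aa)
  paste(.REVERSE_CODON[chars], collapse = "")
}

.random_utr <- function(len) {
  utr <- .sample_chars(c("A", "C", "G", "T"), len)
  # strip start codons so the embedded precursor ORF is the only one
  while (grepl("ATG", utr, fixed = TRUE)) {
    utr <- sub("ATG", "ACG", utr, fixed = TRUE)
  }
  utr
}

#' Generate a synthetic venom-gland precursor transcript library
#'
#' Each record is a toxin precursor -- random signal peptide (15-30 aa with
#' a hydrophobic core and small residues at the -1/-3 positions),
#' propeptide (5-25 aa ending in an acidic processing quadruplet "EExR"),
#' mature region drawn from a cysteine framework template with randomised
#' loop residues, and (with probability `p_amidated`) a Gly + two basic
#' amidation tail -- reverse-translated and embedded in a transcript with
#' ATG-free 5'/3' UTR padding.  Ground truth sufficient for exact boundary
#' scoring is returned alongside.
#'
#' @param n number of records
#' @param seed RNG seed (generator-local stream)
#' @param frameworks character vector of framework patterns (see
#'   [tbo_it2_framework()])
#' @param p_amidated probability of emitting the canonical Gly+Lys+Arg tail
#' @return list with `transcripts` (named character vector of DNA) and
#'   `truth` (data.frame: id, signal/propeptide/mature interval bounds in
#'   precursor coordinates, amidated flag, aa_sequence, mature_seq,
#'   orf_start_nt, orf_end_nt)
#' @export
gen_precursor_library <- function(n, seed = 1L,
                                  frameworks = tbo_it2_framework(),
                                  p_amidated = 0.7) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(frameworks) == 0) stop("frameworks must be non-empty", call. = FALSE)
  .with_seed(seed, {
    transcripts <- character(n)
    ids <- sprintf("SYN%04d", seq_len(n))
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      # rejection-sample until the embedded precursor is the only ORF of at
      # least 40 codons, so ORF-level ground truth is unambiguous
      repeat {
        sig <- .random_signal()
        pro <- .random_propeptide()
        mat <- .mature_from_framework(sample(frameworks, 1))
        amidated <- stats::runif(1) < p_amidated
        tail <- if (amidated) "GKR" else ""
        aa <- paste0(sig, pro, mat, tail)
        cds <- paste0(reverse_translate(aa), "TAA")
        utr5 <- .random_utr(sample(20:60, 1))
        utr3 <- .random_utr(sample(20:60, 1))
        tx <- paste0(utr5, cds, utr3)
        if (nrow(find_orfs(tx, min_aa_len = 40L)) == 1L) break
      }
      transcripts[i] <- tx
      ks <- nchar(sig); kp <- nchar(pro); km <- nchar(mat)
      rows[[i]] <- data.frame(
        id = ids[i], signal_start = 1L, signal_end = ks,
        pro_start = ks + 1L, pro_end = ks + kp,
        mature_start = ks + kp + 1L, mature_end = ks + kp + km,
        amidated = amidated, aa_sequence = aa, mature_seq = mat,
        orf_start_nt = nchar(utr5) + 1L,
        orf_end_nt = nchar(utr5) + 3L * nchar(aa),
        stringsAsFactors = FALSE
      )
    }
    list(transcripts = stats::setNames(transcripts, ids),
         truth = do.call(rbind, rows))
  })
}

#' Generate a synthetic MS/MS run from peptidoforms
#'
#' One spectrum per peptidoform: precursor m/z with Gaussian ppm error, all
#' 1+ b/y fragment ions minus a random dropout fraction, log-normal
#' intensities, plus uniform-random noise peaks.
#'
#' @param peptidoforms list of `peptidoform` objects (see
#'   [apply_modifications()])
#' @param seed RNG seed
#' @param ppm_error_sd Gaussian precursor mass error (ppm standard
#'   deviation); fragment m/z get a matching absolute jitter bounded well
#'   below the 0.02 Da matching tolerance
#' @param frag_noise_peaks uniform-random noise peaks per spectrum
#' @param dropout fraction of fragment ions removed at random, in [0, 0.9]
#' @param precursor_charge charge state written to each spectrum
#' @return list with `spectra` (list of [spectrum()]) and `truth`
#'   (data.frame: spectrum_id, sequence, description)
#' @export
gen_msms_run <- function(peptidoforms, seed = 1L, ppm_error_sd = 2,
                         frag_noise_peaks = 0L, dropout = 0,
                         precursor_charge = 2L) {
  if (dropout < 0 || dropout > 0.9) stop("dropout must be in [0, 0.9]", call. = FALSE)
  .with_seed(seed, {
    spectra <- vector("list", length(peptidoforms))
    rows <- vector("list", length(peptidoforms))
    for (i in seq_along(peptidoforms)) {
      pf <- peptidoforms[[i]]
      id <- sprintf("synspec_%04d", i)
      m <- peptidoform_mass(pf)
      pmz <- mz(m, precursor_charge) * (1 + stats::rnorm(1, 0, ppm_error_sd) * 1e-6)
      frags <- fragment_ions(pf, charges = 1L)
      keep <- stats::runif(nrow(frags)) >= dropout
      fmz <- frags$mz[keep] + stats::rnorm(sum(keep), 0, 0.002)
      fint <- stats::rlnorm(sum(keep), meanlog = log(1e4), sdlog = 0.6)
      if (frag_noise_peaks > 0) {
        nmz <- stats::runif(frag_noise_peaks, 100, max(1500, max(frags$mz)))
        nint <- stats::rlnorm(frag_noise_peaks, meanlog = log(3e3), sdlog = 0.6)
        fmz <- c(fmz, nmz); fint <- c(fint, nint)
      }
      spectra[[i]] <- spectrum(id, pmz, precursor_charge, fmz, fint)
      rows[[i]] <- data.frame(spectrum_id = id, sequence = pf$sequence,
                              description = pf$description,
                              stringsAsFactors = FALSE)
    }
    list(spectra = spectra, truth = do.call(rbind, rows))
  })
}

#' Generate pure-noise MS/MS spectra (null model for FDR checks)
#'
#' Precursor m/z values are drawn near the masses of the supplied
#' peptidoforms (so the tolerance gate admits candidates) but the peak list
#' is uniform random noise.
#'
#' @param n number of spectra
#' @param peptidoforms peptidoforms whose masses seed the precursor draw
#' @param seed RNG seed
#' @param n_peaks noise peaks per spectrum
#' @param precursor_charge charge state
#' @return list of [spectrum()] objects
#' @export
gen_noise_spectra <- function(n, peptidoforms, seed = 1L, n_peaks = 60L,
                              precursor_charge = 2L) {
  .with_seed(seed, {
    masses <- vapply(peptidoforms, peptidoform_mass, numeric(1))
    lapply(seq_len(n), function(i) {
      m <- sample(masses, 1) * (1 + stats::rnorm(1, 0, 3) * 1e-6)
      pmz <- mz(m, precursor_charge)
      mzv <- stats::runif(n_peaks, 100, 1500)
      intv <- stats::rlnorm(n_peaks, meanlog = log(5e3), sdlog = 0.8)
      spectrum(sprintf("noise_%04d", i), pmz, precursor_charge, mzv, intv)
    })
  })
}

#' Generate a synthetic MS1 peak table from intact proteoforms
#'
#' For each proteoform, the exact isotope envelope (from
#' [isotope_envelope()]) is laid down at each charge state in
#' `charge_range`, abundance-scaled, with optional uniform-random noise
#' peaks.
#'
#' @param proteoforms named list of [proteoform()] objects
#' @param charge_range charge states (within 1..8)
#' @param seed RNG seed
#' @param noise_peaks number of random noise peaks
#' @param scale base intensity scale
#' @return list with `peaks` (data.frame scan, mz, intensity, sorted by mz
#'   within scan) and `truth` (data.frame: id, sequence, n_disulfides,
#'   amidated, monoisotopic_mass, charges)
#' @export
gen_ms1_run <- function(proteoforms, charge_range = 4:7, seed = 1L,
                        noise_peaks = 0L, scale = 1e6) {
  if (any(charge_range < 1) || any(charge_range > 8)) {
    stop("charge_range must lie within 1..8", call. = FALSE)
  }
  ids <- names(proteoforms)
  if (is.null(ids)) ids <- sprintf("proteoform_%d", seq_along(proteoforms))
  .with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_along(proteoforms)) {
      p <- proteoforms[[i]]
      env <- isotope_envelope(proteoform_composition(p), prune = 0.01)
      m0 <- monoisotopic_mass(p)
      for (z in charge_range) {
        abu <- scale * env$abundance * stats::runif(1, 0.5, 1.5)
        rows[[length(rows) + 1L]] <- data.frame(
          scan = 1L, mz = (env$mass + z * PROTON_MASS) / z, intensity = abu)
      }
      truth[[i]] <- data.frame(id = ids[i], sequence = p$sequence,
                               n_disulfides = p$n_disulfides,
                               amidated = p$c_amidated, monoisotopic_mass = m0,
                               charges = paste(charge_range, collapse = ","),
                               stringsAsFactors = FALSE)
    }
    if (noise_peaks > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        scan = 1L, mz = stats::runif(noise_peaks, 300, 2000),
        intensity = stats::rlnorm(noise_peaks, log(1e4), 1))
    }
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(peaks$scan, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks,
         truth = if (length(truth) > 0) do.call(rbind, truth) else NULL)
  })
}

# Place atom D at distance `r` from C, angle `theta` (deg) D-C-B, dihedral
# `chi` (deg) D-C-B-A (NeRF internal-to-Cartesian step).
.place_atom <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), -r * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build a polypeptide backbone from phi/psi angles
#'
#' Ideal bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 A;
#' trans peptide bonds), carbonyl O placed in the peptide plane.  Used for
#' turn-classification fixtures and toy scaffolds.
#'
#' @param seq protein sequence
#' @param phi,psi vectors of backbone dihedrals in degrees (length
#'   `nchar(seq)`; terminal undefined angles are ignored)
#' @return a [structure_model()] without side-chain atoms
#' @export
build_backbone <- function(seq, phi, psi) {
  chars <- .validate_protein(seq)
  n <- length(chars)
  stopifnot(length(phi) == n, length(psi) == n)
  atoms <- list()
  add <- function(resno, atom, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      resno = resno, atom = atom, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  # residue 1 seed geometry
  N1 <- c(0, 0, 0)
  CA1 <- c(1.458, 0, 0)
  C1 <- .place_atom(c(0, 1, 0), N1, CA1, 1.525, 111.2,
                    if (is.na(psi[1])) 180 else psi[1] + 0)  # orientation seed
  add(1L, "N", N1); add(1L, "CA", CA1); add(1L, "C", C1)
  prevN <- N1; prevCA <- CA1; prevC <- C1
  for (i in 2:n) {
    Ni <- .place_atom(prevN, prevCA, prevC, 1.329, 116.6,
                      if (is.na(psi[i - 1])) 180 else psi[i - 1])
    CAi <- .place_atom(prevCA, prevC, Ni, 1.458, 121.9, 180)  # omega trans
    Ci <- .place_atom(prevC, Ni, CAi, 1.525, 111.2,
                      if (is.na(phi[i])) 180 else phi[i])
    add(i, "N", Ni); add(i, "CA", CAi); add(i, "C", Ci)
    # carbonyl O of residue i-1: in the C(i-1) plane opposite N(i)
    Oprev <- .place_atom(Ni, prevCA, prevC, 1.231, 120.5, 180)
    add(i - 1L, "O", Oprev)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  # final O: place using psi-dependent frame
  Ofin <- .place_atom(prevN, prevCA, prevC, 1.231, 120.5,
                      if (is.na(psi[n])) 0 else psi[n] + 180)
  add(n, "O", Ofin)
  structure_model(
    residues = data.frame(index = seq_len(n), aa = chars,
                          stringsAsFactors = FALSE),
    atoms = do.call(rbind, atoms)
  )
}

#' Generate a toy 3D structure with pinned disulfide pairs
#'
#' Backbone built from randomised near-extended torsions; Sgamma atoms of
#' paired cysteines are placed 2.03 A apart midway between the partners'
#' Calpha positions, and Sgamma atoms of unpaired cysteines sit 1.8 A off
#' their own Calpha, guaranteed >= 5 A from every other Sgamma.  The
#' geometry is a fixture for disulfide detection, not a physical model.
#'
#' @param seq protein sequence
#' @param disulfide_pairs data.frame with `res_i`, `res_j` (1-based residue
#'   positions; must be Cys) or NULL
#' @param seed RNG seed
#' @return a [structure_model()] with SG atoms on cysteines
#' @export
gen_toy_structure <- function(seq, disulfide_pairs = NULL, seed = 1L) {
  chars <- .validate_protein(seq)
  n <- length(chars)
  if (!is.null(disulfide_pairs) && nrow(disulfide_pairs) > 0) {
    involved <- c(disulfide_pairs$res_i, disulfide_pairs$res_j)
    if (any(chars[involved] != "C")) {
      stop("disulfide pair references a non-Cys residue", call. = FALSE)
    }
    if (anyDuplicated(involved)) stop("a Cys appears in two pairs", call. = FALSE)
  }
  .with_seed(seed, {
    phi <- stats::runif(n, -150, -110)
    psi <- stats::runif(n, 110, 150)
    model <- build_backbone(seq, phi, psi)
    paired <- integer(0)
    if (!is.null(disulfide_pairs) && nrow(disulfide_pairs) > 0) {
      for (k in seq_len(nrow(disulfide_pairs))) {
        i <- disulfide_pairs$res_i[k]; j <- disulfide_pairs$res_j[k]
        cai <- .get_atom(model, i, "CA"); caj <- .get_atom(model, j, "CA")
        mid <- (cai + caj) / 2 + stats::runif(3, -0.2, 0.2)
        u <- caj - cai; u <- u / sqrt(sum(u^2))
        sgi <- mid - u * 1.015
        sgj <- mid + u * 1.015
        model$atoms <- rbind(model$atoms,
          data.frame(resno = c(i, j), atom = "SG",
                     x = c(sgi[1], sgj[1]), y = c(sgi[2], sgj[2]),
                     z = c(sgi[3], sgj[3]), stringsAsFactors = FALSE))
        paired <- c(paired, i, j)
      }
    }
    free_cys <- setdiff(which(chars == "C"), paired)
    for (r in free_cys) {
      ca <- .get_atom(model, r, "CA")
      sgr <- ca + c(0, 0, 8)   # well away from the backbone plane and all bonds
      model$atoms <- rbind(model$atoms,
        data.frame(resno = r, atom = "SG", x = sgr[1], y = sgr[2], z = sgr[3],
                   stringsAsFactors = FALSE))
    }
    model
  })
}
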