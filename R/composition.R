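#' Elemental compositions
#'
#' An elemental composition is a named integer vector over the elements
#' C, H, N, O, S.  Compositions are closed under addition and subtraction;
#' subtraction that would drive any count negative is an error.
#'
#' @param C,H,N,O,S non-negative integer atom counts
#' @return an object of class `elemental_composition`
#' @examples
#' composition(C = 2, H = 5, N = 1, O = 2)  # glycine + water
#' @export
composition <- function(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L) {
  x <- c(C = as.integer(C), H = as.integer(H), N = as.integer(N),
         O = as.integer(O), S = as.integer(S))
  if (any(x < 0)) stop("atom counts must be non-negative", call. = FALSE)
  structure(x, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x != 0]
  if (length(nz) == 0) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(nz), nz, collapse = " "), "\n")
  }
  invisible(x)
}

comp_add <- function(a, b) {
  composition(
    C = a[["C"]] + b[["C"]], H = a[["H"]] + b[["H"]], N = a[["N"]] + b[["N"]],
    O = a[["O"]] + b[["O"]], S = a[["S"]] + b[["S"]]
  )
}

comp_subtract <- function(a, b) {
  out <- unclass(a) - unclass(b)
  if (any(out < 0)) stop("composition subtraction would be negative", call. = FALSE)
  do.call(composition, as.list(out))
}

#' Elemental composition of an unmodified peptide
#'
#' Sum of residue formulas plus one water.
#'
#' @param seq protein sequence (canonical 20 letters)
#' @return an `elemental_composition`
#' @export
peptide_composition <- function(seq) {
  chars <- .validate_protein(seq)
  counts <- colSums(.RESIDUE_COMP[chars, , drop = FALSE])
  counts["H"] <- counts["H"] + 2L
  counts["O"] <- counts["O"] + 1L
  do.call(composition, as.list(counts))
}

#' Construct a proteoform
#'
#' A proteoform is a mature peptide sequence plus its PTM state: number of
#' disulfide bonds, C-terminal amidation, and fixed residue modifications.
#' Each disulfide removes two hydrogen atoms; amidation replaces the
#' C-terminal hydroxyl with an amine (-O +N +H, -0.984 Da).
#'
#' @param sequence protein sequence
#' @param n_disulfides number of intramolecular disulfide bonds
#' @param c_amidated logical, C-terminal amide
#' @param fixed_mods list of modification specs as returned by e.g.
#'   [mod_carbamidomethyl()]; each is applied to every matching residue
#' @return an object of class `proteoform`
#' @examples
#' p <- proteoform("CIQRHRSCRKSSECCGCSVCQCNLFGQNCQCKSGGLIAC",
#'                 n_disulfides = 5, c_amidated = TRUE)
#' monoisotopic_mass(p)
#' @export
proteoform <- function(sequence, n_disulfides = 0L, c_amidated = FALSE,
                       fixed_mods = list()) {
  chars <- .validate_protein(sequence)
  n_cys <- sum(chars == "C")
  if (2L * n_disulfides > n_cys) {
    stop(sprintf("%d disulfides require %d Cys but sequence has %d",
                 n_disulfides, 2L * n_disulfides, n_cys), call. = FALSE)
  }
  structure(
    list(sequence = sequence, n_disulfides = as.integer(n_disulfides),
         c_amidated = isTRUE(c_amidated), fixed_mods = fixed_mods),
    class = "proteoform"
  )
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("proteoform: %s\n  %d disulfide bond(s); C-terminal amide: %s\n",
              x$sequence, x$n_disulfides, x$c_amidated))
  if (length(x$fixed_mods) > 0) {
    cat("  fixed mods:", paste(vapply(x$fixed_mods, `[[`, "", "name"),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fixed/variable modification specifications
#'
#' `mod_carbamidomethyl()` is the iodoacetamide-induced +57.02146 Da
#' alkylation (composition +C2H3NO); by default on Cys, but over-alkylation
#' targets (M, H, K, W) can be requested for variable searches.
#' `mod_amidation()` is the C-terminal amide, recorded as a terminal (not
#' residue-site) modification with delta -0.9840 Da.
#'
#' @param residues residue letters the modification applies to
#' @return a modification spec list with fields `name`, `residues`, `delta`
#'   (Da) and `comp_delta` (signed per-element atom counts)
#' @export
mod_carbamidomethyl <- function(residues = "C") {
  list(name = "carbamidomethyl", residues = residues,
       delta = 57.02146, comp_delta = c(C = 2L, H = 3L, N = 1L, O = 1L, S = 0L))
}

#' @rdname mod_carbamidomethyl
#' @export
mod_amidation <- function() {
  list(name = "amidated", residues = character(0),
       delta = -(15.9949146221 - 14.0030740052 - 1.0078250319),
       comp_delta = c(C = 0L, H = 1L, N = 1L, O = -1L, S = 0L), terminal = "C")
}

AMIDATION_DELTA <- mod_amidation()$delta  # -0.9840156 Da

#' Elemental composition of a proteoform
#'
#' @param p a [proteoform()]
#' @return an `elemental_composition`
#' @export
proteoform_composition <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  counts <- as.numeric(unclass(peptide_composition(p$sequence)))
  names(counts) <- c("C", "H", "N", "O", "S")
  counts["H"] <- counts["H"] - 2L * p$n_disulfides
  if (p$c_amidated) {
    counts["O"] <- counts["O"] - 1L
    counts["N"] <- counts["N"] + 1L
    counts["H"] <- counts["H"] + 1L
  }
  for (m in p$fixed_mods) {
    nsite <- sum(chars %in% m$residues)
    if (nsite > 0) counts <- counts + nsite * m$comp_delta[names(counts)]
  }
  do.call(composition, as.list(counts))
}

#' Neutral monoisotopic mass
#'
#' For a proteoform: residue-mass sum + water, minus two hydrogen atoms per
#' disulfide bond, plus the amide delta (-0.9840 Da) if C-terminally
#' amidated, plus fixed-modification deltas.  For an elemental composition:
#' the sum over lightest-isotope masses.
#'
#' @param x a [proteoform()], an `elemental_composition`, or a plain
#'   protein sequence string
#' @return neutral monoisotopic mass in Da
#' @export
monoisotopic_mass <- function(x) UseMethod("monoisotopic_mass")

#' @export
monoisotopic_mass.character <- function(x) {
  chars <- .validate_protein(x)
  sum(.RESIDUE_MONO[chars]) + WATER_MASS
}

#' @export
monoisotopic_mass.proteoform <- function(x) {
  chars <- strsplit(x$sequence, "", fixed = TRUE)[[1]]
  m <- monoisotopic_mass.character(x$sequence) -
    2 * x$n_disulfides * H_ATOM_MASS +
    if (x$c_amidated) AMIDATION_DELTA else 0
  for (mod in x$fixed_mods) m <- m + sum(chars %in% mod$residues) * mod$delta
  m
}

#' @export
monoisotopic_mass.elemental_composition <- function(x) {
  lightest <- vapply(.ELEMENT_ISOTOPES, function(d) d$mass[1], numeric(1))
  sum(unclass(x) * lightest[names(x)])
}

#' Abundance-weighted average mass of a composition
#'
#' @param x an `elemental_composition`
#' @return average mass in Da
#' @export
average_mass <- function(x) {
  stopifnot(inherits(x, "elemental_composition"))
  avg <- vapply(.ELEMENT_ISOTOPES,
                function(d) sum(d$mass * d$abundance) / sum(d$abundance),
                numeric(1))
  sum(unclass(x) * avg[names(x)])
}

#' m/z of a neutral mass at a given positive charge
#'
#' @param neutral_mass neutral mass in Da
#' @param z charge state, positive integer
#' @return m/z (Da per elementary charge), protonation model
#' @examples
#' mz(1000, 2)  # 501.0036
#' @export
mz <- function(neutral_mass, z) {
  if (any(z <= 0) || any(z != as.integer(z))) {
    stop("charge z must be a positive integer", call. = FALSE)
  }
  (neutral_mass + z * PROTON_MASS) / z
}

# Convolve two unit-resolution isotope distributions (data.frames with
# offset / mass / abundance), aggregating by nominal offset.  Exact masses
# within an offset bin are abundance-weighted means.
.convolve_dist <- function(a, b) {
  off <- outer(a$offset, b$offset, `+`)
  ab <- outer(a$abundance, b$abundance)
  ms <- outer(a$mass, b$mass, `+`)
  key <- as.integer(off)
  tot <- tapply(as.numeric(ab), key, sum)
  wm <- tapply(as.numeric(ab * ms), key, sum) / tot
  data.frame(offset = as.integer(names(tot)), mass = as.numeric(wm),
             abundance = as.numeric(tot))
}

.dist_prune <- function(d, floor) {
  d <- d[d$abundance >= floor, , drop = FALSE]
  d[order(d$offset), , drop = FALSE]
}

# n-fold self-convolution by binary exponentiation.
.dist_power <- function(d, n, floor) {
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else
        .dist_prune(.convolve_dist(result, base), floor)
    }
    n <- n %/% 2
    if (n > 0) base <- .dist_prune(.convolve_dist(base, base), floor)
  }
  result
}

#' Isotope envelope of an elemental composition
#'
#' Exact polynomial convolution of the per-element isotope distributions,
#' aggregated at unit (nominal-offset) resolution -- the resolution at which
#' MS1 cluster peaks are read.  Offset 0 is the monoisotopic peak.
#'
#' @param comp an `elemental_composition` (or a [proteoform()], whose
#'   composition is derived first)
#' @param prune abundance floor in (0, 0.01]; isotopologue bins below it are
#'   dropped during and after convolution (abundances are not renormalised,
#'   so they sum to at most 1)
#' @return a data.frame of class `isotope_envelope` with columns `offset`
#'   (integer nominal offset from monoisotopic), `mass` (exact
#'   abundance-weighted mass in Da) and `abundance` (fraction in [0,1]),
#'   sorted by offset
#' @examples
#' env <- isotope_envelope(composition(C = 1))
#' env$abundance  # 0.9893, 0.0107
#' @export
isotope_envelope <- function(comp, prune = 1e-6) {
  if (inherits(comp, "proteoform")) comp <- proteoform_composition(comp)
  stopifnot(inherits(comp, "elemental_composition"))
  if (prune <= 0 || prune > 0.01) stop("prune must be in (0, 0.01]", call. = FALSE)
  counts <- unclass(comp)
  if (sum(counts) == 0) stop("empty composition", call. = FALSE)
  # keep a generous internal floor so pruning mid-convolution cannot bias
  # the retained bins at the requested floor
  inner_floor <- min(prune, 1e-9)
  total <- NULL
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    d <- .dist_power(.ELEMENT_ISOTOPES[[el]], counts[[el]], inner_floor)
    total <- if (is.null(total)) d else
      .dist_prune(.convolve_dist(total, d), inner_floor)
  }
  total <- .dist_prune(total, prune)
  rownames(total) <- NULL
  class(total) <- c("isotope_envelope", "data.frame")
  total
}

#' Most abundant isotopologue of an envelope
#'
#' @param env an `isotope_envelope`
#' @return one-row data.frame (offset, mass, abundance) of the apex peak
#' @export
envelope_apex <- function(env) {
  stopifnot(inherits(env, "isotope_envelope"))
  env[which.max(env$abundance), , drop = FALSE]
}
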