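#' Default precursor segmentation parameters
#'
#' The signal-peptide heuristic is a documented approximation (no HMM): the
#' signal length k is chosen in `signal_range` to maximise the mean
#' Kyte-Doolittle hydropathy of residues 5..k-5, subject to (a) a run of at
#' least `core_run` consecutive residues with hydropathy above `core_min`
#' inside positions 1..k (the hydrophobic h-core), and (b) small residues
#' (A/G/S/C) at positions k and k-2 (the von Heijne -1/-3 rule).
#'
#' The propeptide ends at the last residue of a processing quadruplet motif
#' -- three residues with at least one acidic (D/E) followed by Arg, cleaved
#' after the Arg -- occurring before the first cysteine of the mature region.
#'
#' @param signal_range candidate signal lengths (residues)
#' @param core_min per-residue Kyte-Doolittle threshold defining the h-core
#' @param core_run minimum h-core run length
#' @param small_residues residues accepted at the -1/-3 positions
#' @param min_mature minimum mature-region length
#' @return a named list of parameters for [segment_precursor()]
#' @export
segmentation_params <- function(signal_range = 15:30, core_min = 1.5,
                                core_run = 8L,
                                small_residues = c("A", "G", "S", "C"),
                                min_mature = 10L) {
  list(signal_range = signal_range, core_min = core_min,
       core_run = as.integer(core_run), small_residues = small_residues,
       min_mature = as.integer(min_mature))
}

.longest_run_above <- function(vals, threshold) {
  above <- vals > threshold
  if (!any(above)) return(0L)
  r <- rle(above)
  max(r$lengths[r$values])
}

.signal_length <- function(chars, params) {
  n <- length(chars)
  kd <- .KYTE_DOOLITTLE[chars]
  best_k <- NA_integer_
  best_score <- -Inf
  for (k in params$signal_range) {
    if (k + params$min_mature > n) break
    if (!(chars[k] %in% params$small_residues)) next
    if (!(chars[k - 2L] %in% params$small_residues)) next
    if (.longest_run_above(kd[seq_len(k)], params$core_min) < params$core_run) next
    core <- kd[5:(k - 5L)]
    score <- mean(core)
    if (score > best_score) {
      best_score <- score
      best_k <- k
    }
  }
  best_k
}

# Positions (1-based, within `chars`, restricted to `from..to`) of Arg
# residues completing a processing quadruplet motif: 3 preceding residues
# containing >= 1 acidic (D/E), cleavage after the Arg.
.quadruplet_ends <- function(chars, from, to) {
  ends <- integer(0)
  for (p in seq(max(from, 4L), to)) {
    if (chars[p] != "R") next
    if (any(chars[(p - 3L):(p - 1L)] %in% c("D", "E"))) ends <- c(ends, p)
  }
  ends
}

#' Segment a toxin precursor into signal / propeptide / mature / tail
#'
#' Applies the hydrophobic-core signal heuristic (see
#' [segmentation_params()]), locates the propeptide end at the last
#' processing-quadruplet Arg before the first mature-region cysteine, trims
#' a C-terminal amidation tail ([detect_amidation_tail()]), and returns a
#' precursor model whose four intervals partition the sequence.
#'
#' @param aa_sequence precursor protein sequence beginning with Met,
#'   length >= 30
#' @param params segmentation parameters from [segmentation_params()]
#' @return an object of class `precursor_model`: list with `aa_sequence`,
#'   1-based inclusive intervals `signal`, `propeptide` (possibly empty,
#'   encoded `c(NA, NA)`), `mature`, `amidation_tail` (possibly empty),
#'   logical `amidated`, and `mature_seq` (tail-trimmed mature sequence).
#'   Returns `NULL` with attribute-free reason via error when no plausible
#'   signal region exists.
#' @export
segment_precursor <- function(aa_sequence, params = segmentation_params()) {
  chars <- .validate_protein(aa_sequence)
  n <- length(chars)
  if (n < 30) stop("precursor too short to segment (< 30 aa)", call. = FALSE)
  if (chars[1] != "M") stop("precursor must begin with Met", call. = FALSE)

  k <- .signal_length(chars, params)
  if (is.na(k)) {
    stop(sprintf("no plausible signal region (reason: no k in %d..%d satisfies the h-core and -1/-3 constraints)",
                 min(params$signal_range), max(params$signal_range)),
         call. = FALSE)
  }

  first_cys <- which(chars == "C")
  first_cys <- first_cys[first_cys > k]
  search_to <- if (length(first_cys) > 0) first_cys[1] - 1L else n
  pro_end <- NA_integer_
  if (search_to > k) {
    ends <- .quadruplet_ends(chars, k + 1L, search_to)
    if (length(ends) > 0) pro_end <- max(ends)
  }

  mature_start <- if (is.na(pro_end)) k + 1L else pro_end + 1L
  tail_info <- detect_amidation_tail(substr(aa_sequence, mature_start, n))
  mature_end <- mature_start + nchar(tail_info$sequence) - 1L
  if (mature_end - mature_start + 1L < params$min_mature) {
    stop("mature region shorter than minimum length", call. = FALSE)
  }

  structure(list(
    aa_sequence = aa_sequence,
    signal = c(1L, k),
    propeptide = if (is.na(pro_end)) c(NA_integer_, NA_integer_) else c(k + 1L, pro_end),
    mature = c(mature_start, mature_end),
    amidation_tail = if (tail_info$tail_length > 0) c(mature_end + 1L, n) else c(NA_integer_, NA_integer_),
    amidated = tail_info$amidated,
    mature_seq = tail_info$sequence
  ), class = "precursor_model")
}

#' @export
print.precursor_model <- function(x, ...) {
  fmt <- function(iv) if (anyNA(iv)) "-" else sprintf("%d-%d", iv[1], iv[2])
  cat(sprintf("precursor (%d aa): signal %s | propeptide %s | mature %s | tail %s%s\n",
              nchar(x$aa_sequence), fmt(x$signal), fmt(x$propeptide),
              fmt(x$mature), fmt(x$amidation_tail),
              if (x$amidated) " (amidated)" else ""))
  cat("mature:", x$mature_seq, "\n")
  invisible(x)
}

#' Detect and trim a C-terminal amidation signal
#'
#' Peptidylglycine alpha-amidation consumes a C-terminal glycine (the amide
#' donor) which, in toxin precursors, may be followed by up to two basic
#' residues removed by carboxypeptidase.  If the sequence ends in
#' Gly-(Lys|Arg){0,2} with at least one residue preceding the Gly, the tail
#' is removed and the product flagged amidated; otherwise the input is
#' returned unchanged.
#'
#' @param mature_candidate protein sequence, length >= 5
#' @return list with `sequence` (trimmed), `amidated` (logical),
#'   `tail_length` (0-3)
#' @examples
#' detect_amidation_tail("NLFGQNCQCKSGGLIACGKR")
#' @export
detect_amidation_tail <- function(mature_candidate) {
  if (nchar(mature_candidate) < 5) stop("sequence too short (< 5 aa)", call. = FALSE)
  m <- regexpr("G[KR]{0,2}$", mature_candidate)
  if (m > 1) {
    tail_len <- attr(m, "match.length")
    list(sequence = substr(mature_candidate, 1L, m - 1L),
         amidated = TRUE, tail_length = as.integer(tail_len))
  } else {
    list(sequence = mature_candidate, amidated = FALSE, tail_length = 0L)
  }
}

#' Cysteine framework of a mature peptide
#'
#' Records the ordered cysteine positions and a canonical spacing pattern:
#' the gap lengths before, between and after the cysteines, interleaved with
#' `C`.  For the Tbo-IT2-like arrangement the pattern reads
#' `0C6C5C0C1C2C1C6C1C7C0`.  The pattern round-trips to positions via
#' [parse_cys_pattern()].
#'
#' @param mature protein sequence
#' @return list of class `cys_framework`: `positions` (integer), `pattern`
#'   (string; empty when linear), `n_cys`, `linear` (TRUE when < 2 Cys),
#'   `mature_length`
#' @export
cys_framework <- function(mature) {
  chars <- .validate_protein(mature)
  pos <- which(chars == "C")
  n <- length(chars)
  if (length(pos) < 2) {
    return(structure(list(positions = pos, pattern = "", n_cys = length(pos),
                          linear = TRUE, mature_length = n),
                     class = "cys_framework"))
  }
  gaps <- c(pos[1] - 1L, diff(pos) - 1L, n - pos[length(pos)])
  pattern <- paste0(gaps[1], paste0("C", gaps[-1], collapse = ""))
  structure(list(positions = pos, pattern = pattern, n_cys = length(pos),
                 linear = FALSE, mature_length = n),
            class = "cys_framework")
}

#' @rdname cys_framework
#' @param pattern a spacing pattern produced by [cys_framework()]
#' @return for `parse_cys_pattern`: integer cysteine positions
#' @export
parse_cys_pattern <- function(pattern) {
  gaps <- as.integer(strsplit(pattern, "C", fixed = TRUE)[[1]])
  if (anyNA(gaps) || length(gaps) < 2) stop("malformed cysteine pattern", call. = FALSE)
  pos <- integer(length(gaps) - 1L)
  at <- 0L
  for (i in seq_len(length(gaps) - 1L)) {
    at <- at + gaps[i] + 1L
    pos[i] <- at
  }
  pos
}

#' @export
print.cys_framework <- function(x, ...) {
  if (x$linear) {
    cat(sprintf("linear peptide (%d Cys)\n", x$n_cys))
  } else {
    cat(sprintf("%d-Cys framework: %s\n  positions: %s\n", x$n_cys, x$pattern,
                paste(x$positions, collapse = ", ")))
  }
  invisible(x)
}
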