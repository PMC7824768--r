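#' Build a target-decoy search database from precursor models
#'
#' Emits one target entry per non-empty propeptide region and one per
#' mature region of every precursor, then appends one full-reversal decoy
#' per target (decoy count always equals target count).
#'
#' @param precursors named list of `precursor_model` objects (see
#'   [segment_precursor()])
#' @return data.frame of class `search_db` with columns `accession`,
#'   `sequence`, `kind` ("propeptide"/"mature"), `is_decoy`, `amidated`
#' @export
build_search_db <- function(precursors) {
  ids <- names(precursors)
  if (is.null(ids)) ids <- sprintf("precursor_%d", seq_along(precursors))
  rows <- list()
  for (i in seq_along(precursors)) {
    p <- precursors[[i]]
    if (is.null(p$mature_seq) || nchar(p$mature_seq) == 0) {
      stop(sprintf("precursor '%s' lacks a mature region", ids[i]), call. = FALSE)
    }
    if (!anyNA(p$propeptide)) {
      pro_seq <- substr(p$aa_sequence, p$propeptide[1], p$propeptide[2])
      rows[[length(rows) + 1L]] <- data.frame(
        accession = paste0(ids[i], "|pro"), sequence = pro_seq,
        kind = "propeptide", is_decoy = FALSE, amidated = FALSE,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      accession = paste0(ids[i], "|mat"), sequence = p$mature_seq,
      kind = "mature", is_decoy = FALSE, amidated = isTRUE(p$amidated),
      stringsAsFactors = FALSE)
  }
  targets <- do.call(rbind, rows)
  if (anyDuplicated(targets$accession)) stop("duplicate accessions in database", call. = FALSE)
  decoys <- targets
  decoys$accession <- paste0("DECOY_", targets$accession)
  decoys$sequence <- vapply(targets$sequence, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  decoys$is_decoy <- TRUE
  db <- rbind(targets, decoys)
  rownames(db) <- NULL
  class(db) <- c("search_db", "data.frame")
  db
}

#' Precompute the candidate peptidoform index for a database
#'
#' Digests every entry, enumerates modified forms, and returns a flat table
#' keyed by neutral monoisotopic mass for fast precursor-tolerance lookups.
#' C-terminal amidation is applied as a protein-level variable modification:
#' C-terminal peptides of amidated mature entries are emitted both with and
#' without the amide.
#'
#' @param db a `search_db`
#' @param enzyme,max_missed digestion settings (see [digest()])
#' @param fixed,variable,max_variable modification settings (see
#'   [apply_modifications()])
#' @param min_length minimum peptide length retained
#' @return list with `table` (data.frame accession, is_decoy, start, end,
#'   mass, n_var_mods, form_id) and `forms` (list of `peptidoform`s indexed
#'   by form_id), sorted by mass
#' @export
build_peptidoform_index <- function(db, enzyme = "trypsin", max_missed = 4L,
                                    fixed = list(mod_carbamidomethyl()),
                                    variable = list(), max_variable = 2L,
                                    min_length = 5L) {
  forms <- list()
  rows <- list()
  for (r in seq_len(nrow(db))) {
    entry <- db[r, ]
    pep <- digest(entry$sequence, enzyme, max_missed = max_missed)
    pep <- pep[nchar(pep$sequence) >= min_length, , drop = FALSE]
    for (k in seq_len(nrow(pep))) {
      amid_states <- FALSE
      if (entry$amidated && !entry$is_decoy && pep$end[k] == nchar(entry$sequence) &&
          entry$kind == "mature") {
        amid_states <- c(FALSE, TRUE)
      }
      # decoys of amidated matures: amide on the reversed C-terminal peptide,
      # keeping the target/decoy candidate space symmetric
      if (entry$amidated && entry$is_decoy && pep$end[k] == nchar(entry$sequence) &&
          entry$kind == "mature") {
        amid_states <- c(FALSE, TRUE)
      }
      for (am in amid_states) {
        pfs <- apply_modifications(pep$sequence[k], fixed = fixed,
                                   variable = variable,
                                   max_variable = max_variable,
                                   c_amidated = am)
        for (pf in pfs) {
          forms[[length(forms) + 1L]] <- pf
          rows[[length(rows) + 1L]] <- data.frame(
            accession = entry$accession, is_decoy = entry$is_decoy,
            start = pep$start[k], end = pep$end[k],
            missed_cleavages = pep$missed_cleavages[k],
            mass = peptidoform_mass(pf), n_var_mods = pf$n_var_mods,
            form_id = length(forms), stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$mass)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, forms = forms)
}

# Greedy one-peak-one-fragment matching in m/z order.  Both lists are
# walked once; a peak and a theoretical fragment are paired when within
# frag_tol, and each side is consumed at most once.
.match_fragments <- function(peak_mz, frag_mz, frag_tol) {
  fo <- order(frag_mz)
  fm <- frag_mz[fo]
  matched_frag <- integer(0)
  matched_peak <- integer(0)
  i <- 1L; j <- 1L
  np <- length(peak_mz); nf <- length(fm)
  while (i <= np && j <= nf) {
    d <- peak_mz[i] - fm[j]
    if (abs(d) <= frag_tol) {
      matched_peak <- c(matched_peak, i)
      matched_frag <- c(matched_frag, fo[j])
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(peaks = matched_peak, frags = matched_frag)
}

#' Hyperscore-style PSM score
#'
#' `log(n_b! * n_y!) + log(matched_intensity / total_intensity + eps)` with
#' `eps = 1e-6`: the factorial term rewards consistent series coverage, the
#' intensity term rewards explaining the signal.  Invariant to peak order
#' and to uniform intensity scaling.
#'
#' @param n_b,n_y matched b- and y-ion counts
#' @param matched_intensity,total_intensity summed intensities
#' @return numeric score
#' @export
hyperscore <- function(n_b, n_y, matched_intensity, total_intensity) {
  lfactorial(n_b) + lfactorial(n_y) +
    log(matched_intensity / max(total_intensity, .Machine$double.eps) + 1e-6)
}

#' Match one spectrum against the candidate index
#'
#' Candidates are peptidoforms whose theoretical precursor m/z lies within
#' `prec_tol_ppm` of the observed precursor at the observed charge.  Each is
#' scored by [hyperscore()] over greedily matched 1+ b/y fragments; the best
#' PSM is retained (ties: fewer variable modifications, then lexicographic
#' peptide).
#'
#' @param spec a [spectrum()]
#' @param index a peptidoform index from [build_peptidoform_index()]
#' @param prec_tol_ppm precursor tolerance in ppm
#' @param frag_tol_da fragment tolerance in Da
#' @return one-row data.frame PSM (spectrum_id, accession, sequence, start,
#'   end, missed_cleavages, amidated, description, score, n_matched,
#'   is_decoy) or NULL when no candidate falls in the window
#' @export
match_spectrum <- function(spec, index, prec_tol_ppm = 10, frag_tol_da = 0.02) {
  if (prec_tol_ppm <= 0 || frag_tol_da <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  tab <- index$table
  if (is.null(tab) || nrow(tab) == 0 || nrow(spec$peaks) == 0) return(NULL)
  z <- spec$precursor_charge
  obs_neutral <- spec$precursor_mz * z - z * PROTON_MASS
  tol <- obs_neutral * prec_tol_ppm * 1e-6
  lo <- findInterval(obs_neutral - tol, tab$mass) + 1L
  hi <- findInterval(obs_neutral + tol, tab$mass)
  if (hi < lo) return(NULL)
  total_int <- sum(spec$peaks$intensity)
  best <- NULL
  for (r in lo:hi) {
    pf <- index$forms[[tab$form_id[r]]]
    frags <- fragment_ions(pf, charges = 1L)
    mm <- .match_fragments(spec$peaks$mz, frags$mz, frag_tol_da)
    n_b <- sum(frags$series[mm$frags] == "b")
    n_y <- sum(frags$series[mm$frags] == "y")
    sc <- hyperscore(n_b, n_y, sum(spec$peaks$intensity[mm$peaks]), total_int)
    cand <- list(score = sc, n_matched = length(mm$frags), row = r,
                 n_var = tab$n_var_mods[r], seq = pf$sequence, desc = pf$description,
                 amidated = pf$c_amidated)
    if (is.null(best) ||
        sc > best$score ||
        (sc == best$score && (cand$n_var < best$n_var ||
                              (cand$n_var == best$n_var && cand$seq < best$seq)))) {
      best <- cand
    }
  }
  r <- best$row
  data.frame(
    spectrum_id = spec$id, accession = tab$accession[r], sequence = best$seq,
    start = tab$start[r], end = tab$end[r],
    missed_cleavages = tab$missed_cleavages[r], amidated = best$amidated,
    description = best$desc, score = best$score, n_matched = best$n_matched,
    is_decoy = tab$is_decoy[r], stringsAsFactors = FALSE
  )
}

#' Search a set of spectra
#'
#' @param spectra list of [spectrum()] objects
#' @param index peptidoform index
#' @param ... passed to [match_spectrum()]
#' @return data.frame of best PSMs (one row per matched spectrum)
#' @export
search_spectra <- function(spectra, index, ...) {
  psms <- lapply(spectra, match_spectrum, index = index, ...)
  psms <- psms[!vapply(psms, is.null, logical(1))]
  if (length(psms) == 0) {
    return(data.frame(spectrum_id = character(0), accession = character(0),
                      sequence = character(0), start = integer(0), end = integer(0),
                      missed_cleavages = integer(0), amidated = logical(0),
                      description = character(0), score = numeric(0),
                      n_matched = integer(0), is_decoy = logical(0)))
  }
  out <- do.call(rbind, psms)
  rownames(out) <- NULL
  out
}

#' Target-decoy FDR filtering at the PSM level
#'
#' For every score threshold t, FDR(t) = #decoys >= t / max(1, #targets
#' >= t); the q-value of a PSM is the minimum FDR over all thresholds at or
#' below its score (monotonized).  Targets with q <= alpha are returned.
#'
#' @param psms PSM data.frame with `score` and `is_decoy`
#' @param alpha FDR threshold in (0, 0.5)
#' @return list with `accepted` (target PSMs with q <= alpha, q_value
#'   column added) and `all` (all PSMs with q-values)
#' @export
target_decoy_fdr <- function(psms, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)", call. = FALSE)
  if (nrow(psms) == 0) {
    psms$q_value <- numeric(0)
    return(list(accepted = psms, all = psms))
  }
  ord <- order(psms$score, decreasing = TRUE)
  x <- psms[ord, , drop = FALSE]
  n_decoy <- cumsum(x$is_decoy)
  n_target <- cumsum(!x$is_decoy)
  # PSMs sharing a score must share counts: take the counts at the last
  # index of each tied block
  fdr <- n_decoy / pmax(1, n_target)
  last_of_tie <- rev(!duplicated(rev(x$score)))
  block_fdr <- fdr
  block_fdr[!last_of_tie] <- NA
  block_fdr <- rev(cummin_na(rev(block_fdr)))  # fill ties from block end
  q <- rev(cummin(rev(block_fdr)))             # monotonize from the bottom
  x$q_value <- pmin(q, 1)
  accepted <- x[!x$is_decoy & x$q_value <= alpha, , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted, all = x)
}

# cummin that propagates the last non-NA value into NA slots (used to share
# a tied block's FDR, computed at the block end, with every member)
cummin_na <- function(v) {
  cur <- Inf
  for (i in seq_along(v)) {
    if (!is.na(v[i])) cur <- v[i]
    v[i] <- cur
  }
  v
}

#' Sequence coverage from accepted PSMs
#'
#' @param psms accepted PSM data.frame with `start`, `end` columns (one
#'   protein's PSMs)
#' @param protein_length parent protein length
#' @return list with `intervals` (data.frame start, end of merged covered
#'   runs), `covered` (residue count), `fraction`, and `peptides`
#'   (data.frame sequence, start, end, psm_count)
#' @export
sequence_coverage <- function(psms, protein_length) {
  if (nrow(psms) == 0) {
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                covered = 0L, fraction = 0,
                peptides = data.frame(sequence = character(0), start = integer(0),
                                      end = integer(0), psm_count = integer(0))))
  }
  if (any(psms$start < 1) || any(psms$end > protein_length)) {
    stop("PSM coordinates outside protein", call. = FALSE)
  }
  mask <- logical(protein_length)
  for (i in seq_len(nrow(psms))) mask[psms$start[i]:psms$end[i]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  key <- paste(psms$sequence, psms$start, psms$end)
  cnt <- table(key)
  uniq <- !duplicated(key)
  peptides <- data.frame(sequence = psms$sequence[uniq], start = psms$start[uniq],
                         end = psms$end[uniq],
                         psm_count = as.integer(cnt[key[uniq]]),
                         stringsAsFactors = FALSE)
  peptides <- peptides[order(peptides$start, peptides$end), , drop = FALSE]
  rownames(peptides) <- NULL
  list(intervals = iv, covered = sum(mask), fraction = sum(mask) / protein_length,
       peptides = peptides)
}
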