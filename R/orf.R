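#' Find open reading frames in a transcript
#'
#' Scans the three forward frames (cDNA libraries are orientation-specific;
#' reverse-strand scanning is available behind `both_strands`) for
#' Met-initiated, stop-terminated reading frames.  Each ATG is paired with
#' the first in-frame stop codon downstream; the ORF coordinates cover the
#' coding region excluding the stop codon.  Candidate ORFs containing an
#' ambiguous base (N) are excluded.
#'
#' @param sequence DNA sequence string (A/C/G/T/N); characters outside this
#'   alphabet reject the record with a diagnostic
#' @param min_aa_len minimum protein length (>= 10 is typical for toxin
#'   screens; any value >= 1 is accepted for testing)
#' @param id transcript identifier carried into the output
#' @param both_strands also scan the three reverse-complement frames
#' @return data.frame with columns `transcript_id`, `frame` (0-2, with
#'   negative values for reverse frames when scanned), `start_nt`, `end_nt`
#'   (1-based inclusive, input-strand coordinates), `aa_sequence`
#' @examples
#' find_orfs("ATGGCATAA", min_aa_len = 1)
#' @export
find_orfs <- function(sequence, min_aa_len = 10L, id = "transcript",
                      both_strands = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty transcript sequence", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf("transcript '%s' rejected: non-DNA character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  out <- .scan_forward_frames(sequence, min_aa_len, id)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    rev_orfs <- .scan_forward_frames(rc, min_aa_len, id)
    if (nrow(rev_orfs) > 0) {
      n <- nchar(sequence)
      # map back to input-strand coordinates
      s <- rev_orfs$start_nt; e <- rev_orfs$end_nt
      rev_orfs$start_nt <- n - e + 1L
      rev_orfs$end_nt <- n - s + 1L
      rev_orfs$frame <- -(rev_orfs$frame + 1L)
      out <- rbind(out, rev_orfs)
    }
  }
  rownames(out) <- NULL
  out
}

.GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

.scan_forward_frames <- function(sequence, min_aa_len, id) {
  n <- nchar(sequence)
  res <- list()
  code <- Biostrings::GENETIC_CODE
  for (frame in 0:2) {
    if (n < frame + 3L) next
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(sequence, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% .GENETIC_CODE_STOPS
    stop_idx <- which(is_stop)
    for (si in which(is_start)) {
      downstream <- stop_idx[stop_idx > si]
      if (length(downstream) == 0) next
      ei <- downstream[1]
      aa_codons <- codons[si:(ei - 1L)]
      if (length(aa_codons) < min_aa_len) next
      if (any(grepl("N", aa_codons, fixed = TRUE))) next
      aa <- paste(code[aa_codons], collapse = "")
      res[[length(res) + 1L]] <- data.frame(
        transcript_id = id, frame = frame,
        start_nt = starts[si], end_nt = starts[ei - 1L] + 2L,
        aa_sequence = aa, stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0) {
    data.frame(transcript_id = character(0), frame = integer(0),
               start_nt = integer(0), end_nt = integer(0),
               aa_sequence = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, res)
  }
}

#' Find ORFs across a whole transcript library
#'
#' @param transcripts named character vector (names are transcript ids) or a
#'   `Biostrings::DNAStringSet`
#' @param ... passed to [find_orfs()]
#' @return combined ORF data.frame; transcripts with invalid characters are
#'   skipped with a warning naming the record
#' @export
find_orfs_library <- function(transcripts, ...) {
  if (inherits(transcripts, "DNAStringSet")) {
    transcripts <- stats::setNames(as.character(transcripts), names(transcripts))
  }
  ids <- names(transcripts)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("transcripts must carry unique names", call. = FALSE)
  }
  out <- lapply(ids, function(i) {
    tryCatch(find_orfs(transcripts[[i]], id = i, ...),
             error = function(e) {
               warning(conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(find_orfs("ATG", min_aa_len = 10L)[0, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
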