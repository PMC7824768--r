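#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings.  `read_fasta_dna` / `read_fasta_protein`
#' return named character vectors; `write_fasta` wraps sequences at 60
#' columns.
#'
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta_dna
#' @export
read_fasta_protein <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta_dna
#' @param seqs named character vector of sequences
#' @param type "dna" or "protein"
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an MGF (Mascot generic format) peak-list file
#'
#' Supports BEGIN/END IONS blocks with TITLE, PEPMASS, CHARGE and peak
#' lines (m/z, intensity).  Peaks are returned sorted by m/z.
#'
#' @param path MGF file path
#' @return list of spectra; each spectrum is a list with `id`,
#'   `precursor_mz`, `precursor_charge`, and `peaks` (data.frame mz,
#'   intensity)
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      id <- NA_character_; pmz <- NA_real_; z <- NA_integer_
      mzs <- numeric(0); ints <- numeric(0)
      i <- i + 1L
      while (i <= n && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          id <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "[ \t]")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          z <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (grepl("^[0-9]", ln)) {
          parts <- strsplit(ln, "[ \t]+")[[1]]
          mzs <- c(mzs, as.numeric(parts[1]))
          ints <- c(ints, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      ord <- order(mzs)
      spectra[[length(spectra) + 1L]] <- spectrum(
        id = if (is.na(id)) sprintf("spectrum_%d", length(spectra) + 1L) else id,
        precursor_mz = pmz, precursor_charge = z,
        mz = mzs[ord], intensity = ints[ord]
      )
    }
    i <- i + 1L
  }
  spectra
}

#' @rdname read_mgf
#' @param spectra list of spectrum objects (see [spectrum()])
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("%.5f %.2f", s$peaks$mz, s$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Construct a centroided spectrum
#'
#' @param id spectrum identifier
#' @param precursor_mz precursor m/z
#' @param precursor_charge precursor charge state
#' @param mz,intensity peak arrays; stored sorted by m/z
#' @return list of class `spectrum`
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  ord <- order(mz)
  structure(list(id = id, precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 peaks = data.frame(mz = mz[ord], intensity = intensity[ord])),
            class = "spectrum")
}

#' Minimal mzML subset reader
#'
#' Parses the subset of mzML needed for this pipeline: `<spectrum>` elements
#' with an MS level, 64-bit (or 32-bit) little-endian base64 m/z and
#' intensity arrays (zlib-compressed or not), and for MS2 spectra the
#' selected-ion m/z and charge state.  This is not a general mzML
#' implementation.
#'
#' @param path mzML file path
#' @return list with `ms1` (data.frame scan, mz, intensity) and `ms2` (list
#'   of [spectrum()] objects)
#' @export
read_mzml_subset <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  ms1_rows <- list()
  ms2 <- list()
  for (sp in specs) {
    id <- xml2::xml_attr(sp, "id")
    cv <- xml2::xml_find_all(sp, "./cvParam")
    accs <- xml2::xml_attr(cv, "accession")
    vals <- xml2::xml_attr(cv, "value")
    ms_level <- suppressWarnings(as.integer(vals[accs == "MS:1000511"][1]))
    arrays <- .decode_binary_arrays(sp)
    if (is.na(ms_level) || is.null(arrays)) next
    if (ms_level == 1L) {
      scan <- suppressWarnings(as.integer(sub(".*scan=(\\d+).*", "\\1", id)))
      ms1_rows[[length(ms1_rows) + 1L]] <- data.frame(
        scan = if (is.na(scan)) length(ms1_rows) + 1L else scan,
        mz = arrays$mz, intensity = arrays$intensity
      )
    } else if (ms_level == 2L) {
      ion <- xml2::xml_find_first(sp, ".//selectedIon")
      pmz <- NA_real_; z <- NA_integer_
      if (!inherits(ion, "xml_missing")) {
        icv <- xml2::xml_find_all(ion, "./cvParam")
        iacc <- xml2::xml_attr(icv, "accession")
        ival <- xml2::xml_attr(icv, "value")
        pmz <- suppressWarnings(as.numeric(ival[iacc == "MS:1000744"][1]))
        z <- suppressWarnings(as.integer(ival[iacc == "MS:1000041"][1]))
      }
      ms2[[length(ms2) + 1L]] <- spectrum(id, pmz, z, arrays$mz, arrays$intensity)
    }
  }
  list(
    ms1 = if (length(ms1_rows) > 0) do.call(rbind, ms1_rows) else
      data.frame(scan = integer(0), mz = numeric(0), intensity = numeric(0)),
    ms2 = ms2
  )
}

.decode_binary_arrays <- function(sp) {
  bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
  out <- list()
  for (b in bdas) {
    cv <- xml2::xml_find_all(b, "./cvParam")
    accs <- xml2::xml_attr(cv, "accession")
    is_mz <- "MS:1000514" %in% accs
    is_int <- "MS:1000515" %in% accs
    bits64 <- "MS:1000523" %in% accs
    zlibbed <- "MS:1000574" %in% accs
    raw64 <- xml2::xml_text(xml2::xml_find_first(b, "./binary"))
    bytes <- jsonlite::base64_dec(gsub("[[:space:]]", "", raw64))
    if (zlibbed) bytes <- memDecompress(bytes, type = "gzip")
    vals <- readBin(bytes, what = "double",
                    size = if (bits64) 8L else 4L,
                    n = length(bytes) %/% (if (bits64) 8L else 4L),
                    endian = "little")
    if (is_mz) out$mz <- vals
    if (is_int) out$intensity <- vals
  }
  if (is.null(out$mz) || is.null(out$intensity)) return(NULL)
  out
}

#' Read / write an MS1 peak table
#'
#' Tab-separated columns: scan, mz, intensity.
#'
#' @param path file path
#' @return data.frame with scan, mz, intensity
#' @export
read_ms1_table <- function(path) {
  utils::read.delim(path, colClasses = c("integer", "numeric", "numeric"))
}

#' @rdname read_ms1_table
#' @param peaks data.frame with scan, mz, intensity
#' @export
write_ms1_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate precursor annotations
#'
#' One row per precursor: id, region coordinates (1-based inclusive),
#' amidation flag and cysteine spacing pattern.  With `gff = TRUE`,
#' GFF3-like feature lines are returned instead.
#'
#' @param models named list of `precursor_model` objects
#' @param gff return GFF3-like feature lines (character vector)
#' @return data.frame (or character vector when `gff = TRUE`)
#' @export
annotation_table <- function(models, gff = FALSE) {
  ids <- names(models)
  if (is.null(ids)) ids <- sprintf("precursor_%d", seq_along(models))
  if (gff) {
    lines <- character(0)
    for (i in seq_along(models)) {
      m <- models[[i]]
      add <- function(type, iv) {
        if (anyNA(iv)) return(character(0))
        sprintf("%s\tvenomtk\t%s\t%d\t%d\t.\t+\t.\tID=%s_%s", ids[i], type,
                iv[1], iv[2], ids[i], type)
      }
      lines <- c(lines, add("signal_peptide", m$signal),
                 add("propeptide", m$propeptide), add("mature_peptide", m$mature),
                 add("amidation_tail", m$amidation_tail))
    }
    return(lines)
  }
  do.call(rbind, lapply(seq_along(models), function(i) {
    m <- models[[i]]
    fw <- cys_framework(m$mature_seq)
    iv <- function(x) if (anyNA(x)) "." else sprintf("%d-%d", x[1], x[2])
    data.frame(id = ids[i], signal = iv(m$signal), propeptide = iv(m$propeptide),
               mature = iv(m$mature), amidation_tail = iv(m$amidation_tail),
               amidated = m$amidated, cys_pattern = fw$pattern,
               mature_seq = m$mature_seq, stringsAsFactors = FALSE)
  }))
}
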