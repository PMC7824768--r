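#' Assemble overlapping synthetic-gene oligonucleotides
#'
#' Merges sense-strand fragments (reverse-strand oligos must be
#' reverse-complemented first, or passed via `rev`) by maximal
#' suffix-prefix overlap, in the given order.
#'
#' @param fwd character vector of sense-strand oligos, 5' to 3' order
#' @param rev character vector of antisense oligos (reverse-complemented
#'   before merging), ordered by their position along the gene
#' @param min_overlap minimum accepted overlap length
#' @return assembled DNA string
#' @export
assemble_oligos <- function(fwd, rev = character(0), min_overlap = 10L) {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frags <- c(toupper(gsub("[[:space:]]", "", fwd)),
             vapply(toupper(gsub("[[:space:]]", "", rev)), rc, "", USE.NAMES = FALSE))
  merge2 <- function(a, b) {
    for (k in seq(min(nchar(a), nchar(b)), min_overlap)) {
      if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) {
        return(paste0(a, substr(b, k + 1L, nchar(b))))
      }
    }
    stop("fragments do not overlap by at least ", min_overlap, " nt", call. = FALSE)
  }
  Reduce(merge2, frags)
}

#' The mature Tbo-IT2 peptide reconstructed from its synthetic gene
#'
#' Assembles the five published expression-construct oligonucleotides
#' (shipped in `inst/extdata/tbo_it2_oligos.fasta`), finds the open
#' reading frame, translates it, and removes the initiator Met that was
#' engineered for CNBr cleavage of the fusion protein.  The result is the
#' 39-residue mature toxin.
#'
#' @return protein sequence string (39 residues)
#' @examples
#' nchar(tbo_it2_mature())  # 39
#' @export
tbo_it2_mature <- function() {
  path <- system.file("extdata", "tbo_it2_oligos.fasta", package = "venomtk",
                      mustWork = TRUE)
  oligos <- read_fasta_dna(path)
  is_rev <- grepl("rev", names(oligos))
  gene <- assemble_oligos(fwd = oligos[!is_rev], rev = oligos[is_rev])
  orfs <- find_orfs(gene, min_aa_len = 10L, id = "tbo_it2_gene")
  if (nrow(orfs) == 0) stop("no ORF found in assembled gene", call. = FALSE)
  aa <- orfs$aa_sequence[which.max(nchar(orfs$aa_sequence))]
  sub("^M", "", aa)
}

#' The intact venom Tbo-IT2 proteoform
#'
#' The mature 39-mer with its five disulfide bonds and C-terminal amide.
#'
#' @return a [proteoform()]
#' @export
tbo_it2_proteoform <- function() {
  proteoform(tbo_it2_mature(), n_disulfides = 5L, c_amidated = TRUE)
}
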