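# Global (Needleman-Wunsch) identity between two mature peptides:
# match = 1, mismatch = 0, gap = -1; identity = matches / alignment length.
.pairwise_identity <- function(a, b) {
  aas <- .AA_LETTERS
  sm <- matrix(0, length(aas), length(aas), dimnames = list(aas, aas))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1,
    type = "global"
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Group mature toxin sequences into homologous families
#'
#' Single-linkage clustering on global pairwise identity (Needleman-Wunsch,
#' match 1 / mismatch 0 / gap -1; identity = matches / alignment length).
#' Two sequences may only be linked when they carry an identical number of
#' cysteines -- the cysteine scaffold is the family invariant.  The family
#' representative is the lexicographically smallest member, which makes the
#' result independent of input order.
#'
#' @param matures character vector of mature peptide sequences
#' @param identity_threshold linkage threshold in (0, 1]
#' @return list of `toxin_family` objects, each with `members`,
#'   `representative` and `framework` (the representative's
#'   [cys_framework()]); families ordered by representative
#' @export
group_families <- function(matures, identity_threshold = 0.7) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  }
  n <- length(matures)
  if (n == 0) return(list())
  ncys <- vapply(matures, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] == "C")
  }, integer(1))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (ncys[i] != ncys[j]) next
        if (matures[i] == matures[j] ||
            .pairwise_identity(matures[i], matures[j]) >= identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fams <- lapply(split(seq_len(n), roots), function(idx) {
    members <- sort(matures[idx])
    structure(list(members = members, representative = members[1],
                   framework = cys_framework(members[1])),
              class = "toxin_family")
  })
  fams <- fams[order(vapply(fams, `[[`, "", "representative"))]
  names(fams) <- NULL
  fams
}

#' @export
print.toxin_family <- function(x, ...) {
  cat(sprintf("toxin family: %d member(s), %d Cys\n  representative: %s\n",
              length(x$members), x$framework$n_cys, x$representative))
  invisible(x)
}
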