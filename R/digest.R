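.ENZYMES <- list(
  trypsin = list(residues = c("K", "R"), proline_rule = FALSE),
  gluc = list(residues = c("E", "D"), proline_rule = FALSE)
)

# Internal cleavage-site positions (cut AFTER these residues), excluding the
# final residue of the parent.
.cleavage_sites <- function(chars, enzyme, proline_rule = FALSE) {
  n <- length(chars)
  sites <- which(chars %in% .ENZYMES[[enzyme]]$residues)
  sites <- sites[sites < n]
  if (proline_rule && length(sites) > 0) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  sites
}

#' In-silico protease digestion
#'
#' Cleaves C-terminal to Lys/Arg (trypsin) or Glu/Asp (GluC; the enzyme
#' gains Asp specificity in ammonium bicarbonate buffer) and enumerates all
#' peptides with at most `max_missed` internal cleavage sites.  The
#' "no cleavage before proline" exception is off by default and available
#' via `proline_rule`.  Peptides ending at the parent C-terminus inherit the
#' parent's amidation state.
#'
#' @param parent a [proteoform()] or plain protein sequence
#' @param enzyme "trypsin" or "gluc"
#' @param max_missed maximum missed cleavages, 0..6
#' @param proline_rule suppress cleavage when the following residue is Pro
#' @return data.frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive parent coordinates), `missed_cleavages`, `c_amidated`
#' @examples
#' digest("CIQRHRSCRKSSECCGCSVCQCNLFGQNCQCKSGGLIAC", "trypsin", max_missed = 1)
#' @export
digest <- function(parent, enzyme, max_missed = 0L, proline_rule = FALSE) {
  if (!enzyme %in% names(.ENZYMES)) {
    stop(sprintf("unknown enzyme '%s'; supported: %s", enzyme,
                 paste(names(.ENZYMES), collapse = ", ")), call. = FALSE)
  }
  if (max_missed < 0 || max_missed > 6) stop("max_missed must be in 0..6", call. = FALSE)
  amidated <- FALSE
  if (inherits(parent, "proteoform")) {
    amidated <- parent$c_amidated
    parent <- parent$sequence
  }
  chars <- .validate_protein(parent)
  n <- length(chars)
  sites <- .cleavage_sites(chars, enzyme, proline_rule)
  bounds <- c(0L, sites, n)          # peptide i runs bounds[i]+1 .. bounds[i+1]
  npep <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(npep)) {
    for (j in i:min(npep, i + max_missed)) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(parent, s, e), start = s, end = e,
        missed_cleavages = j - i,
        c_amidated = amidated && e == n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate modified peptidoforms
#'
#' Applies fixed modifications to every matching residue and enumerates
#' variable modifications combinatorially over the remaining eligible sites
#' (sites already carrying a fixed modification are skipped), up to
#' `max_variable` per peptide.  The number of returned forms equals
#' `sum over k <= max_variable of choose(n_sites, k)`.
#'
#' @param sequence peptide sequence
#' @param fixed list of fixed modification specs (see
#'   [mod_carbamidomethyl()])
#' @param variable list of variable modification specs
#' @param max_variable maximum variable modifications per peptide, 0..4
#' @param c_amidated logical: the peptide carries a C-terminal amide
#'   (adds the amide delta to every form)
#' @return list of `peptidoform` objects: each has `sequence`,
#'   `site_deltas` (numeric per-residue mass deltas), `c_amidated`,
#'   `n_var_mods`, `delta_mass` (total), `description`
#' @export
apply_modifications <- function(sequence, fixed = list(), variable = list(),
                                max_variable = 2L, c_amidated = FALSE) {
  if (max_variable < 0 || max_variable > 4) {
    stop("max_variable must be in 0..4", call. = FALSE)
  }
  chars <- .validate_protein(sequence)
  L <- length(chars)
  site_deltas <- numeric(L)
  fixed_sites <- logical(L)
  desc_fixed <- character(0)
  for (m in fixed) {
    hits <- which(chars %in% m$residues)
    site_deltas[hits] <- site_deltas[hits] + m$delta
    fixed_sites[hits] <- TRUE
    if (length(hits) > 0) desc_fixed <- c(desc_fixed, sprintf("%s@%d", m$name, hits))
  }
  var_sites <- list()
  for (m in variable) {
    hits <- which(chars %in% m$residues & !fixed_sites)
    for (h in hits) var_sites[[length(var_sites) + 1L]] <- list(pos = h, mod = m)
  }
  nv <- length(var_sites)
  choose_sets <- list(integer(0))
  if (nv > 0 && max_variable > 0) {
    for (k in seq_len(min(nv, max_variable))) {
      combs <- utils::combn(nv, k, simplify = FALSE)
      choose_sets <- c(choose_sets, combs)
    }
  }
  lapply(choose_sets, function(set) {
    sd <- site_deltas
    desc <- desc_fixed
    for (s in set) {
      sd[var_sites[[s]]$pos] <- sd[var_sites[[s]]$pos] + var_sites[[s]]$mod$delta
      desc <- c(desc, sprintf("%s@%d", var_sites[[s]]$mod$name, var_sites[[s]]$pos))
    }
    structure(list(
      sequence = sequence, site_deltas = sd, c_amidated = c_amidated,
      n_var_mods = length(set),
      delta_mass = sum(sd) + if (c_amidated) AMIDATION_DELTA else 0,
      description = if (length(desc) == 0) "unmodified" else paste(desc, collapse = ";")
    ), class = "peptidoform")
  })
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' @param pf a `peptidoform` from [apply_modifications()]
#' @return neutral mass in Da
#' @export
peptidoform_mass <- function(pf) {
  monoisotopic_mass(pf$sequence) + pf$delta_mass
}

#' Theoretical b/y fragment ions
#'
#' Conventional definitions: the b_i ion is the N-terminal fragment of i
#' residues (neutral mass = residue + modification sum), the y_j ion the
#' C-terminal fragment of j residues (+ water, + the amide delta when the
#' peptidoform is C-terminally amidated).  m/z = (neutral + z * proton) / z.
#'
#' @param pf a `peptidoform` (or plain sequence, taken unmodified)
#' @param charges integer fragment charge states (default 1)
#' @return data.frame with `series` ("b"/"y"), `index` (1..L-1), `charge`,
#'   `mz`; 2 (L-1) |charges| rows
#' @examples
#' fragment_ions(apply_modifications("GG")[[1]])
#' @export
fragment_ions <- function(pf, charges = 1L) {
  if (is.character(pf)) pf <- apply_modifications(pf)[[1]]
  chars <- strsplit(pf$sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2) stop("peptide must have length >= 2", call. = FALSE)
  res_mass <- .RESIDUE_MONO[chars] + pf$site_deltas
  b_neutral <- cumsum(res_mass)[seq_len(L - 1L)]
  y_neutral <- cumsum(rev(res_mass))[seq_len(L - 1L)] + WATER_MASS +
    if (pf$c_amidated) AMIDATION_DELTA else 0
  rows <- lapply(charges, function(z) {
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = rep(seq_len(L - 1L), 2L),
      charge = z,
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Digest report in the style of a bottom-up identification table
#'
#' @param parent a [proteoform()] or sequence
#' @param enzymes character vector of enzyme names
#' @param max_missed maximum missed cleavages
#' @return data.frame with Enzyme, Peptide (with `-NH2` suffix on amidated
#'   peptides), `AA_from`, `AA_to`, `Missed_Cleavages`
#' @export
digest_table <- function(parent, enzymes = c("trypsin", "gluc"), max_missed = 4L) {
  rows <- lapply(enzymes, function(e) {
    d <- digest(parent, e, max_missed = max_missed)
    data.frame(Enzyme = e,
               Peptide = paste0(d$sequence, ifelse(d$c_amidated, "-NH2", "")),
               AA_from = d$start, AA_to = d$end,
               Missed_Cleavages = d$missed_cleavages, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
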