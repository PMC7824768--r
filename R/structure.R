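.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.AA1TO3 <- stats::setNames(names(.AA3TO1), .AA3TO1)

#' Construct a structure model
#'
#' A structure model holds ordered residues with backbone (N, CA, C, O) and,
#' for cysteines, side-chain Sgamma coordinates in Angstrom.
#'
#' @param residues data.frame with `index` (strictly increasing integer) and
#'   `aa` (one-letter code)
#' @param atoms data.frame with `resno`, `atom` (N/CA/C/O/SG), `x`, `y`, `z`
#' @return list of class `structure_model`
#' @export
structure_model <- function(residues, atoms) {
  if (is.unsorted(residues$index, strictly = TRUE)) {
    stop("residue indices must be strictly increasing", call. = FALSE)
  }
  for (i in seq_len(nrow(residues))) {
    have <- atoms$atom[atoms$resno == residues$index[i]]
    if (!all(c("N", "CA", "C", "O") %in% have)) {
      stop(sprintf("residue %d lacks a complete backbone", residues$index[i]),
           call. = FALSE)
    }
  }
  structure(list(residues = residues, atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure model: %d residues, %d atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

.get_atom <- function(model, resno, atom) {
  r <- model$atoms[model$atoms$resno == resno & model$atoms$atom == atom, ]
  if (nrow(r) == 0) return(NULL)
  c(r$x[1], r$y[1], r$z[1])
}

#' Read a PDB file (fixed-column ATOM records)
#'
#' Minimal reader for this package's needs: ATOM records of the first MODEL
#' (or a chosen one), altLoc blank or 'A', author residue numbering
#' preserved, one chain.  Atoms kept: N, CA, C, O and SG.
#'
#' @param path PDB file path
#' @param model_number which MODEL to read from multi-model (NMR) files
#' @return a [structure_model()]
#' @export
read_pdb_model <- function(path, model_number = 1L) {
  lines <- readLines(path)
  in_model <- 0L
  keep <- character(0)
  saw_model <- any(startsWith(lines, "MODEL"))
  for (ln in lines) {
    if (startsWith(ln, "MODEL")) in_model <- in_model + 1L
    if (startsWith(ln, "ATOM")) {
      if (!saw_model || in_model == model_number) keep <- c(keep, ln)
    }
    if (startsWith(ln, "ENDMDL") && saw_model && in_model >= model_number) break
  }
  if (length(keep) == 0) stop("no ATOM records found", call. = FALSE)
  atom_name <- trimws(substr(keep, 13, 16))
  altloc <- substr(keep, 17, 17)
  res3 <- trimws(substr(keep, 18, 20))
  resno <- as.integer(substr(keep, 23, 26))
  x <- as.numeric(substr(keep, 31, 38))
  y <- as.numeric(substr(keep, 39, 46))
  z <- as.numeric(substr(keep, 47, 54))
  ok <- altloc %in% c(" ", "A") & atom_name %in% c("N", "CA", "C", "O", "SG")
  atoms <- data.frame(resno = resno[ok], atom = atom_name[ok],
                      x = x[ok], y = y[ok], z = z[ok], stringsAsFactors = FALSE)
  uniq <- !duplicated(paste(resno, res3))
  residues <- data.frame(index = resno[uniq],
                         aa = unname(.AA3TO1[res3[uniq]]), stringsAsFactors = FALSE)
  residues <- residues[!is.na(residues$aa), , drop = FALSE]
  residues <- residues[order(residues$index), , drop = FALSE]
  rownames(residues) <- NULL
  structure_model(residues, atoms)
}

#' Write a structure model as PDB ATOM records
#'
#' @param model a [structure_model()]
#' @param path output path
#' @export
write_pdb_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_len(nrow(model$residues))) {
    resno <- model$residues$index[i]
    res3 <- .AA1TO3[model$residues$aa[i]]
    at <- model$atoms[model$atoms$resno == resno, , drop = FALSE]
    for (j in seq_len(nrow(at))) {
      serial <- serial + 1L
      name <- at$atom[j]
      writeLines(sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                         serial, name, res3, resno, at$x[j], at$y[j], at$z[j],
                         substr(name, 1, 1)), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Detect disulfide bonds from Sgamma geometry
#'
#' All cysteine pairs with an Sgamma-Sgamma distance at or below
#' `max_ss_dist` are considered; bonds are assigned greedily
#' shortest-distance-first so that every cysteine joins at most one bond.
#' Cysteines missing an Sgamma atom are skipped with a warning.
#'
#' @param model a [structure_model()]
#' @param max_ss_dist detection threshold in Angstrom (canonical S-S bond
#'   is about 2.05)
#' @return data.frame with `res_i`, `res_j` (residue indices, i < j) and
#'   `distance`
#' @export
detect_disulfides <- function(model, max_ss_dist = 2.5) {
  cys <- model$residues$index[model$residues$aa == "C"]
  sg <- list()
  for (r in cys) {
    p <- .get_atom(model, r, "SG")
    if (is.null(p)) {
      warning(sprintf("Cys %d has no SG atom; skipped", r), call. = FALSE)
    } else {
      sg[[as.character(r)]] <- p
    }
  }
  ids <- as.integer(names(sg))
  out <- data.frame(res_i = integer(0), res_j = integer(0), distance = numeric(0))
  if (length(ids) < 2) return(out)
  pairs <- utils::combn(seq_along(ids), 2)
  d <- apply(pairs, 2, function(p) sqrt(sum((sg[[p[1]]] - sg[[p[2]]])^2)))
  ord <- order(d)
  taken <- logical(length(ids))
  for (k in ord) {
    if (d[k] > max_ss_dist) break
    a <- pairs[1, k]; b <- pairs[2, k]
    if (taken[a] || taken[b]) next
    taken[a] <- taken[b] <- TRUE
    out <- rbind(out, data.frame(res_i = min(ids[a], ids[b]),
                                 res_j = max(ids[a], ids[b]), distance = d[k]))
  }
  out <- out[order(out$res_i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral angles
#'
#' @param model a [structure_model()]
#' @return data.frame with `index`, `phi`, `psi` (degrees; NA at termini)
#' @export
phi_psi <- function(model) {
  idx <- model$residues$index
  n <- length(idx)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- .get_atom(model, idx[i], "N"); CAi <- .get_atom(model, idx[i], "CA")
    Ci <- .get_atom(model, idx[i], "C")
    if (i > 1 && idx[i - 1] == idx[i] - 1L) {
      Cprev <- .get_atom(model, idx[i - 1], "C")
      if (!is.null(Cprev)) phi[i] <- .dihedral(Cprev, Ni, CAi, Ci)
    }
    if (i < n && idx[i + 1] == idx[i] + 1L) {
      Nnext <- .get_atom(model, idx[i + 1], "N")
      if (!is.null(Nnext)) psi[i] <- .dihedral(Ni, CAi, Ci, Nnext)
    }
  }
  data.frame(index = idx, phi = phi, psi = psi)
}

# Canonical beta-turn dihedrals (Hutchinson-Thornton convention):
# phi(i+1), psi(i+1), phi(i+2), psi(i+2).
.BETA_TURN_TYPES <- list(
  I    = c(-60, -30, -90, 0),
  `I'` = c(60, 30, 90, 0),
  II   = c(-60, 120, 80, 0),
  `II'`= c(60, -120, -80, 0),
  VIII = c(-60, -30, -120, 120)
)
# Canonical gamma-turn dihedrals at i+1: classic / inverse.
.GAMMA_TURN_TYPES <- list(gamma = c(75, -64), `inverse-gamma` = c(-79, 69))

.angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# A set of observed angles matches canonical values if every deviation is
# within `tol`, with at most one angle allowed up to `tol_one`.
.angles_match <- function(obs, canon, tol = 30, tol_one = 45) {
  d <- .angle_diff(obs, canon)
  sum(d > tol) <= 1 && all(d <= tol_one)
}

#' Classify beta- and gamma-turns from backbone geometry
#'
#' Beta-turns: four consecutive residues with Calpha(i)-Calpha(i+3) <= 7 A
#' whose central residues are not part of a continuing helix (three or more
#' consecutive residues in the alpha region); the type is assigned by
#' comparing (phi, psi) of i+1 and i+2 to canonical values within +/- 30
#' degrees (one angle may deviate up to 45); type IV when no canonical type
#' fits.  Gamma-turns: three consecutive residues typed from (phi, psi) of
#' i+1 against the classic / inverse canonical values.
#'
#' @param model a [structure_model()]
#' @return data.frame with `start`, `end` (residue indices), `kind`
#'   ("beta"/"gamma"), `type`
#' @export
classify_turns <- function(model) {
  pp <- phi_psi(model)
  idx <- model$residues$index
  n <- length(idx)
  if (n < 3) stop("need at least 3 consecutive residues", call. = FALSE)
  helical <- !is.na(pp$phi) & !is.na(pp$psi) &
    .angle_diff(pp$phi, -60) <= 30 & .angle_diff(pp$psi, -45) <= 30
  in_helix <- logical(n)
  r <- rle(helical)
  at <- 1L
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= 4) {
      in_helix[at:(at + r$lengths[k] - 1L)] <- TRUE
    }
    at <- at + r$lengths[k]
  }
  out <- list()
  for (i in seq_len(max(0, n - 3L))) {
    if (any(diff(idx[i:(i + 3L)]) != 1L)) next
    ca1 <- .get_atom(model, idx[i], "CA")
    ca4 <- .get_atom(model, idx[i + 3L], "CA")
    if (is.null(ca1) || is.null(ca4)) next
    if (sqrt(sum((ca1 - ca4)^2)) > 7) next
    if (in_helix[i + 1L] && in_helix[i + 2L]) next
    obs <- c(pp$phi[i + 1L], pp$psi[i + 1L], pp$phi[i + 2L], pp$psi[i + 2L])
    if (anyNA(obs)) next
    type <- "IV"
    best_dev <- Inf
    for (tn in names(.BETA_TURN_TYPES)) {
      canon <- .BETA_TURN_TYPES[[tn]]
      if (.angles_match(obs, canon)) {
        dev <- sum(.angle_diff(obs, canon))
        if (dev < best_dev) {
          best_dev <- dev
          type <- tn
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(start = idx[i], end = idx[i + 3L],
                                          kind = "beta", type = type,
                                          stringsAsFactors = FALSE)
  }
  for (i in seq_len(max(0, n - 2L))) {
    if (any(diff(idx[i:(i + 2L)]) != 1L)) next
    obs <- c(pp$phi[i + 1L], pp$psi[i + 1L])
    if (anyNA(obs)) next
    for (tn in names(.GAMMA_TURN_TYPES)) {
      if (.angles_match(obs, .GAMMA_TURN_TYPES[[tn]], tol = 30, tol_one = 45)) {
        out[[length(out) + 1L]] <- data.frame(start = idx[i], end = idx[i + 2L],
                                              kind = "gamma", type = tn,
                                              stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0), type = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Q structure-similarity score
#'
#' `Q = Nalgn^2 / ((1 + (RMSD/R0)^2) * Nres1 * Nres2)` with `R0 = 3` A:
#' alignment length rewarded, RMSD penalised, normalised by both chain
#' lengths so Q = 1 only for identical complete matches.
#'
#' @param nres1,nres2 chain lengths
#' @param nalgn aligned residue count (<= min(nres1, nres2))
#' @param rmsd superposition RMSD in Angstrom
#' @param r0 RMSD scale in Angstrom
#' @return Q in (0, 1]
#' @examples
#' q_score(34, 39, 33, 1.68)  # 0.63
#' @export
q_score <- function(nres1, nres2, nalgn, rmsd, r0 = 3.0) {
  if (nres1 <= 0 || nres2 <= 0) stop("chain lengths must be positive", call. = FALSE)
  if (nalgn > min(nres1, nres2)) stop("Nalgn exceeds a chain length", call. = FALSE)
  if (rmsd < 0) stop("RMSD must be non-negative", call. = FALSE)
  nalgn^2 / ((1 + (rmsd / r0)^2) * nres1 * nres2)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `coords_b` onto `coords_a` over
#' the given correspondence, via SVD of the covariance matrix with the
#' usual determinant correction against improper rotations.
#'
#' @param coords_a,coords_b numeric matrices (n x 3)
#' @param correspondence two-column integer matrix of matched row indices
#'   (defaults to identity when the matrices are conformable)
#' @return list with `rotation` (3x3), `translation` (length 3, applied as
#'   `coords %*% R + t`), `rmsd`, and `transformed` (all of `coords_b`
#'   mapped into frame a)
#' @export
superpose <- function(coords_a, coords_b, correspondence = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (is.null(correspondence)) {
    if (nrow(coords_a) != nrow(coords_b)) {
      stop("matrices not conformable; supply a correspondence", call. = FALSE)
    }
    correspondence <- cbind(seq_len(nrow(coords_a)), seq_len(nrow(coords_a)))
  }
  A <- coords_a[correspondence[, 1], , drop = FALSE]
  B <- coords_b[correspondence[, 2], , drop = FALSE]
  if (nrow(A) < 3) stop("need at least 3 corresponding pairs", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (any(svd(A0)$d[2] < 1e-9) || any(svd(B0)$d[2] < 1e-9)) {
    stop("degenerate (collinear) coordinate set", call. = FALSE)
  }
  H <- t(B0) %*% A0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- ca - as.numeric(cb %*% R)
  B_fit <- sweep(B %*% R, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((B_fit - A)^2)))
  transformed <- sweep(coords_b %*% R, 2, t_vec, `+`)
  list(rotation = R, translation = t_vec, rmsd = rmsd, transformed = transformed)
}

#' Classify inhibitor-cystine-knot (ICK) disulfide topology
#'
#' Searches all 3-subsets of the bonds; a subset is an ICK core when,
#' after ranking its six cysteines by sequence order, the connectivity is
#' (1-4)(2-5)(3-6) -- the abcabc pattern whose third bond threads the
#' macrocycle formed by the first two.  Remaining bonds are labelled
#' "C-terminal clamp" when one partner is the last cysteine of the
#' framework, "hairpin staple" when both partners lie strictly between the
#' core's rank-4 and rank-6 cysteines, and "other" otherwise.
#'
#' @param bonds data.frame with `res_i`, `res_j` (positions matching
#'   `cys_positions`)
#' @param cys_positions ordered cysteine positions of the framework
#' @return list with `has_core` (logical), `core` (data.frame of the three
#'   core bonds or NULL), `extras` (data.frame res_i, res_j, role)
#' @export
classify_ick <- function(bonds, cys_positions) {
  all_res <- c(bonds$res_i, bonds$res_j)
  if (!all(all_res %in% cys_positions)) {
    stop("bond residues must appear in cys_positions", call. = FALSE)
  }
  if (anyDuplicated(all_res)) {
    stop("duplicate cysteine usage across bonds", call. = FALSE)
  }
  nb <- nrow(bonds)
  core_idx <- NULL
  if (nb >= 3) {
    for (sub in utils::combn(nb, 3, simplify = FALSE)) {
      res6 <- sort(c(bonds$res_i[sub], bonds$res_j[sub]))
      rank_of <- stats::setNames(seq_along(res6), res6)
      conn <- vapply(sub, function(b) {
        paste(sort(c(rank_of[[as.character(bonds$res_i[b])]],
                     rank_of[[as.character(bonds$res_j[b])]])), collapse = "-")
      }, "")
      if (setequal(conn, c("1-4", "2-5", "3-6"))) {
        core_idx <- sub
        break
      }
    }
  }
  if (is.null(core_idx)) {
    return(list(has_core = FALSE, core = NULL,
                extras = data.frame(res_i = bonds$res_i, res_j = bonds$res_j,
                                    role = rep("other", nb))))
  }
  core <- bonds[core_idx, c("res_i", "res_j"), drop = FALSE]
  rownames(core) <- NULL
  core6 <- sort(c(core$res_i, core$res_j))
  last_cys <- max(cys_positions)
  rest <- setdiff(seq_len(nb), core_idx)
  roles <- vapply(rest, function(b) {
    pr <- c(bonds$res_i[b], bonds$res_j[b])
    if (any(pr == last_cys)) return("C-terminal clamp")
    if (all(pr > core6[4] & pr < core6[6])) return("hairpin staple")
    "other"
  }, "")
  extras <- data.frame(res_i = bonds$res_i[rest], res_j = bonds$res_j[rest],
                       role = roles, stringsAsFactors = FALSE)
  rownames(extras) <- NULL
  list(has_core = TRUE, core = core, extras = extras)
}

#' NOE distance calibration
#'
#' Upper interproton distance limits from the r^-6 dependence of NOESY
#' cross-peak intensities: `d = ref_distance * (ref_intensity /
#' intensity)^(1/6)`, clipped to the 2.0-6.0 A range meaningful for NOE
#' restraints.
#'
#' @param intensity observed cross-peak intensity (> 0)
#' @param ref_intensity reference cross-peak intensity (> 0)
#' @param ref_distance reference distance in Angstrom
#' @param clip lower/upper clip bounds in Angstrom
#' @return upper distance limit in Angstrom
#' @export
noe_calibrate <- function(intensity, ref_intensity, ref_distance,
                          clip = c(2.0, 6.0)) {
  if (any(intensity <= 0) || any(ref_intensity <= 0) || any(ref_distance <= 0)) {
    stop("intensities and distances must be positive", call. = FALSE)
  }
  d <- ref_distance * (ref_intensity / intensity)^(1 / 6)
  pmin(pmax(d, clip[1]), clip[2])
}

#' Disulfide restraints for structure calculation
#'
#' The conventional annealing scheme: per bond, three upper and three lower
#' bounds -- Sgamma(i)-Sgamma(j) in [2.0, 2.1] A, Cbeta(i)-Sgamma(j) and
#' Sgamma(i)-Cbeta(j) in [3.0, 3.1] A.  Five bonds therefore yield 15 upper
#' and 15 lower restraints.
#'
#' @param bonds data.frame with `res_i`, `res_j`
#' @return data.frame of class `restraint_set` with `atom1`, `atom2`,
#'   `lower`, `upper`, `kind`
#' @export
disulfide_restraints <- function(bonds) {
  if (nrow(bonds) == 0) stop("bonds must be non-empty", call. = FALSE)
  rows <- lapply(seq_len(nrow(bonds)), function(k) {
    i <- bonds$res_i[k]; j <- bonds$res_j[k]
    data.frame(
      atom1 = c(sprintf("%d:SG", i), sprintf("%d:CB", i), sprintf("%d:SG", i)),
      atom2 = c(sprintf("%d:SG", j), sprintf("%d:SG", j), sprintf("%d:CB", j)),
      lower = c(2.0, 3.0, 3.0), upper = c(2.1, 3.1, 3.1),
      kind = "disulfide", stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write restraints in a CYANA-like three-column layout
#'
#' One line per bound: atom1, atom2, distance; upper bounds first, then
#' lower bounds.
#'
#' @param restraints a `restraint_set`
#' @param path output path
#' @export
write_restraints <- function(restraints, path) {
  up <- sprintf("%-10s %-10s %6.2f", restraints$atom1, restraints$atom2,
                restraints$upper)
  lo <- sprintf("%-10s %-10s %6.2f", restraints$atom1, restraints$atom2,
                restraints$lower)
  writeLines(c("# upper bounds", up, "# lower bounds", lo), path)
  invisible(path)
}

#' Sliding-window hydrophobicity profile (Wimley-White interface scale)
#'
#' Per-residue mean of the interface-scale free energies over a centred
#' window; window positions extending past the termini are truncated.
#' Negative values indicate membrane-interface-favourable (hydrophobic)
#' stretches.
#'
#' @param seq protein sequence
#' @param window odd window width <= sequence length
#' @return numeric vector, one value per residue (kcal/mol)
#' @export
hydrophobicity_profile <- function(seq, window = 5L) {
  chars <- .validate_protein(seq)
  n <- length(chars)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > n) stop("window exceeds sequence length", call. = FALSE)
  vals <- .WIMLEY_WHITE_INTERFACE[chars]
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(vals[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Simplified antiparallel beta-strand detection
#'
#' Flags residue pairs whose backbone N and O atoms form reciprocal
#' hydrogen bonds (N-O distance <= `hbond_dist`) with |i - j| >= 3, the
#' signature of an antiparallel sheet.  This is a geometric approximation,
#' not DSSP.
#'
#' @param model a [structure_model()]
#' @param hbond_dist N-O hydrogen-bond distance cutoff in Angstrom
#' @return data.frame of paired residues (`res_i`, `res_j`)
#' @export
detect_sheet_pairs <- function(model, hbond_dist = 3.5) {
  idx <- model$residues$index
  out <- data.frame(res_i = integer(0), res_j = integer(0))
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (idx[b] - idx[a] < 3) next
      Na <- .get_atom(model, idx[a], "N"); Oa <- .get_atom(model, idx[a], "O")
      Nb <- .get_atom(model, idx[b], "N"); Ob <- .get_atom(model, idx[b], "O")
      if (is.null(Na) || is.null(Oa) || is.null(Nb) || is.null(Ob)) next
      if (sqrt(sum((Na - Ob)^2)) <= hbond_dist &&
          sqrt(sum((Nb - Oa)^2)) <= hbond_dist) {
        out <- rbind(out, data.frame(res_i = idx[a], res_j = idx[b]))
      }
    }
  }
  out
}
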