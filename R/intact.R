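#' Detect isotope clusters in an MS1 peak list
#'
#' Greedy longest-run-first grouping: for every unused peak and every charge
#' z in `charges`, a run is grown by repeatedly looking for an unused peak
#' at the expected 13C spacing (1.00336 / z) within `spacing_tol`; the
#' longest run over all (start, z) pairs is committed, its peaks consumed,
#' and the search repeats.  Charge is assigned from the spacing that
#' produced the run; the monoisotopic m/z is the first peak of the run.
#'
#' @param peaks data.frame with `mz` and `intensity`, sorted by m/z (a
#'   `scan` column is ignored; detect per scan and aggregate upstream)
#' @param min_peaks minimum peaks per cluster; shorter runs are discarded
#' @param spacing_tol tolerance on the peak spacing in Da
#' @param charges charge states to consider
#' @return list of `isotope_cluster` objects: `charge`, `monoisotopic_mz`,
#'   `peaks` (data.frame mz, intensity), `apex` (index of the most intense
#'   peak), `neutral_mass`
#' @export
detect_clusters <- function(peaks, min_peaks = 3L, spacing_tol = 0.01,
                            charges = 1:8) {
  if (is.unsorted(peaks$mz)) stop("peaks must be sorted by m/z", call. = FALSE)
  n <- nrow(peaks)
  used <- logical(n)
  clusters <- list()
  repeat {
    best_run <- NULL
    avail <- which(!used)
    if (length(avail) == 0) break
    for (z in charges) {
      step <- C13_SPACING / z
      for (s in avail) {
        run <- s
        cur_mz <- peaks$mz[s]
        repeat {
          target <- cur_mz + step
          cand <- which(!used & abs(peaks$mz - target) <= spacing_tol)
          if (length(cand) == 0) break
          nxt <- cand[which.min(abs(peaks$mz[cand] - target))]
          run <- c(run, nxt)
          cur_mz <- peaks$mz[nxt]
        }
        if (is.null(best_run) || length(run) > length(best_run$idx)) {
          best_run <- list(idx = run, z = z)
        }
      }
    }
    if (is.null(best_run) || length(best_run$idx) < min_peaks) break
    idx <- best_run$idx
    used[idx] <- TRUE
    pk <- peaks[idx, c("mz", "intensity"), drop = FALSE]
    rownames(pk) <- NULL
    z <- best_run$z
    clusters[[length(clusters) + 1L]] <- structure(list(
      charge = z, monoisotopic_mz = pk$mz[1], peaks = pk,
      apex = which.max(pk$intensity),
      neutral_mass = pk$mz[1] * z - z * PROTON_MASS
    ), class = "isotope_cluster")
  }
  clusters
}

#' @export
print.isotope_cluster <- function(x, ...) {
  cat(sprintf("isotope cluster: z=%d, mono m/z %.4f (neutral %.4f Da), %d peaks, apex +%d\n",
              x$charge, x$monoisotopic_mz, x$neutral_mass, nrow(x$peaks),
              x$apex - 1L))
  invisible(x)
}

# Exhaustive (n_disulfides x amidation) hypothesis grid for a sequence.
proteoform_hypotheses <- function(sequence, fixed_mods = list()) {
  n_cys <- sum(strsplit(sequence, "", fixed = TRUE)[[1]] == "C")
  grid <- expand.grid(n_ss = 0:(n_cys %/% 2), amidated = c(FALSE, TRUE))
  lapply(seq_len(nrow(grid)), function(i) {
    proteoform(sequence, n_disulfides = grid$n_ss[i],
               c_amidated = grid$amidated[i], fixed_mods = fixed_mods)
  })
}

#' Match isotope clusters to intact proteoform hypotheses
#'
#' For every candidate sequence, an exhaustive hypothesis grid over
#' disulfide count (0..floor(nCys/2)) and C-terminal amidation is scored
#' against the clusters' inferred neutral monoisotopic masses.  The best
#' hypothesis per sequence (smallest mean absolute ppm error over matching
#' clusters) is reported; sequences with no hypothesis within `tol_ppm`
#' are reported unmatched.
#'
#' @param clusters list of `isotope_cluster`s (possibly pooled over scans)
#' @param candidates named character vector of candidate sequences
#' @param tol_ppm mass tolerance in ppm (<= 20)
#' @param fixed_mods fixed modifications applied to every hypothesis
#' @return data.frame with one row per candidate: `id`, `sequence`,
#'   `matched`, `n_disulfides`, `amidated`, `theoretical_mass`,
#'   `observed_mass` (intensity-weighted mean over matched clusters),
#'   `ppm_error`, `n_charge_states`, `charges`
#' @export
match_intact <- function(clusters, candidates, tol_ppm = 10,
                         fixed_mods = list()) {
  if (tol_ppm > 20) stop("tol_ppm must be <= 20", call. = FALSE)
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("candidate_%d", seq_along(candidates))
  cl_mass <- vapply(clusters, `[[`, numeric(1), "neutral_mass")
  cl_z <- vapply(clusters, function(c) as.numeric(c$charge), numeric(1))
  rows <- lapply(seq_along(candidates), function(i) {
    seq_i <- candidates[[i]]
    hyps <- proteoform_hypotheses(seq_i, fixed_mods)
    best <- NULL
    for (h in hyps) {
      m_theo <- monoisotopic_mass(h)
      if (length(cl_mass) > 0) {
        ppm <- (cl_mass - m_theo) / m_theo * 1e6
        hit <- which(abs(ppm) <= tol_ppm)
      } else {
        hit <- integer(0)
      }
      if (length(hit) == 0) next
      err <- mean(abs(ppm[hit]))
      if (is.null(best) || err < best$err) {
        best <- list(h = h, hit = hit, err = err, m_theo = m_theo,
                     ppm = mean(ppm[hit]))
      }
    }
    if (is.null(best)) {
      data.frame(id = ids[i], sequence = seq_i, matched = FALSE,
                 n_disulfides = NA_integer_, amidated = NA,
                 theoretical_mass = NA_real_, observed_mass = NA_real_,
                 ppm_error = NA_real_, n_charge_states = 0L, charges = "",
                 stringsAsFactors = FALSE)
    } else {
      zs <- sort(unique(cl_z[best$hit]))
      data.frame(id = ids[i], sequence = seq_i, matched = TRUE,
                 n_disulfides = best$h$n_disulfides, amidated = best$h$c_amidated,
                 theoretical_mass = best$m_theo,
                 observed_mass = mean(cl_mass[best$hit]),
                 ppm_error = best$ppm, n_charge_states = length(zs),
                 charges = paste(zs, collapse = ","), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
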