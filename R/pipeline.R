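#' Build a run configuration
#'
#' Validates and assembles the configuration for [run_pipeline()].  A YAML
#' file with the same field names can be loaded with [read_run_config()].
#'
#' @param transcripts_fasta path to transcript FASTA (DNA), or NULL
#' @param mgf paths to MGF MS/MS files (possibly per enzyme, named)
#' @param ms1_table path to a tab-separated MS1 peak table, or NULL
#' @param pdb path to a PDB file of a candidate toxin structure, or NULL
#' @param enzymes enzymes to search (one MGF per enzyme, in order)
#' @param prec_tol_ppm,frag_tol_da search tolerances
#' @param max_missed maximum missed cleavages
#' @param fdr_alpha PSM-level FDR threshold
#' @param max_variable maximum variable modifications per peptide
#' @param min_orf_aa minimum ORF length (amino acids)
#' @param intact_tol_ppm intact-match tolerance
#' @param seed RNG seed recorded with the run
#' @param out_dir output directory
#' @return validated config list of class `run_config`
#' @export
run_config <- function(transcripts_fasta = NULL, mgf = character(0),
                       ms1_table = NULL, pdb = NULL,
                       enzymes = c("trypsin", "gluc"),
                       prec_tol_ppm = 10, frag_tol_da = 0.02,
                       max_missed = 4L, fdr_alpha = 0.01, max_variable = 2L,
                       min_orf_aa = 40L, intact_tol_ppm = 10, seed = 1L,
                       out_dir = tempfile("venomtk_run_")) {
  stopifnot(prec_tol_ppm > 0, frag_tol_da > 0, fdr_alpha > 0, fdr_alpha < 0.5)
  if (!all(enzymes %in% c("trypsin", "gluc"))) {
    stop("enzymes must be among: trypsin, gluc", call. = FALSE)
  }
  for (p in c(transcripts_fasta, unname(mgf), ms1_table, pdb)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p, call. = FALSE)
  }
  if (length(mgf) > 0 && is.null(names(mgf))) {
    names(mgf) <- enzymes[seq_along(mgf)]
  }
  structure(list(
    transcripts_fasta = transcripts_fasta, mgf = mgf, ms1_table = ms1_table,
    pdb = pdb, enzymes = enzymes, prec_tol_ppm = prec_tol_ppm,
    frag_tol_da = frag_tol_da, max_missed = as.integer(max_missed),
    fdr_alpha = fdr_alpha, max_variable = as.integer(max_variable),
    min_orf_aa = as.integer(min_orf_aa), intact_tol_ppm = intact_tol_ppm,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML config path
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.log_stage <- function(log_con, ...) {
  msg <- sprintf(...)
  writeLines(msg, log_con)
  message(msg)
}

#' Run the full discovery pipeline
#'
#' annotate -> digest/search -> intact -> structure, producing a
#' consolidated per-toxin evidence table.  Amidation is called "confirmed"
#' only when proteomic evidence covers the C-terminus with the amide: an
#' accepted C-terminal peptide PSM carrying the amide, or an intact match
#' whose best hypothesis requires it.
#'
#' @param config a [run_config()]
#' @return list with `report` (per-toxin evidence data.frame), `psms`
#'   (accepted PSMs per enzyme), `intact` (intact matches), `structure`
#'   (disulfides/turn/ICK annotations or NULL), `out_dir`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))

  stage <- "annotate"
  result <- tryCatch({
    # -- annotate ---------------------------------------------------------
    models <- list()
    if (!is.null(config$transcripts_fasta)) {
      transcripts <- read_fasta_dna(config$transcripts_fasta)
      orfs <- find_orfs_library(transcripts, min_aa_len = config$min_orf_aa)
      .log_stage(log_con, "[annotate] %d transcripts, %d ORFs (min %d aa)",
                 length(transcripts), nrow(orfs), config$min_orf_aa)
      for (r in seq_len(nrow(orfs))) {
        m <- tryCatch(segment_precursor(orfs$aa_sequence[r]),
                      error = function(e) NULL)
        if (!is.null(m)) models[[orfs$transcript_id[r]]] <- m
      }
      .log_stage(log_con, "[annotate] %d precursors segmented", length(models))
      ann <- annotation_table(models)
      utils::write.table(ann, file.path(config$out_dir, "annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # -- search -----------------------------------------------------------
    stage <- "search"
    accepted <- list()
    if (length(config$mgf) > 0 && length(models) > 0) {
      db <- build_search_db(models)
      for (enz in names(config$mgf)) {
        spectra <- read_mgf(config$mgf[[enz]])
        index <- build_peptidoform_index(
          db, enzyme = enz, max_missed = config$max_missed,
          fixed = list(mod_carbamidomethyl()),
          variable = list(mod_carbamidomethyl(c("M", "H", "K", "W"))),
          max_variable = config$max_variable)
        psms <- search_spectra(spectra, index,
                               prec_tol_ppm = config$prec_tol_ppm,
                               frag_tol_da = config$frag_tol_da)
        flt <- target_decoy_fdr(psms, alpha = config$fdr_alpha)
        accepted[[enz]] <- flt$accepted
        .log_stage(log_con,
                   "[search:%s] %d spectra, %d PSMs, %d accepted at %.0f%% FDR (tol %g ppm / %g Da)",
                   enz, length(spectra), nrow(psms), nrow(flt$accepted),
                   100 * config$fdr_alpha, config$prec_tol_ppm, config$frag_tol_da)
        utils::write.table(flt$accepted,
                           file.path(config$out_dir, sprintf("psms_%s.tsv", enz)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    # -- intact -----------------------------------------------------------
    stage <- "intact"
    intact <- NULL
    if (!is.null(config$ms1_table) && length(models) > 0) {
      peaks <- read_ms1_table(config$ms1_table)
      clusters <- list()
      for (sc in unique(peaks$scan)) {
        pk <- peaks[peaks$scan == sc, , drop = FALSE]
        pk <- pk[order(pk$mz), , drop = FALSE]
        clusters <- c(clusters, detect_clusters(pk, min_peaks = 3L))
      }
      cand <- vapply(models, `[[`, "", "mature_seq")
      # the propeptides enter the candidate list too; their absence from the
      # venom is a reportable outcome, not an error
      pro <- vapply(models, function(m) {
        if (anyNA(m$propeptide)) "" else
          substr(m$aa_sequence, m$propeptide[1], m$propeptide[2])
      }, "")
      pro <- pro[nchar(pro) > 0]
      names(pro) <- paste0(names(pro), "|pro")
      intact <- match_intact(clusters, c(cand, pro),
                             tol_ppm = config$intact_tol_ppm)
      .log_stage(log_con, "[intact] %d clusters, %d/%d candidates matched",
                 length(clusters), sum(intact$matched), nrow(intact))
      utils::write.table(intact, file.path(config$out_dir, "intact.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # -- structure --------------------------------------------------------
    stage <- "structure"
    struct_ann <- NULL
    if (!is.null(config$pdb)) {
      model <- read_pdb_model(config$pdb)
      bonds <- detect_disulfides(model)
      seq_model <- paste(model$residues$aa, collapse = "")
      fw <- cys_framework(seq_model)
      ick <- if (nrow(bonds) >= 3)
        classify_ick(bonds, fw$positions) else list(has_core = FALSE)
      struct_ann <- list(disulfides = bonds, framework = fw, ick = ick,
                         turns = classify_turns(model))
      .log_stage(log_con, "[structure] %d disulfides, ICK core: %s",
                 nrow(bonds), ick$has_core)
    }

    # -- consolidated report ---------------------------------------------
    stage <- "report"
    rows <- lapply(names(models), function(id) {
      m <- models[[id]]
      acc <- paste0(id, "|mat")
      pep_rows <- do.call(rbind, lapply(names(accepted), function(enz) {
        a <- accepted[[enz]]
        a <- a[a$accession == acc, , drop = FALSE]
        if (nrow(a) > 0) cbind(enzyme = enz, a) else NULL
      }))
      n_pep <- if (is.null(pep_rows)) 0L else
        length(unique(paste(pep_rows$sequence, pep_rows$start, pep_rows$end)))
      cterm_pep <- !is.null(pep_rows) &&
        any(pep_rows$end == nchar(m$mature_seq) & pep_rows$amidated)
      im <- if (!is.null(intact)) intact[intact$id == id, , drop = FALSE] else NULL
      intact_hit <- !is.null(im) && nrow(im) > 0 && im$matched[1]
      intact_amide <- intact_hit && isTRUE(im$amidated[1])
      data.frame(
        id = id, mature_seq = m$mature_seq,
        transcript_support = TRUE, n_unique_peptides = n_pep,
        n_psms = if (is.null(pep_rows)) 0L else nrow(pep_rows),
        intact_match = intact_hit,
        intact_hypothesis = if (intact_hit)
          sprintf("%dSS%s", im$n_disulfides[1],
                  if (im$amidated[1]) "+amide" else "") else "",
        intact_ppm = if (intact_hit) im$ppm_error[1] else NA_real_,
        intact_charge_states = if (intact_hit) im$n_charge_states[1] else 0L,
        amidation_confirmed = cterm_pep || intact_amide,
        stringsAsFactors = FALSE
      )
    })
    report <- if (length(rows) > 0) do.call(rbind, rows) else NULL
    if (!is.null(report)) {
      utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .log_stage(log_con, "[report] %d toxins summarised", length(rows))
    list(report = report, psms = accepted, intact = intact,
         structure = struct_ann, out_dir = config$out_dir)
  }, error = function(e) {
    .log_stage(log_con, "[FAILED at stage %s] %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}
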