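#' Build a double-well model from two reference conformations
#'
#' Convenience constructor covering the standard build: native contacts for
#' each conformation, single-well potentials, optional ligand augmentation
#' of the closed well, and exponential mixing.
#'
#' @param open,closed reference [calpha_structure()]s (or a `toy_system`,
#'   passed as `open` with `closed` missing).
#' @param ligand_contacts optional 2-column matrix of pairs added to the
#'   closed potential only.
#' @param contact_scale contact energy multiplier (default 2.5; 1 gives the
#'   unscaled "weak" variant).
#' @param eps_O,beta_mix mixing parameters (see [double_well_model()]).
#' @param cutoff,min_separation contact rule.
#' @param dihedral_mult per-residue dihedral stiffness multipliers
#'   (named list/vector `residue -> multiplier`, e.g. glycine-like 0.2,
#'   proline-like 5), applied to both wells.
#' @param ... further arguments to [go_potential()].
#' @return a [double_well_model()].
#' @export
build_model <- function(open, closed = NULL, ligand_contacts = NULL,
                        contact_scale = 2.5, eps_O = 0, beta_mix = 0.1,
                        cutoff = 8.0, min_separation = 3L,
                        dihedral_mult = NULL, ...) {
  if (inherits(open, "toy_system")) {
    sys <- open
    if (is.null(ligand_contacts)) ligand_contacts <- sys$ligand_contacts
    closed <- sys$closed
    open <- sys$open
  }
  n <- nrow(open$xyz)
  mult <- rep(1, n)
  if (!is.null(dihedral_mult)) {
    idx <- as.integer(names(dihedral_mult))
    if (is.null(names(dihedral_mult)) || anyNA(idx))
      stop("dihedral_mult must be named by residue position")
    mult[idx] <- as.numeric(dihedral_mult)
  }
  co <- build_contacts(open, cutoff, min_separation)
  cc <- build_contacts(closed, cutoff, min_separation)
  pO <- go_potential(open, co, contact_scale = contact_scale,
                     dihedral_mult = mult, min_separation = min_separation,
                     ...)
  pC <- go_potential(closed, cc, contact_scale = contact_scale,
                     dihedral_mult = mult, min_separation = min_separation,
                     ...)
  if (!is.null(ligand_contacts) && nrow(ligand_contacts))
    pC <- add_ligand_contacts(pC, ligand_contacts, closed)
  double_well_model(pO, pC, eps_O = eps_O, beta_mix = beta_mix,
                    open = open, closed = closed)
}

#' Analyse a trajectory end to end
#'
#' Projection onto the reaction coordinates, basin identification,
#' transition-path extraction, separatrix optimisation, and O/TS/C
#' partitioning.
#'
#' @param model the [double_well_model()] sampled.
#' @param trajectory the [run_langevin()] result.
#' @param com_pairs,ratio,shared_native passed to [project()].
#' @param bins histogram bins for basin finding.
#' @param slopes,n_intercepts,band separatrix search grid.
#' @return list with `coords`, `basins`, `paths`, `separatrix`,
#'   `partition`.
#' @export
analyze_run <- function(model, trajectory, com_pairs = NULL, ratio = 1.1,
                        shared_native = "own", bins = 40L,
                        slopes = seq(-3, 3, length.out = 61),
                        n_intercepts = 41L, band = NULL) {
  coords <- project(trajectory, model, com_pairs = com_pairs,
                    ratio = ratio, shared_native = shared_native)
  basins <- find_basins(coords, bins = bins)
  paths <- transition_paths(basins)
  sep <- optimize_separatrix(coords, paths, basins, slopes = slopes,
                             n_intercepts = n_intercepts, band = band)
  part <- partition(coords, sep, paths)
  list(coords = coords, basins = basins, paths = paths, separatrix = sep,
       partition = part)
}

#' Configuration for an end-to-end pipeline run
#'
#' One run is one variant: wild type, heated (temperature change),
#' per-residue stiffness edits (`dihedral_mult`), or contact-scale edits.
#'
#' @param system a `toy_system` or list with `open`/`closed` structures.
#' @param ligand_contacts pairs added to the closed well (`NULL`: the toy
#'   system's own; `FALSE`: apo, none).
#' @param contact_scale,eps_O,beta_mix model constants.
#' @param calibrate_keq if non-`NULL`, calibrate `eps_O` to this target
#'   closed/open ratio before production.
#' @param sim production [simulation_config()].
#' @param calib_sim calibration-run config (default: `sim`).
#' @param dihedral_mult named per-residue stiffness multipliers.
#' @param ratio,delta,min_delta,display_floor analysis thresholds.
#' @param window_folded,window_rigid rotamer windows (degrees).
#' @param com_pairs domain pairs for rigid-body coordinates.
#' @return object of class `run_config`.
#' @export
run_config <- function(system, ligand_contacts = NULL, contact_scale = 2.5,
                       eps_O = 3.7, beta_mix = 0.1, calibrate_keq = NULL,
                       sim = simulation_config(), calib_sim = sim,
                       dihedral_mult = NULL, ratio = 1.1, delta = 0.2,
                       min_delta = 0.1, display_floor = 0.5,
                       window_folded = 60, window_rigid = 20,
                       com_pairs = NULL) {
  stopifnot(ratio > 0, delta > 0, min_delta > 0, display_floor > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Execute a full pipeline run
#'
#' Build, optionally calibrate, simulate, partition, and compute the
#' ensemble statistics: residue foldedness tables (60- and 20-degree
#' windows), classified contact-probability tables, rigid-body dispersions,
#' ensemble mean positions, and PMFs over (Q_O, Q_C) and the first
#' center-of-mass pair.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, tables and a plain-text
#'   report are written there.
#' @return object of class `pipeline_run`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  lig <- config$ligand_contacts
  if (isFALSE(lig)) lig <- matrix(integer(), 0, 2)
  model <- build_model(config$system, ligand_contacts = lig,
                       contact_scale = config$contact_scale,
                       eps_O = config$eps_O, beta_mix = config$beta_mix,
                       dihedral_mult = config$dihedral_mult)
  calib <- NULL
  if (!is.null(config$calibrate_keq)) {
    calib <- calibrate(model, config$calibrate_keq, config$calib_sim)
    model <- calib$model
  }
  traj <- run_langevin(model, config = config$sim)
  an <- analyze_run(model, traj, com_pairs = config$com_pairs,
                    ratio = config$ratio)
  part <- an$partition

  refs <- dihedral_reference(model$open, model$closed)
  angles <- pseudodihedrals_frames(traj$frames)
  res60 <- p_folded(angles, refs, part, window = config$window_folded)
  res20 <- p_folded(angles, refs, part, window = config$window_rigid)

  union_contacts <- rbind(
    model$partition$O_unique[, c("i", "j", "r0", "eps", "provenance")],
    model$partition$C_unique[, c("i", "j", "r0", "eps", "provenance")],
    all_contacts_for(model$partition, "C")[
      all_contacts_for(model$partition, "C")$provenance == "shared", ])
  ctab <- classify(contact_probabilities(traj$frames, union_contacts, part,
                                         ratio = config$ratio),
                   delta = config$delta,
                   display_floor = config$display_floor)

  rcm_cols <- grep("^r_cm_", names(an$coords), value = TRUE)
  disp <- lapply(rcm_cols, function(cl)
    dispersion(an$coords[[cl]], part$labels, "O"))
  names(disp) <- rcm_cols

  pmf_q <- pmf(an$coords$Q_O, an$coords$Q_C,
               temperature = config$sim$temperature,
               names = c("Q_O", "Q_C"))
  pmf_rcm <- if (length(rcm_cols) >= 1)
    pmf(an$coords[[rcm_cols[1]]],
        if (length(rcm_cols) >= 2) an$coords[[rcm_cols[2]]] else NULL,
        temperature = config$sim$temperature, names = rcm_cols)
  else NULL

  pos_args <- c(list(part), as.list(an$coords[c("Q_O", "Q_C", rcm_cols)]))
  positions <- do.call(ensemble_positions, pos_args)

  report <- list(K_eq = part$K_eq, p_TP = an$separatrix$p_TP,
                 n_transitions = an$paths$n_transitions,
                 sigma_O = vapply(disp, `[[`, 0, "sd"),
                 mean_O = vapply(disp, `[[`, 0, "mean"),
                 positions = positions,
                 model_hash = traj$model_hash, seed = config$sim$seed,
                 eps_O = model$eps_O, beta_mix = model$beta_mix)

  run <- structure(list(config = config, model = model, calibration = calib,
                        trajectory = traj, analysis = an,
                        residue_stats = res60, residue_stats_rigid = res20,
                        contact_stats = ctab, dispersions = disp,
                        pmf_q = pmf_q, pmf_rcm = pmf_rcm, report = report),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat("Pipeline run (seed ", r$seed, ", model ", r$model_hash, ")\n",
      sprintf("  K_eq = %.3g, p_TP = %.3f, %d transitions\n",
              r$K_eq, r$p_TP, r$n_transitions), sep = "")
  for (nm in names(r$sigma_O))
    cat(sprintf("  %s: O-ensemble mean %.2f A, sigma %.2f A\n",
                nm, r$mean_O[nm], r$sigma_O[nm]))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, nm)
    utils::write.table(df, file.path(out_dir, nm), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wtsv(run$analysis$coords, "coordinates.tsv")
  wtsv(data.frame(frame = seq_along(run$analysis$partition$labels),
                  label = run$analysis$partition$labels,
                  direction = run$analysis$partition$direction),
       "partition.tsv")
  wtsv(run$residue_stats, "residue_stats_60.tsv")
  wtsv(run$residue_stats_rigid, "residue_stats_20.tsv")
  wtsv(run$contact_stats, "contact_stats.tsv")
  wtsv(as.data.frame(run$pmf_q), "pmf_q.tsv")
  if (!is.null(run$pmf_rcm)) wtsv(as.data.frame(run$pmf_rcm), "pmf_rcm.tsv")
  r <- run$report
  writeLines(c(sprintf("model_hash %s", r$model_hash),
               sprintf("seed %d", r$seed),
               sprintf("eps_O %.6f", r$eps_O),
               sprintf("beta_mix %.6f", r$beta_mix),
               sprintf("K_eq %.6f", r$K_eq),
               sprintf("p_TP %.6f", r$p_TP),
               sprintf("n_transitions %d", r$n_transitions),
               sprintf("sigma_O %s %.6f", names(r$sigma_O), r$sigma_O)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Compare two pipeline runs
#'
#' Difference tables between a perturbed and a reference run: per-residue
#' foldedness differences, per-contact probability differences restricted
#' to contacts characteristic in either run, and the two (Q_O, Q_C) PMFs
#' side by side. Subtraction order is `runA - runB` (pass the perturbed run
#' first).
#'
#' @param runA,runB [run_pipeline()] results on structurally matched
#'   systems.
#' @param min_delta display threshold on `|delta p|`.
#' @return list with `residues` (delta p_folded), `contacts` (delta p), and
#'   `pmfs` (list of the two grids).
#' @export
compare_runs <- function(runA, runB, min_delta = 0.1) {
  if (nrow(runA$model$open$xyz) != nrow(runB$model$open$xyz))
    stop("runs have different system sizes")
  list(residues = compare(runA$residue_stats, runB$residue_stats,
                          min_delta = min_delta),
       contacts = compare(runA$contact_stats, runB$contact_stats,
                          min_delta = min_delta),
       pmfs = list(A = runA$pmf_q, B = runB$pmf_q))
}
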