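#' Locate the open and closed basins from the Q_C distribution
#'
#' The closed basin core sits at the high-Q_C mode of the histogram of
#' `Q_C`; the open core at the first (lowest-Q_C) local maximum. This
#' identification via `Q_C` is robust when the two wells are poorly
#' separated along `Q_O`. Core radii reach to the nearest histogram local
#' minimum between the modes, floored at two bin widths.
#'
#' @param tbl a `coordinate_table` from [project()], or any data.frame with
#'   `Q_O` and `Q_C` columns.
#' @param bins number of histogram bins.
#' @param min_frac local maxima below this fraction of the tallest bin are
#'   treated as noise.
#' @return object of class `basin_definition`: per-basin center (Q_O, Q_C),
#'   radius (in Q_C), and per-frame core membership (`in_O`, `in_C`).
#' @export
find_basins <- function(tbl, bins = 40L, min_frac = 0.05) {
  qc <- tbl$Q_C
  if (is.null(qc)) stop("table must contain Q_C")
  rng <- range(qc)
  if (diff(rng) < 1e-12)
    stop("Q_C distribution is degenerate; no transition sampled - ",
         "recalibrate beta_mix/eps_O")
  # a fraction-of-contacts coordinate over k contacts only takes k+1 levels;
  # never use more bins than distinct values or the histogram fragments
  bins <- min(bins, length(unique(round(qc, 9))))
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  width <- edges[2] - edges[1]
  cnt <- tabulate(pmin(pmax(findInterval(qc, edges, all.inside = TRUE), 1L),
                       bins), bins)
  sm <- stats::filter(cnt, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(cnt[1:2]); sm[bins] <- mean(cnt[(bins - 1):bins])
  sm <- as.numeric(sm)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  is_max <- vapply(seq_len(bins), function(b) {
    l <- if (b > 1) sm[b - 1] else -Inf
    r <- if (b < bins) sm[b + 1] else -Inf
    sm[b] > l && sm[b] >= r
  }, TRUE)
  peaks <- which(is_max & sm >= min_frac * max(sm))
  if (length(peaks) < 2L) {
    # a strongly unbalanced equilibrium puts the minority basin far below
    # min_frac of the main mode; accept any peak holding a non-trivial
    # absolute share of the frames
    floor_cnt <- max(5, 0.0025 * length(qc))
    peaks <- which(is_max & sm >= floor_cnt)
  }
  if (length(peaks) < 2L)
    stop("Q_C distribution is unimodal; no transition sampled - ",
         "recalibrate beta_mix/eps_O")
  bO <- peaks[1]; bC <- peaks[length(peaks)]
  between <- bO:bC
  bmin <- between[which.min(sm[between])]
  rO <- max(abs(centers[bmin] - centers[bO]) / 2, 2 * width)
  rC <- max(abs(centers[bmin] - centers[bC]) / 2, 2 * width)
  in_O <- abs(qc - centers[bO]) <= rO
  in_C <- abs(qc - centers[bC]) <= rC
  ov <- in_O & in_C
  if (any(ov)) { in_O[ov] <- FALSE; in_C[ov] <- FALSE }
  center_O <- c(Q_O = mean(tbl$Q_O[in_O]), Q_C = centers[bO])
  center_C <- c(Q_O = mean(tbl$Q_O[in_C]), Q_C = centers[bC])
  structure(list(center_O = center_O, center_C = center_C,
                 radius_O = rO, radius_C = rC,
                 in_O = in_O, in_C = in_C, method = "Q_C histogram modes"),
            class = "basin_definition")
}

#' @export
print.basin_definition <- function(x, ...) {
  cat(sprintf("Basins (by %s):\n  O core: Q_C = %.3f +- %.3f (%d frames)\n  C core: Q_C = %.3f +- %.3f (%d frames)\n",
              x$method, x$center_O["Q_C"], x$radius_O, sum(x$in_O),
              x$center_C["Q_C"], x$radius_C, sum(x$in_C)))
  invisible(x)
}

#' Extract reactive transition-path segments
#'
#' A transition path runs from the last frame inside one basin core to the
#' first frame inside the other core, with no intermediate return to the
#' origin core; excursions that re-enter the origin core are not reactive
#' and are discarded.
#'
#' @param basins a [find_basins()] result (or any list with logical `in_O`,
#'   `in_C` per frame).
#' @return object of class `transition_paths`: data.frame `segments`
#'   (`start`, `end`: first/last intermediate frame indices - `start >
#'   end` marks a direct core-to-core hop with no intermediate frames -
#'   and `direction`: `"closing"` for O to C), plus per-frame `on_path`
#'   logical and `direction` character vector.
#' @export
transition_paths <- function(basins) {
  in_O <- basins$in_O; in_C <- basins$in_C
  nf <- length(in_O)
  seg <- list()
  on_path <- logical(nf)
  dir_vec <- rep(NA_character_, nf)
  origin <- NA_character_
  exit_frame <- NA_integer_
  for (f in seq_len(nf)) {
    here <- if (in_O[f]) "O" else if (in_C[f]) "C" else NA_character_
    if (is.na(here)) next
    if (!is.na(origin) && here != origin) {
      s <- exit_frame + 1L; e <- f - 1L
      dir <- if (origin == "O") "closing" else "opening"
      seg[[length(seg) + 1L]] <- data.frame(start = s, end = e,
                                            direction = dir)
      if (e >= s) { on_path[s:e] <- TRUE; dir_vec[s:e] <- dir }
    }
    origin <- here
    exit_frame <- f
  }
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(start = integer(), end = integer(), direction = character())
  structure(list(segments = segments, on_path = on_path,
                 direction = dir_vec, n_transitions = nrow(segments)),
            class = "transition_paths")
}

#' @export
print.transition_paths <- function(x, ...) {
  cat("Transition paths: ", x$n_transitions, " crossings (",
      sum(x$segments$direction == "closing"), " closing, ",
      sum(x$segments$direction == "opening"), " opening), ",
      sum(x$on_path), " frames on paths\n", sep = "")
  invisible(x)
}

#' Find the p_TP-optimal separatrix line in (Q_O, Q_C) space
#'
#' Over a grid of lines `Q_C = m Q_O + b` that separate the two basin
#' centers, computes the transition-path probability of each line's band
#' (frames within perpendicular distance `band` of the line): the fraction
#' of band frames that lie on reactive transition paths. Returns the
#' maximising line. For diffusive dynamics p_TP is bounded by 0.5.
#'
#' @param tbl coordinate table with `Q_O`, `Q_C`.
#' @param paths a [transition_paths()] result.
#' @param basins a [find_basins()] result.
#' @param slopes slope grid.
#' @param n_intercepts intercept grid size (spanning the data).
#' @param band band half-width in Q units (perpendicular distance);
#'   default 0.02. `NULL` adapts the width to the coordinate resolution:
#'   a fraction-of-contacts coordinate over k contacts moves on a lattice
#'   of spacing 1/k, and the band must be able to capture a lattice column
#'   (`max(0.02, 0.55 * min lattice spacing)`).
#' @return object of class `separatrix`: `slope`, `intercept`, `band`,
#'   `p_TP`, per-frame `in_band` and `side` (+1 above the line, the closed
#'   side).
#' @export
optimize_separatrix <- function(tbl, paths, basins,
                                slopes = seq(-3, 3, length.out = 61),
                                n_intercepts = 41L, band = 0.02) {
  if (paths$n_transitions < 1L)
    stop("no transition paths; cannot place a separatrix")
  qo <- tbl$Q_O; qc <- tbl$Q_C
  if (is.null(band)) {
    spacing <- function(v) {
      u <- sort(unique(round(v, 9)))
      if (length(u) < 2L) return(Inf)
      min(diff(u))
    }
    band <- max(0.02, 0.55 * min(spacing(qo), spacing(qc)))
  }
  cO <- basins$center_O; cC <- basins$center_C
  best <- list(p = -1)
  any_band <- FALSE
  for (m in slopes) {
    r <- qc - m * qo
    rr <- range(r)
    if (diff(rr) < 1e-12) next
    for (b in seq(rr[1], rr[2], length.out = n_intercepts)) {
      sO <- cO["Q_C"] - m * cO["Q_O"] - b
      sC <- cC["Q_C"] - m * cC["Q_O"] - b
      if (!(sO < 0 && sC > 0)) next   # must separate the basin centers
      inb <- abs(r - b) / sqrt(1 + m^2) <= band
      nb <- sum(inb)
      if (!nb) next
      any_band <- TRUE
      p <- sum(paths$on_path[inb]) / nb
      if (p > best$p) best <- list(p = p, m = m, b = b)
    }
  }
  if (!any_band)
    stop("no frames fall within any candidate separatrix band")
  m <- best$m; b <- best$b
  r <- qc - m * qo - b
  structure(list(slope = m, intercept = b, band = band, p_TP = best$p,
                 in_band = abs(r) / sqrt(1 + m^2) <= band,
                 side = ifelse(r > 0, 1L, -1L)),
            class = "separatrix")
}

#' @export
print.separatrix <- function(x, ...) {
  cat(sprintf("Separatrix: Q_C = %.3f Q_O + %.3f (band +- %.3f), p_TP = %.3f\n",
              x$slope, x$intercept, x$band, x$p_TP))
  invisible(x)
}

#' Partition trajectory frames into O, TS and C ensembles
#'
#' TS frames lie within the separatrix band *and* on a reactive transition
#' path (keeping the crossing direction); every remaining frame is assigned
#' open or closed by its side of the line. The equilibrium constant is the
#' closed/open frame-count ratio.
#'
#' @param tbl coordinate table (frame count reference).
#' @param separatrix an [optimize_separatrix()] result.
#' @param paths a [transition_paths()] result.
#' @return object of class `ensemble_partition`: `labels` (factor
#'   O/TS/C per frame), `direction` (closing/opening for TS frames), `K_eq`
#'   (`NA` with a warning if no open frames), frame counts, and the
#'   separatrix echoed through.
#' @export
partition <- function(tbl, separatrix, paths) {
  nf <- nrow(tbl)
  lab <- ifelse(separatrix$side > 0, "C", "O")
  is_ts <- separatrix$in_band & paths$on_path
  lab[is_ts] <- "TS"
  dir <- rep(NA_character_, nf)
  dir[is_ts] <- paths$direction[is_ts]
  nO <- sum(lab == "O"); nC <- sum(lab == "C")
  keq <- if (nO == 0L) {
    warning("no open-ensemble frames; K_eq undefined")
    NA_real_
  } else nC / nO
  structure(list(labels = factor(lab, levels = c("O", "TS", "C")),
                 direction = dir, K_eq = keq,
                 counts = c(O = nO, TS = sum(is_ts), C = nC),
                 separatrix = separatrix),
            class = "ensemble_partition")
}

#' @export
print.ensemble_partition <- function(x, ...) {
  cat(sprintf("Ensemble partition: O %d / TS %d / C %d frames; K_eq = %s; p_TP = %.3f\n",
              x$counts["O"], x$counts["TS"], x$counts["C"],
              ifelse(is.na(x$K_eq), "undefined", sprintf("%.3g", x$K_eq)),
              x$separatrix$p_TP))
  invisible(x)
}

#' Equilibrium constant from closing and opening rates
#'
#' @param k_close,k_open rates (1/s), both positive.
#' @return `k_close / k_open`.
#' @export
keq_from_rates <- function(k_close, k_open) {
  if (k_close <= 0 || k_open <= 0) stop("rates must be positive")
  k_close / k_open
}

#' Calibrate the open-well offset to a target equilibrium constant
#'
#' Iterates `eps_O` using exponential-reweighting predictions between
#' re-simulations until the measured closed/open population ratio falls
#' within a stated tolerance of the target. Between simulations the stored
#' per-frame single-well energies allow the mixed energy at any trial
#' `eps_O` to be recomputed exactly, so each K_eq prediction is a
#' zero-cost reweighting; each accepted update is then verified by a fresh
#' simulation.
#'
#' @param model a [double_well_model()].
#' @param target_keq target closed/open ratio (> 0).
#' @param config a [simulation_config()] for each calibration run.
#' @param tol relative tolerance on the achieved K_eq (default 0.25,
#'   matching the stochastic spread of repeat runs).
#' @param max_iter maximum re-simulation rounds.
#' @return list with `eps_O`, `K_eq` (measured at the returned `eps_O`),
#'   `model` (updated), `iterations`, and a `trace` data.frame.
#' @export
calibrate <- function(model, target_keq, config = simulation_config(),
                      tol = 0.25, max_iter = 6L) {
  stopifnot(target_keq > 0)
  beta_T <- 1 / (KB_KCAL * config$temperature)
  trace <- data.frame(iter = integer(), eps_O = numeric(), K_eq = numeric())
  pool <- list()
  for (it in seq_len(max_iter)) {
    cfg <- config
    # round 1 reuses the caller's seed; later rounds draw fresh noise, with
    # a modular step that keeps the seed a valid 32-bit integer
    if (it > 1L)
      cfg$seed <- as.integer((as.numeric(config$seed) +
                              (it - 1) * 7919) %% 2147483646) + 1L
    traj <- run_langevin(model, config = cfg)
    an <- analyze_run(model, traj)
    keq <- an$partition$K_eq
    trace <- rbind(trace, data.frame(iter = it, eps_O = model$eps_O,
                                     K_eq = keq))
    if (is.finite(keq) && abs(keq - target_keq) / target_keq <= tol)
      return(list(eps_O = model$eps_O, K_eq = keq, model = model,
                  iterations = it - 1L, trace = trace,
                  analysis = an, trajectory = traj))
    pool[[it]] <- list(eo = traj$energies$E_O, ec = traj$energies$E_C,
                       eps = model$eps_O,
                       isC = an$partition$labels == "C",
                       isO = an$partition$labels == "O")
    # pooled exponential-reweighting prediction of K_eq(eps'): every run
    # reweights its own frames from the eps_O it was generated at
    pred <- function(eps) {
      num <- 0; den <- 0
      for (p in pool) {
        e_run <- mix_scalar(p$eo, p$ec, p$eps, model$beta_mix)
        w <- exp(-beta_T * (mix_scalar(p$eo, p$ec, eps, model$beta_mix) -
                            e_run))
        num <- num + sum(w[p$isC]); den <- den + sum(w[p$isO])
      }
      num / den
    }
    g <- function(eps) log(pred(eps)) - log(target_keq)
    lo <- model$eps_O - 20; hi <- model$eps_O + 20
    if (g(lo) * g(hi) > 0)
      stop("calibration failed to bracket target K_eq; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"))
    model$eps_O <- stats::uniroot(g, c(lo, hi), tol = 1e-4)$root
  }
  stop("calibration did not converge in ", max_iter, " iterations; trace:\n",
       paste(utils::capture.output(print(trace)), collapse = "\n"))
}
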