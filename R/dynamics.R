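#' @useDynLib dwgo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

KB_KCAL <- 0.0019872041       # kcal/mol/K
TIME_UNIT_FS <- 48.88821      # sqrt(g/mol A^2 / (kcal/mol)) in fs

#' Simulation configuration
#'
#' @param timestep integration step in femtoseconds.
#' @param n_steps number of steps (>= 1).
#' @param temperature simulation temperature in Kelvin.
#' @param friction Langevin friction in 1/ps. The default is low to speed
#'   barrier crossing; configurable.
#' @param save_stride record a frame every `save_stride` steps.
#' @param seed integer RNG seed.
#' @param mass bead mass in g/mol (default: mean residue mass).
#' @param e_div divergence threshold: abort when `|E|` exceeds it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(timestep = 15, n_steps = 1e5,
                              temperature = 300, friction = 0.2,
                              save_stride = 100L, seed = 1,
                              mass = 110, e_div = 1e6) {
  stopifnot(timestep > 0, n_steps >= 1, temperature > 0, friction >= 0,
            save_stride >= 1, mass > 0)
  structure(list(timestep = timestep, n_steps = as.numeric(n_steps),
                 temperature = temperature, friction = friction,
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed), mass = mass, e_div = e_div),
            class = "simulation_config")
}

#' Total simulated time
#'
#' @param config a [simulation_config()].
#' @return simulated time in nanoseconds (`n_steps * timestep`).
#' @export
total_time <- function(config) config$n_steps * config$timestep * 1e-6

#' Sample a model with Langevin dynamics
#'
#' BAOAB-discretised Langevin integration of the mixed double-well (or a
#' single-well) potential. Bit-reproducible for a fixed seed.
#'
#' @param model a [double_well_model()] or a single-well [go_potential()].
#' @param start starting conformation (n x 3 matrix or
#'   [calpha_structure()]); defaults to the model's open reference (or the
#'   potential's own reference).
#' @param config a [simulation_config()].
#' @return an object of class `go_trajectory`: list with `frames`
#'   (`nframes x n x 3` array, recorded every `save_stride` steps),
#'   `energies` (data.frame `E`, `E_O`, `E_C`), the `config`, the seed and a
#'   model hash for provenance.
#' @export
run_langevin <- function(model, start = NULL, config = simulation_config()) {
  single <- inherits(model, "go_potential")
  if (is.null(start))
    start <- if (single) model$xyz_ref else model$open$xyz
  if (inherits(start, "calpha_structure")) start <- start$xyz
  start <- as.matrix(start)
  n <- if (single) model$n else model$V_O$n
  if (nrow(start) != n) stop("start conformation size mismatch")

  e0 <- if (single) go_energy(model, start)$energy else
    mixed_energy(model, start)$energy
  if (!is.finite(e0)) stop("non-finite initial energy")

  dt <- config$timestep / TIME_UNIT_FS
  gamma <- config$friction * TIME_UNIT_FS / 1000
  kBT <- KB_KCAL * config$temperature

  set.seed(config$seed)
  pc <- if (single) pot_to_cpp(model) else pot_to_cpp(model$V_C)
  po <- if (single) pc else pot_to_cpp(model$V_O)
  res <- cpp_langevin(po, pc,
                      if (single) 0 else model$eps_O,
                      if (single) 1 else model$beta_mix,
                      single, start, config$n_steps, dt, gamma, kBT,
                      config$mass, config$save_stride, config$e_div)
  if (res$status != "ok")
    stop("energy divergence at step ", res$div_step,
         " (|E| exceeded ", config$e_div, "); check model parameters")
  structure(list(frames = res$frames,
                 energies = data.frame(E = res$E, E_O = res$E_O,
                                       E_C = res$E_C),
                 config = config, seed = config$seed,
                 model_hash = model_hash(model),
                 single_well = single),
            class = "go_trajectory")
}

#' @export
print.go_trajectory <- function(x, ...) {
  cat("Go trajectory: ", dim(x$frames)[1], " frames of ", dim(x$frames)[2],
      " residues (", format(total_time(x$config), digits = 4),
      " ns, stride ", x$config$save_stride, ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

model_hash <- function(model) {
  v <- if (inherits(model, "go_potential"))
    c(model$n, nrow(model$contacts), sum(model$contacts$r0))
  else c(model$V_O$n, nrow(model$V_O$contacts), nrow(model$V_C$contacts),
         model$eps_O, model$beta_mix)
  sprintf("%08x", sum(as.integer(abs(v * 1e4) %% 2147483647)) %% 4294967296)
}

#' Find the temperature at which a single-well potential reaches a target
#' native-contact fraction
#'
#' Bisection on the temperature of short single-well simulations until the
#' mean fraction of all native contacts formed (the `Q_all` of the
#' potential's own contact list, 1.1x criterion) matches the target. Used
#' for corresponding-states temperature matching between homologues.
#'
#' @param potential a single-well [go_potential()] (typically the closed
#'   well).
#' @param target_Q target mean native-contact fraction, in (0, 1).
#' @param T_range Kelvin interval to search.
#' @param config simulation settings for each probe run (seed is reused;
#'   the first half of each run is discarded as equilibration).
#' @param tol convergence tolerance on `Q`.
#' @param max_iter bisection iteration cap.
#' @return list with `temperature` (K) and `Q` achieved.
#' @export
match_temperature <- function(potential, target_Q, T_range = c(200, 600),
                              config = simulation_config(n_steps = 2e4),
                              tol = 0.01, max_iter = 20L) {
  stopifnot(target_Q > 0, target_Q < 1, T_range[1] < T_range[2])
  qat <- function(temp) {
    cfg <- config; cfg$temperature <- temp
    tr <- run_langevin(potential, config = cfg)
    nf <- dim(tr$frames)[1]
    keep <- seq.int(floor(nf / 2) + 1L, nf)
    mean(vapply(keep, function(f)
      fraction_contacts(tr$frames[f, , ], potential$contacts), 0))
  }
  qlo <- qat(T_range[2])  # Q decreases with T: low Q at high T
  qhi <- qat(T_range[1])
  if (target_Q > qhi || target_Q < qlo)
    stop(sprintf(
      "target_Q = %.3f not bracketed: Q(%.0fK) = %.3f, Q(%.0fK) = %.3f",
      target_Q, T_range[1], qhi, T_range[2], qlo))
  if (abs(qhi - target_Q) <= tol)
    return(list(temperature = T_range[1], Q = qhi))
  if (abs(qlo - target_Q) <= tol)
    return(list(temperature = T_range[2], Q = qlo))
  lo <- T_range[1]; hi <- T_range[2]
  q <- NA_real_; mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- qat(mid)
    if (abs(q - target_Q) <= tol) break
    if (q > target_Q) lo <- mid else hi <- mid
  }
  list(temperature = mid, Q = q)
}
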