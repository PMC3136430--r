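#' Generate a synthetic two-conformation hinge protein
#'
#' Builds a toy chain of two locally rigid lobes joined by a three-residue
#' hinge, in an open and a closed conformation that differ only by a rigid
#' rotation of the second lobe about the hinge. Lobe-internal geometry is
#' bitwise identical between the two conformations, so lobe-internal contacts
#' are shared; inter-lobe interface contacts differ with the hinge angle.
#' Each lobe is an ideal alpha-helix-like C-alpha spiral (1.5 A rise,
#' 100 degrees of rotation per residue), which gives realistic local contact
#' density with trivial construction.
#'
#' Ligand pseudo-contacts are the three shortest closed-state inter-lobe
#' residue pairs that are not already native contacts, mimicking substrate
#' bridging of the closed interface with a deterministic rule.
#'
#' The hinge is a precessing axis: bending by `180 - angle` degrees happens
#' about an in-plane axis whose azimuth drifts with the bend
#' (`azimuth = axis_azimuth + axis_precession * (180 - angle)`), so closure
#' engages a different face of the first lobe than partial opening - a
#' closing-with-twist motion that gives both conformations their own unique
#' interface contacts. A conformation depends only on its hinge angle, so
#' equal angles yield bitwise-identical structures.
#'
#' @param n_res number of residues (>= 12).
#' @param hinge_angle_open,hinge_angle_closed angle between the two lobe axes
#'   in degrees, in (0, 180]; 180 is a straight chain.
#' @param axis_azimuth,axis_precession hinge-axis azimuth at zero bend
#'   (degrees) and its drift per degree of bend.
#' @param seed integer seed; affects only the optional coordinate jitter.
#' @param jitter_sd Gaussian jitter (A) applied to the shared base spiral
#'   before assembly (bond lengths are re-regularised afterwards); 0 disables.
#' @param contact_cutoff,min_separation contact rule used only to pick ligand
#'   pseudo-contacts (pairs *not* native by this rule).
#' @param n_ligand number of ligand pseudo-contacts bridging the closed
#'   interface.
#' @return an object of class `toy_system`: list with `open`, `closed`
#'   ([calpha_structure()]s sharing a domain map with `lobeA`, `hinge`,
#'   `lobeB`), `ligand_contacts` (2-column matrix of residue pairs), `seed`,
#'   and the generating angles.
#' @export
make_toy_two_state <- function(n_res, hinge_angle_open = 100,
                               hinge_angle_closed = 55, seed = 1,
                               axis_azimuth = 120, axis_precession = 2.5,
                               jitter_sd = 0.05, contact_cutoff = 8.0,
                               min_separation = 3L, n_ligand = 3L) {
  if (n_res < 12L)
    stop("n_res must be >= 12 to form two lobes around a hinge")
  for (a in c(hinge_angle_open, hinge_angle_closed))
    if (!is.finite(a) || a <= 0 || a > 180)
      stop("hinge angles must lie in (0, 180] degrees")

  bond <- 3.8; rise <- 1.5; turn <- 100 * pi / 180
  radius <- sqrt(bond^2 - rise^2) / (2 * sin(turn / 2))
  k <- seq_len(n_res) - 1L
  base <- cbind(radius * cos(turn * k), radius * sin(turn * k), rise * k)

  if (jitter_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(as.integer(seed))
    base <- base + matrix(stats::rnorm(3L * n_res, sd = jitter_sd), ncol = 3)
    base <- regularise_bonds(base, bond)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  }

  h <- as.integer(ceiling(n_res / 2))
  dm <- list(lobeA = 1:(h - 2L), hinge = (h - 1L):(h + 1L),
             lobeB = (h + 2L):n_res)

  bend <- function(angle) {
    rot <- (180 - angle) * pi / 180
    if (abs(rot) < 1e-12) return(base)
    pivot <- base[h, ]
    psi <- (axis_azimuth + axis_precession * (180 - angle)) * pi / 180
    axis <- c(cos(psi), sin(psi), 0)      # in-plane, perpendicular to lobe-A axis
    R <- rotation_matrix(axis, rot)
    out <- base
    idx <- (h + 1L):n_res
    out[idx, ] <- sweep(sweep(base[idx, , drop = FALSE], 2, pivot) %*% t(R),
                        2, pivot, `+`)
    out
  }

  mk <- function(xyz) calpha_structure(xyz, domain_map = dm)
  open <- mk(bend(hinge_angle_open))
  closed <- mk(bend(hinge_angle_closed))

  # ligand pseudo-contacts: shortest closed-state lobeA-lobeB pairs that are
  # not native contacts under the (cutoff, min_separation) rule
  ia <- dm$lobeA; ib <- dm$lobeB
  pairs <- expand.grid(i = ia, j = ib)
  pairs <- pairs[abs(pairs$j - pairs$i) >= min_separation, ]
  d <- sqrt(rowSums((closed$xyz[pairs$i, , drop = FALSE] -
                     closed$xyz[pairs$j, , drop = FALSE])^2))
  cand <- pairs[d > contact_cutoff, , drop = FALSE]
  dc <- d[d > contact_cutoff]
  ord <- order(dc, cand$i, cand$j)
  lig <- as.matrix(cand[ord[seq_len(min(n_ligand, nrow(cand)))], c("i", "j")])
  dimnames(lig) <- list(NULL, c("i", "j"))

  structure(list(open = open, closed = closed, domain_map = dm,
                 ligand_contacts = lig, seed = as.integer(seed),
                 hinge_angle_open = hinge_angle_open,
                 hinge_angle_closed = hinge_angle_closed),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Toy two-state system: ", nrow(x$open$xyz), " residues, hinge ",
      x$hinge_angle_open, "° (open) / ", x$hinge_angle_closed,
      "° (closed), ", nrow(x$ligand_contacts),
      " ligand pseudo-contacts\n", sep = "")
  invisible(x)
}

# Iteratively restore consecutive C-alpha distances to `bond` after jitter.
regularise_bonds <- function(xyz, bond, iters = 50L) {
  n <- nrow(xyz)
  for (it in seq_len(iters)) {
    worst <- 0
    for (kk in seq_len(n - 1L)) {
      r <- xyz[kk + 1L, ] - xyz[kk, ]
      d <- sqrt(sum(r^2))
      worst <- max(worst, abs(d - bond))
      corr <- 0.5 * (d - bond) / d * r
      xyz[kk, ] <- xyz[kk, ] + corr
      xyz[kk + 1L, ] <- xyz[kk + 1L, ] - corr
    }
    if (worst < 1e-6) break
  }
  xyz
}

# Rotation matrix about unit axis by angle (radians), Rodrigues' formula.
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Write a toy system to disk
#'
#' Conformations as minimal single-chain PDB files (`open.pdb`,
#' `closed.pdb`); domain map and ligand contacts as a plain-text config
#' section (`system.cfg`).
#'
#' @param sys a [make_toy_two_state()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_system <- function(sys, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calpha(sys$open, file.path(dir, "open.pdb"))
  write_calpha(sys$closed, file.path(dir, "closed.pdb"))
  cfg <- c("[domains]",
           vapply(names(sys$domain_map), function(nm) {
             ids <- sys$domain_map[[nm]]
             sprintf("%s = %d-%d", nm, min(ids), max(ids))
           }, ""),
           "[ligand_contacts]",
           apply(sys$ligand_contacts, 1, function(p)
             sprintf("%d %d", p[1], p[2])))
  writeLines(cfg, file.path(dir, "system.cfg"))
  invisible(dir)
}

#' One-dimensional diffusive double-well parameters
#'
#' A symmetric quartic double well `V(x) = h ((x/a)^2 - 1)^2` (energies in
#' kT units) sampled by overdamped Brownian dynamics. Serves as an exactly
#' controlled reference system for basin finding, transition-path extraction
#' and the transition-path-probability bound.
#'
#' @param barrier_height `h`, barrier height in kT (> 0 for a double well;
#'   0 gives free diffusion).
#' @param well_separation `a`, minima at x = -a and +a.
#' @param diffusion diffusion coefficient.
#' @param timestep integration step.
#' @param n_steps number of steps (>= 1).
#' @param seed integer seed.
#' @param x0 initial position (default `-well_separation`).
#' @return an object of class `one_d_double_well`.
#' @export
one_d_double_well <- function(barrier_height, well_separation = 1,
                              diffusion = 1, timestep = 1e-3,
                              n_steps = 1000L, seed = 1,
                              x0 = -well_separation) {
  p <- list(barrier_height = barrier_height,
            well_separation = well_separation, diffusion = diffusion,
            timestep = timestep, n_steps = as.integer(n_steps),
            seed = as.integer(seed), x0 = x0)
  if (!all(vapply(p[1:4], is.finite, TRUE)))
    stop("parameters must be finite")
  if (barrier_height < 0) stop("barrier_height must be >= 0")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (timestep <= 0 || diffusion < 0)
    stop("timestep must be positive and diffusion non-negative")
  structure(p, class = "one_d_double_well")
}

#' Overdamped Brownian dynamics on the 1-D double well
#'
#' Euler-Maruyama integration of `dx = -D V'(x) dt + sqrt(2 D dt) eta`
#' (kT = 1). Reproducible by seed.
#'
#' @param params a [one_d_double_well()].
#' @return numeric vector of length `n_steps + 1` (position series including
#'   the initial point).
#' @export
brownian_1d <- function(params) {
  stopifnot(inherits(params, "one_d_double_well"))
  h <- params$barrier_height; a <- params$well_separation
  D <- params$diffusion; dt <- params$timestep; n <- params$n_steps
  set.seed(params$seed)
  noise <- stats::rnorm(n, sd = sqrt(2 * D * dt))
  x <- numeric(n + 1L)
  x[1] <- params$x0
  c1 <- 4 * h / a^2
  for (k in seq_len(n)) {
    xi <- x[k]
    grad <- c1 * xi * ((xi / a)^2 - 1)
    x[k + 1L] <- xi - D * grad * dt + noise[k]
  }
  x
}
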