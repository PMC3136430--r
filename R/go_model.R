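#' Identify native contacts of a reference conformation
#'
#' All residue pairs at least `min_separation` apart in sequence whose
#' C-alpha distance does not exceed `cutoff`. The native distance is the
#' observed distance; every contact carries the same base well depth (a
#' documented simplification of all-atom contact-energy assignment; a
#' per-contact energy table can be supplied to [go_potential()] to restore
#' fidelity).
#'
#' @param structure a [calpha_structure()].
#' @param cutoff C-alpha distance cutoff in Angstroms.
#' @param min_separation minimum `|i - j|` sequence separation.
#' @param depth uniform base well depth (kcal/mol) before contact scaling.
#' @param provenance provenance label recorded on each contact.
#' @return data.frame with columns `i`, `j` (chain positions, i < j), `r0`
#'   (A), `eps` (kcal/mol), `provenance`.
#' @export
build_contacts <- function(structure, cutoff = 8.0, min_separation = 3L,
                           depth = 0.45, provenance = "native") {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- structure$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_separation &
    d[idx] <= cutoff
  if (!any(keep))
    return(data.frame(i = integer(), j = integer(), r0 = numeric(),
                      eps = numeric(), provenance = character()))
  out <- data.frame(i = as.integer(idx[keep, 1]),
                    j = as.integer(idx[keep, 2]),
                    r0 = d[idx][keep], eps = depth,
                    provenance = provenance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_key <- function(i, j, n) (pmin(i, j) - 1) * n + (pmax(i, j) - 1)

#' Partition two contact lists into unique and shared sets
#'
#' Set operations on `(i, j)` pairs. Shared contacts keep both native
#' distances (`r0_O`, `r0_C`).
#'
#' @param contacts_O,contacts_C contact data.frames from [build_contacts()]
#'   on the open and closed conformations of the same chain.
#' @return list with `O_unique`, `C_unique` (contact data.frames) and
#'   `shared` (data.frame with `i`, `j`, `r0_O`, `r0_C`, `eps`).
#' @export
partition_contacts <- function(contacts_O, contacts_C) {
  n <- max(contacts_O$j, contacts_C$j, 1L)
  ko <- pair_key(contacts_O$i, contacts_O$j, n)
  kc <- pair_key(contacts_C$i, contacts_C$j, n)
  shared_o <- contacts_O[ko %in% kc, , drop = FALSE]
  shared_c <- contacts_C[match(pair_key(shared_o$i, shared_o$j, n), kc), ,
                         drop = FALSE]
  shared <- data.frame(i = shared_o$i, j = shared_o$j,
                       r0_O = shared_o$r0, r0_C = shared_c$r0,
                       eps = shared_o$eps)
  rownames(shared) <- NULL
  ou <- contacts_O[!(ko %in% kc), , drop = FALSE]
  cu <- contacts_C[!(kc %in% ko), , drop = FALSE]
  if (nrow(ou)) ou$provenance <- "O"
  if (nrow(cu)) cu$provenance <- "C"
  rownames(ou) <- rownames(cu) <- NULL
  list(O_unique = ou, C_unique = cu, shared = shared)
}

#' Build a single-well Go potential from a reference conformation
#'
#' Terms: harmonic virtual bonds at the native consecutive C-alpha
#' distances; a generic double-basin pseudo-bond-angle potential permitting
#' both helix-like and extended values (two Gaussian basins, defaults 92 and
#' 130 degrees, equal depth); per-quadruple cosine-series dihedrals with the
#' minimum at the reference torsion; 12-10-6 native-contact wells with the
#' minimum at the native distance; and an r^-12 excluded-volume repulsion
#' for non-native pairs.
#'
#' Per-residue dihedral stiffness multipliers model backbone-flexibility
#' mutations at C-alpha resolution (glycine-like: 0.2; proline-like: 5);
#' a dihedral's depth is the base depth times the product of the four
#' participating residues' multipliers.
#'
#' @param structure the reference [calpha_structure()].
#' @param contacts contact data.frame (default: [build_contacts()] on
#'   `structure`). A `depth` column override table (columns `i`, `j`,
#'   `eps`) may be merged by the caller before passing it in.
#' @param contact_scale multiplier applied to every contact well depth
#'   (default 2.5; set 1 for the unscaled "weak" variant).
#' @param bond_k harmonic bond constant (kcal/mol/A^2).
#' @param angle_theta two basin centres of the generic angle potential
#'   (degrees).
#' @param angle_sigma Gaussian basin width (degrees).
#' @param angle_eps angle potential depth scale (kcal/mol).
#' @param dihedral_k base dihedral depth (kcal/mol).
#' @param dihedral_mult per-residue stiffness multipliers (length n).
#' @param rep_eps,rep_sigma excluded-volume strength (kcal/mol) and radius
#'   (A).
#' @param min_separation minimum sequence separation for the excluded-volume
#'   pairs (matching the contact rule).
#' @return an object of class `go_potential`.
#' @export
go_potential <- function(structure, contacts = build_contacts(structure),
                         contact_scale = 2.5, bond_k = 100,
                         angle_theta = c(92, 130), angle_sigma = 15,
                         angle_eps = 2.0, dihedral_k = 0.5,
                         dihedral_mult = rep(1, nrow(structure$xyz)),
                         rep_eps = 1.0, rep_sigma = 4.0,
                         min_separation = 3L) {
  stopifnot(contact_scale > 0)
  xyz <- structure$xyz
  n <- nrow(xyz)
  if (length(dihedral_mult) != n)
    stop("dihedral_mult must have one entry per residue")
  bond_r0 <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                           xyz[-n, , drop = FALSE])^2))
  phi0 <- numeric(max(n - 3L, 0L))
  dk <- numeric(length(phi0))
  for (k in seq_along(phi0)) {
    phi0[k] <- torsion4(xyz[k, ], xyz[k + 1L, ], xyz[k + 2L, ], xyz[k + 3L, ])
    dk[k] <- dihedral_k * prod(dihedral_mult[k:(k + 3L)])
  }
  structure(list(n = n, xyz_ref = xyz, structure = structure,
                 bond_r0 = bond_r0, bond_k = bond_k,
                 angle_theta = angle_theta, angle_sigma = angle_sigma,
                 angle_eps = angle_eps,
                 dih_phi0 = phi0, dih_k = dk,
                 contacts = contacts, contact_scale = contact_scale,
                 rep_eps = rep_eps, rep_sigma = rep_sigma,
                 min_separation = as.integer(min_separation)),
            class = "go_potential")
}

#' @export
print.go_potential <- function(x, ...) {
  cat("Go potential: ", x$n, " residues, ", nrow(x$contacts),
      " native contacts (scale ", x$contact_scale, ")\n", sep = "")
  invisible(x)
}

# Plain list handed to the compiled core.
pot_to_cpp <- function(pot) {
  list(n = as.integer(pot$n),
       bond_r0 = pot$bond_r0, bond_k = pot$bond_k,
       th1 = pot$angle_theta[1] * pi / 180,
       th2 = pot$angle_theta[2] * pi / 180,
       sig = pot$angle_sigma * pi / 180, eps_a = pot$angle_eps,
       dih_phi0 = pot$dih_phi0 * pi / 180, dih_k = pot$dih_k,
       ci = as.integer(pot$contacts$i), cj = as.integer(pot$contacts$j),
       cr0 = pot$contacts$r0, ceps = pot$contacts$eps * pot$contact_scale,
       rep_eps = pot$rep_eps, rep_sigma = pot$rep_sigma,
       min_sep = pot$min_separation)
}

#' Single-well Go energy and forces
#'
#' @param pot a [go_potential()].
#' @param xyz an n x 3 conformation.
#' @return list with `energy`, `forces` (n x 3) and a per-term `terms`
#'   breakdown (bond, angle, dihedral, contact, repulsion).
#' @export
go_energy <- function(pot, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != pot$n) stop("conformation size mismatch")
  res <- cpp_single_energy(pot_to_cpp(pot), xyz)
  res$forces <- matrix(res$forces, ncol = 3, byrow = TRUE)
  res
}

#' Add ligand-mediated contacts to the closed-state potential
#'
#' Extra contacts (native distances taken from the closed structure) are
#' appended to the C contact list only, modelling the stabilisation of the
#' closed interdomain interface by bound ligand. Pairs duplicating existing
#' contacts are an error.
#'
#' @param potential_C the closed-state [go_potential()].
#' @param pairs 2-column matrix/data.frame of residue pairs (chain
#'   positions).
#' @param closed_structure the closed [calpha_structure()] supplying native
#'   distances.
#' @param depth base well depth for the added contacts (default: the
#'   potential's uniform contact depth).
#' @return a new `go_potential` with the augmented contact list.
#' @export
add_ligand_contacts <- function(potential_C, pairs, closed_structure,
                                depth = NULL) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) return(potential_C)
  if (is.null(depth))
    depth <- if (nrow(potential_C$contacts)) potential_C$contacts$eps[1] else 0.3
  i <- pmin(pairs[, 1], pairs[, 2]); j <- pmax(pairs[, 1], pairs[, 2])
  n <- potential_C$n
  kex <- pair_key(potential_C$contacts$i, potential_C$contacts$j, n)
  knew <- pair_key(i, j, n)
  if (any(knew %in% kex) || anyDuplicated(knew))
    stop("ligand pair duplicates an existing contact: ",
         paste(sprintf("(%d,%d)", i[knew %in% kex | duplicated(knew)],
                       j[knew %in% kex | duplicated(knew)]), collapse = " "))
  xyz <- closed_structure$xyz
  r0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  add <- data.frame(i = as.integer(i), j = as.integer(j), r0 = r0,
                    eps = depth, provenance = "ligand")
  potential_C$contacts <- rbind(potential_C$contacts, add)
  potential_C
}

#' Combine open and closed potentials into a smooth double well
#'
#' Exponential averaging:
#' `E = -(1/beta_mix) ln[exp(-beta_mix (E_O + eps_O)) + exp(-beta_mix E_C)]`.
#' `eps_O` shifts the relative stability of the open state; `beta_mix`
#' controls how sharply the wells join (large values approach
#' `min(E_O + eps_O, E_C)`).
#'
#' @param potential_O,potential_C single-well [go_potential()]s built on the
#'   open and closed reference conformations.
#' @param eps_O energy offset added to the open well (kcal/mol).
#' @param beta_mix mixing parameter (1/(kcal/mol)), > 0.
#' @param open,closed the reference structures (defaults: the potentials'
#'   own references).
#' @return an object of class `double_well_model`, carrying the two
#'   potentials, the mixing parameters, the reference structures and the
#'   contact partition (O-unique / C-unique / shared).
#' @export
double_well_model <- function(potential_O, potential_C, eps_O = 0,
                              beta_mix = 0.1,
                              open = potential_O$structure,
                              closed = potential_C$structure) {
  stopifnot(beta_mix > 0, potential_O$n == potential_C$n)
  part <- partition_contacts(potential_O$contacts[potential_O$contacts$provenance != "ligand", ],
                             potential_C$contacts[potential_C$contacts$provenance != "ligand", ])
  structure(list(V_O = potential_O, V_C = potential_C,
                 eps_O = eps_O, beta_mix = beta_mix,
                 open = open, closed = closed, partition = part),
            class = "double_well_model")
}

#' @export
print.double_well_model <- function(x, ...) {
  p <- x$partition
  cat("Double-well Go model: ", x$V_O$n, " residues; eps_O = ",
      signif(x$eps_O, 4), " kcal/mol, beta_mix = ", x$beta_mix,
      " mol/kcal\n  contacts: ", nrow(p$O_unique), " O-unique, ",
      nrow(p$C_unique), " C-unique, ", nrow(p$shared), " shared, ",
      sum(x$V_C$contacts$provenance == "ligand"), " ligand\n", sep = "")
  invisible(x)
}

#' Mixed double-well energy at a conformation
#'
#' Overflow-safe evaluation of the exponential average, with a per-well
#' breakdown and the identity of the dominating well.
#'
#' @param model a [double_well_model()].
#' @param xyz an n x 3 conformation.
#' @return list with `energy`, `E_O`, `E_C`, `w_O` (the open-well mixing
#'   weight), `dominant` ("O" or "C") and `forces` (n x 3).
#' @export
mixed_energy <- function(model, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != model$V_O$n) stop("conformation size mismatch")
  res <- cpp_mixed_energy(pot_to_cpp(model$V_O), pot_to_cpp(model$V_C),
                          model$eps_O, model$beta_mix, xyz)
  if (!is.finite(res$E_O) || !is.finite(res$E_C))
    stop("non-finite single-well energy")
  res$forces <- matrix(res$forces, ncol = 3, byrow = TRUE)
  res$dominant <- if (res$w_O >= 0.5) "O" else "C"
  res
}

# Mixed energy from per-frame single-well energies (used by reweighting).
mix_scalar <- function(E_O, E_C, eps_O, beta_mix) {
  a <- -beta_mix * (E_O + eps_O)
  b <- -beta_mix * E_C
  m <- pmax(a, b)
  -(m + log(exp(a - m) + exp(b - m))) / beta_mix
}
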