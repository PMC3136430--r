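#' Construct a C-alpha structure object
#'
#' The basic container for a coarse-grained chain: one C-alpha position per
#' residue, ordered by residue number, plus optional domain annotations used
#' by the rigid-body (center-of-mass) coordinates.
#'
#' @param xyz numeric matrix, n x 3, coordinates in Angstroms.
#' @param residue_ids strictly increasing integer residue numbers (default
#'   `1:nrow(xyz)`).
#' @param chain_id single-character chain identifier.
#' @param domain_map named list of integer residue-id vectors (inclusive
#'   ranges expanded by the caller), e.g. `list(CORE = 1:20, LID = 30:44)`.
#' @param exclusions named list (names are domain names) of residue ids to
#'   omit from that domain's center-of-mass calculations, e.g. connector
#'   helices bridging two domains.
#' @return an object of class `calpha_structure`.
#' @export
calpha_structure <- function(xyz, residue_ids = seq_len(nrow(xyz)),
                             chain_id = "A", domain_map = list(),
                             exclusions = list()) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != nrow(xyz))
    stop("residue_ids length must match coordinate rows")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  for (nm in names(domain_map)) {
    bad <- setdiff(domain_map[[nm]], residue_ids)
    if (length(bad))
      stop("domain '", nm, "' refers to residues absent from the chain: ",
           paste(bad, collapse = ", "))
  }
  structure(list(xyz = xyz, residue_ids = residue_ids, chain_id = chain_id,
                 domain_map = domain_map, exclusions = exclusions),
            class = "calpha_structure")
}

#' @export
print.calpha_structure <- function(x, ...) {
  cat("C-alpha structure: ", nrow(x$xyz), " residues (",
      x$residue_ids[1], "-", x$residue_ids[length(x$residue_ids)],
      "), chain ", x$chain_id, "\n", sep = "")
  if (length(x$domain_map))
    cat("  domains:", paste(sprintf("%s[%d]", names(x$domain_map),
                                    lengths(x$domain_map)), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.calpha_structure <- function(x) nrow(x$xyz)

res_index <- function(structure, ids) {
  idx <- match(ids, structure$residue_ids)
  if (anyNA(idx))
    stop("residues not in chain: ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Read C-alpha coordinates from a PDB file or text
#'
#' Extracts one CA atom per residue for a single chain. Alternate locations
#' are resolved by first occurrence; insertion codes are rejected. A residue
#' that appears in the chain without a CA atom is an error.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain chain identifier; `NULL` takes the only chain present.
#' @return a [calpha_structure()] (no domain annotations; attach them
#'   afterwards).
#' @export
read_calpha <- function(pdb, chain = NULL) {
  file <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1], fixed = TRUE)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), file)
  }
  p <- bio3d::read.pdb(file, verbose = FALSE)
  at <- p$atom
  if (is.null(chain)) {
    chains <- unique(at$chain)
    if (length(chains) != 1L)
      stop("multiple chains present (", paste(chains, collapse = ","),
           "); specify one")
    chain <- chains
  }
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain, "' is empty")
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported (residues ",
         paste(unique(at$resno[!is.na(ins) & ins != ""]), collapse = ", "), ")")
  ca <- at[at$elety == "CA", , drop = FALSE]
  miss <- setdiff(unique(at$resno), unique(ca$resno))
  if (length(miss))
    stop("residues lacking a CA atom: ", paste(sort(miss), collapse = ", "))
  if (!nrow(ca)) stop("chain '", chain, "' has no CA atoms")
  # altloc: first occurrence per residue wins
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  calpha_structure(cbind(ca$x, ca$y, ca$z), residue_ids = ca$resno,
                   chain_id = chain)
}

#' Write a C-alpha structure as a minimal PDB file
#'
#' ATOM records only, CA atoms, preserving residue numbering.
#'
#' @param structure a [calpha_structure()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_calpha <- function(structure, file) {
  n <- nrow(structure$xyz)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(structure$xyz)),
                   resno = structure$residue_ids,
                   resid = rep("GLY", n),
                   chain = rep(structure$chain_id, n),
                   elety = rep("CA", n))
  invisible(file)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over a residue
#' selection, returning the transform and the post-fit RMSD over that
#' selection.
#'
#' @param mobile,reference [calpha_structure()] objects sharing the selected
#'   residues.
#' @param selection residue ids to fit on (default: all shared residues).
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% t(R) + t`), `rmsd` (Angstroms over the selection)
#'   and `xyz` (all mobile coordinates after the transform).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection))
    selection <- intersect(mobile$residue_ids, reference$residue_ids)
  im <- res_index(mobile, selection)
  ir <- res_index(reference, selection)
  A <- mobile$xyz[im, , drop = FALSE]
  B <- reference$xyz[ir, , drop = FALSE]
  fit <- kabsch(A, B)
  xyz_all <- sweep(mobile$xyz %*% t(fit$rotation), 2, fit$translation, `+`)
  d <- xyz_all[im, , drop = FALSE] - B
  list(rotation = fit$rotation, translation = fit$translation,
       rmsd = sqrt(mean(rowSums(d^2))), xyz = xyz_all)
}

# Kabsch algorithm: rotation + translation minimizing |R A + t - B|^2.
kabsch <- function(A, B) {
  if (nrow(A) < 3L) stop("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))  # H = B0' A0 ; R = U diag(1,1,d) V'
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("collinear selection: superposition is degenerate")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = R, translation = as.numeric(cb - R %*% ca))
}

#' RMSD between two structures without fitting
#' @noRd
raw_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Center-of-mass distance between two domains
#'
#' Unweighted C-alpha center of mass per domain; residues listed in the
#' structure's `exclusions` entry for a domain are omitted from that domain's
#' center of mass (the mechanism used to drop connector helices bridging two
#' domains from rigid-body coordinates).
#'
#' @param structure a [calpha_structure()] with a domain map.
#' @param domainA,domainB domain names.
#' @param xyz optional replacement coordinate matrix (a trajectory frame) for
#'   the same residue ordering.
#' @return distance in Angstroms.
#' @export
com_distance <- function(structure, domainA, domainB, xyz = NULL) {
  if (is.null(xyz)) xyz <- structure$xyz
  com <- function(dom) {
    ids <- structure$domain_map[[dom]]
    if (is.null(ids)) stop("domain '", dom, "' not in domain map")
    ids <- setdiff(ids, structure$exclusions[[dom]])
    if (!length(ids)) stop("domain '", dom, "' is empty after exclusions")
    colMeans(xyz[res_index(structure, ids), , drop = FALSE])
  }
  sqrt(sum((com(domainA) - com(domainB))^2))
}

#' Wrap angles (degrees) to (-180, 180]
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Minimal angular distance between two angles (degrees)
#' @param a,b angles in degrees.
#' @return distance in `[0, 180]`.
#' @export
angular_distance <- function(a, b) abs(wrap_angle(a - b))

# Torsion of four points (rows of m), degrees in (-180, 180]; NA if degenerate.
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2) / nb, sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Pseudodihedral angles along a C-alpha chain
#'
#' The virtual torsion about the bond between residues i-1 and i, computed
#' over C-alpha atoms (i-2, i-1, i, i+1) and assigned to residue i, so each
#' interior residue carries one angle. Terminal residues (the first two and
#' the last) are `NA`; a collinear quadruple yields `NA` for that residue.
#'
#' @param x a [calpha_structure()] or an n x 3 coordinate matrix.
#' @return named numeric vector of length n (degrees, wrapped to
#'   `(-180, 180]`), names are residue indices (or ids for a structure).
#' @export
pseudodihedrals <- function(x) {
  xyz <- if (inherits(x, "calpha_structure")) x$xyz else as.matrix(x)
  n <- nrow(xyz)
  if (n < 4L) stop("pseudodihedrals need at least 4 residues")
  out <- rep(NA_real_, n)
  for (i in 3:(n - 1L))
    out[i] <- torsion4(xyz[i - 2L, ], xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ])
  names(out) <- if (inherits(x, "calpha_structure")) x$residue_ids else seq_len(n)
  out
}

# Vectorised pseudodihedrals over trajectory frames: frames is an
# (nframes x n x 3) array; returns an (nframes x n) matrix.
pseudodihedrals_frames <- function(frames) {
  nf <- dim(frames)[1]; n <- dim(frames)[2]
  out <- matrix(NA_real_, nf, n)
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  for (i in 3:(n - 1L)) {
    p1 <- frames[, i - 2L, ]; p2 <- frames[, i - 1L, ]
    p3 <- frames[, i, ];      p4 <- frames[, i + 1L, ]
    if (nf == 1L) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4) }
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    m1 <- cross(n1, b2)
    nb <- sqrt(rowSums(b2^2))
    ang <- -atan2(rowSums(m1 * n2) / nb, rowSums(n1 * n2)) * 180 / pi
    bad <- rowSums(n1^2) < 1e-12 | rowSums(n2^2) < 1e-12
    ang[bad] <- NA_real_
    out[, i] <- wrap_angle(ang)
  }
  out
}
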