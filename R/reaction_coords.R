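#' Fraction of native contacts formed in a frame
#'
#' A contact is formed when the instantaneous C-alpha distance does not
#' exceed `ratio` times its native distance.
#'
#' @param frame n x 3 coordinate matrix.
#' @param contacts contact data.frame (`i`, `j`, `r0`).
#' @param ratio formation criterion multiplier (default 1.1).
#' @return fraction in `[0, 1]`.
#' @export
fraction_contacts <- function(frame, contacts, ratio = 1.1) {
  if (!nrow(contacts)) stop("empty contact list")
  frame <- as.matrix(frame)
  d <- sqrt(rowSums((frame[contacts$i, , drop = FALSE] -
                     frame[contacts$j, , drop = FALSE])^2))
  mean(d <= ratio * contacts$r0)
}

# Per-frame formation fractions for a contact set over a trajectory array.
fraction_contacts_frames <- function(frames, contacts, ratio = 1.1) {
  if (!nrow(contacts)) stop("empty contact list")
  nf <- dim(frames)[1]
  formed <- matrix(FALSE, nf, nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    dx <- frames[, contacts$i[k], ] - frames[, contacts$j[k], ]
    if (nf == 1L) dx <- rbind(dx)
    formed[, k] <- sqrt(rowSums(dx^2)) <= ratio * contacts$r0[k]
  }
  formed
}

# Contact set for Q_*,all: unique contacts plus shared ones scored at the
# native distance of the requested well ("own") or the opposite one.
all_contacts_for <- function(partition, well = c("O", "C"),
                             shared_native = c("own", "other")) {
  well <- match.arg(well); shared_native <- match.arg(shared_native)
  uq <- if (well == "O") partition$O_unique else partition$C_unique
  sh <- partition$shared
  own <- (well == "O") == (shared_native == "own")
  shr <- data.frame(i = sh$i, j = sh$j,
                    r0 = if (own) sh$r0_O else sh$r0_C,
                    eps = sh$eps, provenance = "shared")
  rbind(uq[, c("i", "j", "r0", "eps", "provenance")], shr)
}

#' Project a trajectory onto the standard reaction coordinates
#'
#' Computes, per frame: `Q_O` and `Q_C` (fraction of contacts unique to the
#' open/closed reference), `Q_O_all` and `Q_C_all` (including contacts
#' shared between the two references), `rms_O` and `rms_C` (C-alpha RMSD to
#' each reference after least-squares superposition), and center-of-mass
#' distances `r_cm_<A>_<B>` for the requested domain pairs (respecting the
#' structures' center-of-mass exclusion lists, e.g. connector helices).
#'
#' @param trajectory a [run_langevin()] trajectory.
#' @param model the [double_well_model()] that generated it.
#' @param com_pairs list of 2-element character vectors of domain names
#'   (default: all unordered pairs in the open structure's domain map).
#' @param ratio contact formation criterion (default 1.1).
#' @param shared_native for shared contacts in `Q_*_all`: score at the well
#'   being scored's own native distance (`"own"`, default) or the other
#'   well's.
#' @param superpose_on residue ids used for the RMSD fit (default: all).
#' @return data.frame (class `coordinate_table`) with one row per frame.
#' @export
project <- function(trajectory, model, com_pairs = NULL, ratio = 1.1,
                    shared_native = c("own", "other"), superpose_on = NULL) {
  shared_native <- match.arg(shared_native)
  frames <- trajectory$frames
  nf <- dim(frames)[1]
  part <- model$partition
  out <- data.frame(frame = seq_len(nf))

  qcol <- function(contacts) {
    if (!nrow(contacts)) return(rep(NA_real_, nf))
    rowMeans(fraction_contacts_frames(frames, contacts, ratio))
  }
  out$Q_O <- qcol(part$O_unique)
  out$Q_C <- qcol(part$C_unique)
  out$Q_O_all <- qcol(all_contacts_for(part, "O", shared_native))
  out$Q_C_all <- qcol(all_contacts_for(part, "C", shared_native))

  refs <- list(rms_O = model$open, rms_C = model$closed)
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    sel <- if (is.null(superpose_on)) ref$residue_ids else superpose_on
    ir <- res_index(ref, sel)
    B <- ref$xyz[ir, , drop = FALSE]
    out[[nm]] <- vapply(seq_len(nf), function(f) {
      A <- frames[f, ir, ]
      fit <- kabsch(A, B)
      Af <- sweep(A %*% t(fit$rotation), 2, fit$translation, `+`)
      sqrt(mean(rowSums((Af - B)^2)))
    }, 0)
  }

  dm <- model$open$domain_map
  if (is.null(com_pairs) && length(dm) >= 2) {
    nms <- names(dm)
    com_pairs <- list()
    for (a in seq_along(nms)) for (b in seq_along(nms))
      if (a < b) com_pairs[[length(com_pairs) + 1L]] <- c(nms[a], nms[b])
  }
  for (pr in com_pairs) {
    if (!all(pr %in% names(dm)))
      stop("domain(s) missing from map: ",
           paste(setdiff(pr, names(dm)), collapse = ", "))
    col <- paste0("r_cm_", pr[1], "_", pr[2])
    out[[col]] <- vapply(seq_len(nf), function(f)
      com_distance(model$open, pr[1], pr[2], xyz = frames[f, , ]), 0)
  }
  class(out) <- c("coordinate_table", "data.frame")
  out
}

#' Mean and spread of a coordinate within an ensemble
#'
#' Population mean and standard deviation of a per-frame coordinate over the
#' frames carrying a given ensemble label (e.g. the rigid-body flexibility
#' sigma_lid is the standard deviation of the CORE-LID center-of-mass
#' distance over the open ensemble).
#'
#' @param series per-frame numeric coordinate.
#' @param labels per-frame ensemble labels, aligned with `series`.
#' @param which ensemble to summarise (`"O"`, `"TS"` or `"C"`).
#' @return list with `mean` and `sd` (population, i.e. divisor N).
#' @export
dispersion <- function(series, labels, which = c("O", "TS", "C")) {
  which <- match.arg(which)
  if (length(series) != length(labels))
    stop("series and labels must be aligned")
  v <- series[labels == which]
  if (!length(v)) stop("ensemble '", which, "' is empty")
  m <- mean(v)
  list(mean = m, sd = sqrt(mean((v - m)^2)))
}
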