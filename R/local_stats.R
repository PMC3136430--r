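#' Per-residue pseudodihedral reference values
#'
#' For each interior residue, the native pseudodihedral in the open and
#' closed references, their wrapped difference, and the reference rule: if
#' `|delta_alpha| < 20` degrees the reference is the (circular) average of
#' the two native values; otherwise three candidate references are used (the
#' O value, the C value, and their midpoint) and the highest within-window
#' probability among the three is taken.
#'
#' @param open,closed reference [calpha_structure()]s.
#' @return data.frame of class `dihedral_reference`: `residue`, `alpha_O`,
#'   `alpha_C`, `delta` (wrapped, degrees), `rule`
#'   (`"single-average"`/`"three-candidate"`), `ref_avg` (circular
#'   midpoint).
#' @export
dihedral_reference <- function(open, closed) {
  aO <- pseudodihedrals(open)
  aC <- pseudodihedrals(closed)
  delta <- wrap_angle(aC - aO)
  ref <- wrap_angle(aO + delta / 2)
  out <- data.frame(residue = seq_along(aO), alpha_O = aO, alpha_C = aC,
                    delta = delta,
                    rule = ifelse(abs(delta) < 20, "single-average",
                                  "three-candidate"),
                    ref_avg = ref)
  out$rule[is.na(delta)] <- NA
  class(out) <- c("dihedral_reference", "data.frame")
  out
}

ensemble_masks <- function(part) {
  lab <- part$labels
  list(O = lab == "O", C = lab == "C",
       TS_closing = lab == "TS" & part$direction == "closing" &
         !is.na(part$direction),
       TS_opening = lab == "TS" & part$direction == "opening" &
         !is.na(part$direction))
}

win_frac <- function(angles, ref, window) {
  ok <- !is.na(angles)
  if (!any(ok)) return(NA_real_)
  mean(angular_distance(angles[ok], ref) <= window)
}

#' Per-residue backbone foldedness by ensemble
#'
#' The probability, within each ensemble, that a residue's pseudodihedral
#' lies in the same rotamer as its native reference (minimal angular
#' distance at most `window`; 60 degrees for p_folded, 20 for the
#' order-parameter-like p_rigid). The TS value is the unweighted mean of
#' the closing- and opening-direction values. Empty ensembles propagate as
#' `NA`, never as zero.
#'
#' @param angle_series frames x residues matrix of pseudodihedrals
#'   (degrees), e.g. from trajectory frames.
#' @param refs a [dihedral_reference()].
#' @param part an [partition()] ensemble partition aligned with the rows.
#' @param window rotamer window in degrees (60 or 20).
#' @return data.frame of class `residue_stat_table`: per residue `p_O`,
#'   `p_C`, `p_TS_closing`, `p_TS_opening`, `p_TS`, plus the reference
#'   columns.
#' @export
p_folded <- function(angle_series, refs, part, window = 60) {
  if (nrow(angle_series) != length(part$labels))
    stop("angle series and partition must be aligned")
  masks <- ensemble_masks(part)
  n <- ncol(angle_series)
  res <- refs[match(seq_len(n), refs$residue), , drop = FALSE]
  pcols <- matrix(NA_real_, n, length(masks),
                  dimnames = list(NULL, paste0("p_", names(masks))))
  for (r in seq_len(n)) {
    if (is.na(res$rule[r])) next
    cands <- if (res$rule[r] == "single-average") res$ref_avg[r] else
      c(res$alpha_O[r], res$alpha_C[r], res$ref_avg[r])
    for (e in seq_along(masks)) {
      m <- masks[[e]]
      if (!any(m)) next
      pcols[r, e] <- max(vapply(cands, function(cr)
        win_frac(angle_series[m, r], cr, window), 0))
    }
  }
  out <- cbind(res[, c("residue", "alpha_O", "alpha_C", "delta", "rule")],
               as.data.frame(pcols))
  out$p_TS <- (out$p_TS_closing + out$p_TS_opening) / 2
  attr(out, "window") <- window
  class(out) <- c("residue_stat_table", "data.frame")
  out
}

#' Per-contact formation probabilities by ensemble
#'
#' For each contact, the fraction of frames in each ensemble whose C-alpha
#' distance is within `ratio` times the native distance. The TS value is the
#' unweighted mean of the closing and opening directional values; empty
#' ensembles propagate as `NA`.
#'
#' @param frames trajectory frame array (`nframes x n x 3`).
#' @param contacts contact data.frame (`i`, `j`, `r0`, optionally
#'   `provenance`).
#' @param part ensemble partition aligned with the frames.
#' @param ratio formation criterion multiplier.
#' @return data.frame of class `contact_stat_table` with `p_O`, `p_C`,
#'   `p_TS_closing`, `p_TS_opening`, `p_TS`.
#' @export
contact_probabilities <- function(frames, contacts, part, ratio = 1.1) {
  if (dim(frames)[1] != length(part$labels))
    stop("frames and partition must be aligned")
  formed <- fraction_contacts_frames(frames, contacts, ratio)
  masks <- ensemble_masks(part)
  out <- contacts[, intersect(c("i", "j", "r0", "provenance"),
                              names(contacts)), drop = FALSE]
  for (e in names(masks)) {
    m <- masks[[e]]
    out[[paste0("p_", e)]] <- if (any(m))
      colMeans(formed[m, , drop = FALSE]) else NA_real_
  }
  out$p_TS <- (out$p_TS_closing + out$p_TS_opening) / 2
  rownames(out) <- NULL
  class(out) <- c("contact_stat_table", "data.frame")
  out
}

#' Classify contacts as open- or closed-characteristic
#'
#' A contact is O-characteristic when `p_O - p_C >= delta` and
#' C-characteristic when `p_C - p_O >= delta`. Display flags follow the
#' plotting convention: only contacts with `max(p_O, p_C) >= display_floor`
#' are shown, binned by `p_TS` at 0.5 and 0.7.
#'
#' @param table a [contact_probabilities()] result.
#' @param delta characteristic-contact threshold (default 0.2).
#' @param display_floor display threshold on `max(p_O, p_C)` (default 0.5).
#' @return the table with `class` (`"O"`, `"C"`, `"neither"`), `display`
#'   (logical), and `p_TS_bin` (`">=0.7"`, `"0.5-0.7"`, `"<0.5"`).
#' @export
classify <- function(table, delta = 0.2, display_floor = 0.5) {
  dp <- table$p_O - table$p_C
  cls <- rep("neither", nrow(table))
  cls[dp >= delta] <- "O"
  cls[-dp >= delta] <- "C"
  cls[is.na(dp)] <- NA
  table$class <- cls
  table$display <- pmax(table$p_O, table$p_C) >= display_floor
  table$p_TS_bin <- cut(table$p_TS, c(-Inf, 0.5, 0.7, Inf),
                        labels = c("<0.5", "0.5-0.7", ">=0.7"),
                        right = FALSE)
  table
}

#' Difference tables between two simulations
#'
#' Per-contact (or per-residue) probability differences `A - B` (call with
#' the perturbed simulation as `A` and the reference as `B`). For contact
#' tables the display set contains contacts that are O- or C-characteristic
#' in either simulation with `|delta p| >= min_delta` (inclusive) in that
#' ensemble; all differences are retained in the data columns regardless.
#' Missing values propagate as missing.
#'
#' @param tableA,tableB classified [contact_probabilities()] tables or
#'   [p_folded()] residue tables sharing keys (outer join; fully disjoint
#'   keys are an error).
#' @param min_delta display threshold on `|delta p|`.
#' @param delta characteristic threshold used if the tables are not yet
#'   classified.
#' @return data.frame with the joined keys, `dp_O`, `dp_TS`, `dp_C`
#'   (`dp_folded_*` for residue tables) and, for contacts, per-ensemble
#'   `display_*` flags.
#' @export
compare <- function(tableA, tableB, min_delta = 0.1, delta = 0.2) {
  if (all(c("i", "j") %in% names(tableA))) {
    if (is.null(tableA$class)) tableA <- classify(tableA, delta)
    if (is.null(tableB$class)) tableB <- classify(tableB, delta)
    keyA <- paste(tableA$i, tableA$j)
    keyB <- paste(tableB$i, tableB$j)
    if (!length(intersect(keyA, keyB)))
      stop("contact keys are disjoint between the two tables")
    keys <- union(keyA, keyB)
    ia <- match(keys, keyA); ib <- match(keys, keyB)
    ij <- do.call(rbind, strsplit(keys, " "))
    out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
    char_either <- (tableA$class[ia] %in% c("O", "C")) |
      (tableB$class[ib] %in% c("O", "C"))
    for (e in c("O", "TS", "C")) {
      d <- tableA[[paste0("p_", e)]][ia] - tableB[[paste0("p_", e)]][ib]
      out[[paste0("dp_", e)]] <- d
      # inclusive threshold, robust to float representation of the boundary
      out[[paste0("display_", e)]] <- char_either & !is.na(d) &
        abs(d) >= min_delta - 1e-9
    }
    out$char_either <- char_either
    out[order(out$i, out$j), , drop = FALSE]
  } else if ("residue" %in% names(tableA)) {
    keys <- union(tableA$residue, tableB$residue)
    if (!length(intersect(tableA$residue, tableB$residue)))
      stop("residue keys are disjoint between the two tables")
    ia <- match(keys, tableA$residue); ib <- match(keys, tableB$residue)
    out <- data.frame(residue = keys)
    for (e in c("O", "TS", "C")) {
      d <- tableA[[paste0("p_", e)]][ia] - tableB[[paste0("p_", e)]][ib]
      out[[paste0("dp_folded_", e)]] <- d
      out[[paste0("display_", e)]] <- !is.na(d) & abs(d) >= min_delta - 1e-9
    }
    out[order(out$residue), , drop = FALSE]
  } else stop("unrecognised table type")
}
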