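#' Potential of mean force from projected samples
#'
#' One- or two-dimensional PMF from the raw histogram of an equilibrium
#' trajectory (no reweighting: the simulation samples the mixed potential
#' directly): `F(bin) = -kB T ln(count / max_count)` in kcal/mol, so the
#' most occupied bin sits at zero. Empty bins are `NA`.
#'
#' @param x samples along the first coordinate.
#' @param y optional samples along a second coordinate.
#' @param temperature simulation temperature (K).
#' @param bins bins per axis (default 40 over the observed range padded 2%).
#' @param names axis names recorded on the grid.
#' @return object of class `pmf_grid`: bin `edges`/`centers` per axis,
#'   free-energy `F` (vector or matrix, kcal/mol), occupancy `counts`,
#'   `temperature`.
#' @export
pmf <- function(x, y = NULL, temperature = 300, bins = 40L,
                names = c("x", "y")) {
  stopifnot(temperature > 0)
  if (!is.null(y) && length(y) != length(x))
    stop("x and y must be aligned")
  kt <- KB_KCAL * temperature
  ax <- function(v) {
    r <- range(v)
    pad <- diff(r) * 0.02
    if (pad == 0) pad <- max(abs(r[1]), 1) * 0.01
    seq(r[1] - pad, r[2] + pad, length.out = bins + 1L)
  }
  ex <- ax(x)
  bx <- pmin(pmax(findInterval(x, ex, all.inside = TRUE), 1L), bins)
  if (is.null(y)) {
    counts <- tabulate(bx, bins)
  } else {
    ey <- ax(y)
    by <- pmin(pmax(findInterval(y, ey, all.inside = TRUE), 1L), bins)
    counts <- matrix(tabulate((by - 1L) * bins + bx, bins * bins),
                     bins, bins)
  }
  if (sum(counts > 0) == 1L)
    warning("all samples fall in one bin; degenerate grid")
  F <- -kt * log(counts / max(counts))
  F[counts == 0] <- NA_real_
  out <- list(edges = if (is.null(y)) list(ex) else list(ex, ey),
              centers = if (is.null(y)) list((ex[-1] + ex[-length(ex)]) / 2)
                else list((ex[-1] + ex[-length(ex)]) / 2,
                          (ey[-1] + ey[-length(ey)]) / 2),
              F = F, counts = counts, temperature = temperature,
              names = names[seq_len(if (is.null(y)) 1 else 2)])
  class(out) <- "pmf_grid"
  out
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("PMF grid over ", paste(x$names, collapse = " x "), ": ",
      paste(dim(as.matrix(x$F)), collapse = " x "), " bins, ",
      sum(x$counts > 0), " occupied, range ",
      sprintf("%.2f", max(x$F, na.rm = TRUE)), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Mean ensemble positions on PMF axes
#'
#' Average position of the O, TS and C ensembles along the PMF coordinates,
#' for annotating landscapes.
#'
#' @param part an [partition()] result.
#' @param ... named per-frame coordinate vectors.
#' @return data.frame: ensemble x coordinate means.
#' @export
ensemble_positions <- function(part, ...) {
  coords <- list(...)
  labs <- c("O", "TS", "C")
  out <- data.frame(ensemble = labs)
  for (nm in names(coords))
    out[[nm]] <- vapply(labs, function(l) {
      v <- coords[[nm]][part$labels == l]
      if (length(v)) mean(v) else NA_real_
    }, 0)
  out
}

#' Plot a PMF grid
#'
#' 1-D grids are drawn as free-energy profiles; 2-D grids as filled contour
#' maps with contours spaced 0.5 kcal/mol apart, optionally annotated with
#' ensemble mean positions from [ensemble_positions()].
#'
#' @param x a [pmf()] grid.
#' @param positions optional data.frame from [ensemble_positions()] whose
#'   coordinate columns match the grid axes.
#' @param contour_by contour spacing in kcal/mol.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.pmf_grid <- function(x, positions = NULL, contour_by = 0.5, ...) {
  if (length(x$centers) == 1L) {
    plot(x$centers[[1]], x$F, type = "l", xlab = x$names[1],
         ylab = "F (kcal/mol)", ...)
  } else {
    z <- x$F
    zmax <- max(z, na.rm = TRUE)
    graphics::image(x$centers[[1]], x$centers[[2]], z,
                    col = grDevices::hcl.colors(24, "YlGnBu", rev = TRUE),
                    xlab = x$names[1], ylab = x$names[2], ...)
    graphics::contour(x$centers[[1]], x$centers[[2]], z,
                      levels = seq(0, zmax, by = contour_by),
                      add = TRUE, drawlabels = FALSE)
    if (!is.null(positions) && all(x$names %in% names(positions)))
      graphics::text(positions[[x$names[1]]], positions[[x$names[2]]],
                     labels = positions$ensemble, font = 2, col = "red")
  }
  invisible(x)
}

#' Export a PMF grid as a data frame
#' @param x a [pmf()] grid.
#' @param ... unused.
#' @return data.frame of bin centers, counts and free energies.
#' @export
as.data.frame.pmf_grid <- function(x, ...) {
  if (length(x$centers) == 1L) {
    data.frame(stats::setNames(list(x$centers[[1]]), x$names[1]),
               count = x$counts, F = x$F)
  } else {
    g <- expand.grid(x$centers[[1]], x$centers[[2]])
    names(g) <- x$names
    g$count <- as.vector(x$counts)
    g$F <- as.vector(x$F)
    g
  }
}
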