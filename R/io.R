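#' Read a toy/system plain-text config (domains and ligand contacts)
#'
#' Parses the format written by [write_toy_system()]: a `[domains]` section
#' of `name = first-last` inclusive ranges and a `[ligand_contacts]` section
#' of `i j` pairs.
#'
#' @param path config file path.
#' @return list with `domain_map` (named list of integer vectors) and
#'   `ligand_contacts` (2-column integer matrix).
#' @export
read_system_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  domain_map <- list()
  lig <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else if (identical(section, "domains")) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed domain line: ", ln)
      rng <- as.integer(strsplit(trimws(kv[2]), "-", fixed = TRUE)[[1]])
      domain_map[[trimws(kv[1])]] <- rng[1]:rng[2]
    } else if (identical(section, "ligand_contacts")) {
      lig[[length(lig) + 1L]] <- as.integer(strsplit(ln, "\\s+")[[1]])
    }
  }
  lc <- if (length(lig)) do.call(rbind, lig) else matrix(integer(), 0, 2)
  colnames(lc) <- c("i", "j")
  list(domain_map = domain_map, ligand_contacts = lc)
}

#' Apply a per-contact energy override table
#'
#' Merges a table (data.frame or TSV path with columns `i`, `j`, `eps`)
#' into a contact list, replacing the uniform base depth for the listed
#' pairs. Pairs absent from the contact list are an error (they would
#' silently change the model's topology).
#'
#' @param contacts contact data.frame from [build_contacts()].
#' @param overrides data.frame or path to a TSV with `i`, `j`, `eps`.
#' @return the contact data.frame with updated `eps`.
#' @export
apply_contact_energies <- function(contacts, overrides) {
  if (is.character(overrides))
    overrides <- utils::read.table(overrides, header = TRUE, sep = "\t")
  stopifnot(all(c("i", "j", "eps") %in% names(overrides)))
  n <- max(contacts$j, overrides$j)
  idx <- match(pair_key(overrides$i, overrides$j, n),
               pair_key(contacts$i, contacts$j, n))
  if (anyNA(idx))
    stop("override pairs not in the contact list: ",
         paste(sprintf("(%d,%d)", overrides$i[is.na(idx)],
                       overrides$j[is.na(idx)]), collapse = " "))
  contacts$eps[idx] <- overrides$eps
  contacts
}

MODEL_FORMAT_VERSION <- 1L

#' Save a double-well model as a self-describing text file
#'
#' Writes a versioned plain-text serialisation (R `dput` syntax) of the
#' complete model: both single-well potentials, the mixing parameters and
#' the reference structures.
#'
#' @param model a [double_well_model()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
save_model <- function(model, file) {
  strip <- function(pot) {
    pot$structure <- NULL
    unclass(pot)
  }
  payload <- list(format = "dwgo_model", version = MODEL_FORMAT_VERSION,
                  eps_O = model$eps_O, beta_mix = model$beta_mix,
                  V_O = strip(model$V_O), V_C = strip(model$V_C),
                  open = unclass(model$open), closed = unclass(model$closed))
  dput(payload, file = file)
  invisible(file)
}

#' Load a double-well model written by [save_model()]
#'
#' @param file path written by [save_model()].
#' @return a [double_well_model()].
#' @export
load_model <- function(file) {
  p <- dget(file)
  if (!identical(p$format, "dwgo_model"))
    stop("not a dwgo model file")
  if (p$version > MODEL_FORMAT_VERSION)
    stop("model file version ", p$version, " is newer than this package")
  open <- structure(p$open, class = "calpha_structure")
  closed <- structure(p$closed, class = "calpha_structure")
  revive <- function(raw, str) {
    raw$structure <- str
    structure(raw, class = "go_potential")
  }
  double_well_model(revive(p$V_O, open), revive(p$V_C, closed),
                    eps_O = p$eps_O, beta_mix = p$beta_mix,
                    open = open, closed = closed)
}

#' Write a trajectory's frames and energies as plain-text tables
#'
#' `energies.tsv` holds the per-frame total and single-well energies;
#' `frames.tsv` holds the strided coordinates in long format
#' (frame, residue, x, y, z).
#'
#' @param trajectory a [run_langevin()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  en <- cbind(frame = seq_len(nrow(trajectory$energies)),
              trajectory$energies)
  utils::write.table(en, file.path(dir, "energies.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  d <- dim(trajectory$frames)
  long <- data.frame(frame = rep(seq_len(d[1]), d[2]),
                     residue = rep(seq_len(d[2]), each = d[1]),
                     x = as.vector(trajectory$frames[, , 1]),
                     y = as.vector(trajectory$frames[, , 2]),
                     z = as.vector(trajectory$frames[, , 3]))
  utils::write.table(long, file.path(dir, "frames.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("model_hash %s", trajectory$model_hash),
               sprintf("seed %d", trajectory$seed),
               sprintf("n_frames %d", d[1])),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
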