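## PDB v3.3 fixed-column reader/writer.  Handles single structures and
## multi-model trajectories (MODEL/ENDMDL) with per-model CRYST1 records.

#' Read a PDB file
#'
#' Parses ATOM/HETATM records using PDB v3.3 column positions (residue
#' names are read from columns 18-21 to accommodate four-character lipid
#' residue names) and CRYST1 box records.  Multi-model files yield one
#' frame per MODEL block.
#'
#' @param path path to a PDB file.
#' @return a list with `atoms` (an [atom_table()] data frame) and `frames`
#'   (a list of frames, each with `coords`, `box`, `index`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_cryst <- startsWith(lines, "CRYST1")
  is_model <- startsWith(lines, "MODEL")

  model_starts <- which(is_model)
  n_models <- max(1L, length(model_starts))

  ## assign each atom line to a model
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("no ATOM/HETATM records in ", path)
  if (length(model_starts) > 0L) {
    model_of <- findInterval(atom_idx, model_starts)
    if (any(model_of == 0L)) stop("ATOM records before first MODEL in ", path)
  } else {
    model_of <- rep(1L, length(atom_idx))
  }

  first <- atom_idx[model_of == 1L]
  al <- lines[first]
  atoms <- data.frame(
    name    = trimws(substr(al, 13, 16)),
    resname = trimws(substr(al, 18, 21)),
    resid   = as.integer(trimws(substr(al, 23, 26))),
    segid   = trimws(substr(al, 73, 76)),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  blank <- atoms$element == ""
  atoms$element[blank] <- guess_element(atoms$name[blank])
  atoms$element <- toupper(atoms$element)
  atoms$mass <- element_mass(atoms$element)
  atoms$charge <- NA_real_
  atoms <- atom_table(atoms)

  parse_coords <- function(ln) {
    cbind(as.numeric(substr(ln, 31, 38)),
          as.numeric(substr(ln, 39, 46)),
          as.numeric(substr(ln, 47, 54)))
  }

  cryst_box <- function(ln) {
    abc <- c(as.numeric(substr(ln, 7, 15)),
             as.numeric(substr(ln, 16, 24)),
             as.numeric(substr(ln, 25, 33)))
    ang <- c(as.numeric(substr(ln, 34, 40)),
             as.numeric(substr(ln, 41, 47)),
             as.numeric(substr(ln, 48, 54)))
    if (any(abs(ang - 90) > 1e-4)) {
      stop("triclinic boxes are not supported (angles ", paste(ang, collapse = ", "), ")")
    }
    abc
  }

  cryst_idx <- which(is_cryst)
  global_box <- if (length(cryst_idx) > 0L) cryst_box(lines[cryst_idx[1]]) else NULL

  frames <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    ln <- lines[atom_idx[model_of == m]]
    if (length(ln) != nrow(atoms)) {
      stop("model ", m, " has ", length(ln), " atoms, expected ", nrow(atoms))
    }
    box <- global_box
    if (length(model_starts) > 0L) {
      ## CRYST1 inside this model block overrides the global one
      lo <- model_starts[m]
      hi <- if (m < length(model_starts)) model_starts[m + 1L] else length(lines)
      cm <- cryst_idx[cryst_idx > lo & cryst_idx < hi]
      if (length(cm) > 0L) box <- cryst_box(lines[cm[1]])
    }
    frames[[m]] <- new_frame(parse_coords(ln), box = box, index = m - 1L)
  }
  list(atoms = atoms, frames = frames)
}

#' Write a PDB file
#'
#' Writes one model per frame, with a CRYST1 record when box dimensions
#' are available.  Numbers wider than the fixed columns raise an error.
#'
#' @param atoms an [atom_table()].
#' @param frames a single frame or list of frames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, frames, path) {
  if (!is.null(frames$coords)) frames <- list(frames)
  con <- file(path, open = "wb")
  on.exit(close(con))
  multi <- length(frames) > 1L

  nm <- atoms$name
  ## PDB convention: names of <4 chars start in column 14
  nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  serial <- seq_len(nrow(atoms)) %% 100000L

  emit <- function(txt) writeLines(txt, con, sep = "\n")

  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.null(fr$box)) {
      emit(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   fr$box[1], fr$box[2], fr$box[3], 90, 90, 90))
    }
    if (multi) emit(sprintf("MODEL     %4d", i))
    emit(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
                 serial, nm4, substr(atoms$resname, 1, 4),
                 atoms$resid %% 10000L,
                 fr$coords[, 1], fr$coords[, 2], fr$coords[, 3],
                 1, 0, substr(atoms$segid, 1, 4), substr(atoms$element, 1, 2)))
    if (multi) emit("ENDMDL")
  }
  emit("END")
  invisible(path)
}
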