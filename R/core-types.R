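## Core containers: the atom table (static topology), frames (one
## trajectory snapshot), and the TSV time-series table written by every
## analysis.

#' Construct/validate an atom table
#'
#' The static topology shared by all frames: one row per atom with name,
#' element, residue name, integer residue id, segment id, mass (amu) and
#' optional partial charge (e).
#'
#' @param df data frame with columns `name`, `resname`, `resid`, `segid`;
#'   `element`, `mass`, `charge` are filled in when absent.
#' @return the validated data frame with class `atom_table`.
#' @export
atom_table <- function(df) {
  req <- c("name", "resname", "resid", "segid")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 1L) stop("atom table must contain at least one atom")
  if (is.null(df$element)) df$element <- guess_element(df$name)
  df$element <- toupper(df$element)
  if (is.null(df$mass)) df$mass <- element_mass(df$element)
  if (is.null(df$charge)) df$charge <- NA_real_
  df$resid <- as.integer(df$resid)
  if (any(!is.finite(df$mass)) || any(df$mass <= 0)) stop("atom masses must be positive")
  ## residue ids must be non-decreasing within a segment
  for (sg in unique(df$segid)) {
    r <- df$resid[df$segid == sg]
    if (is.unsorted(r)) stop("residue ids not non-decreasing in segment ", sg)
  }
  class(df) <- c("atom_table", "data.frame")
  df
}

#' Construct a trajectory frame
#'
#' @param coords N x 3 numeric matrix of coordinates in Angstrom.
#' @param box orthorhombic box lengths `c(Lx, Ly, Lz)` in Angstrom, or NULL.
#' @param index 0-based global frame index.
#' @param time time in ps, or NA.
#' @return a `frame` object (list with `coords`, `box`, `index`, `time`).
#' @export
new_frame <- function(coords, box = NULL, index = 0L, time = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths")
    }
  }
  structure(list(coords = coords, box = box, index = as.integer(index),
                 time = time), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame", x$index, ":", nrow(x$coords), "atoms",
      if (!is.null(x$box)) paste0("box ", paste(signif(x$box, 6), collapse = " x ")),
      ">\n")
  invisible(x)
}

#' Write a time-series table as TSV
#'
#' One row per analyzed frame, a single `#`-prefixed header line, and
#' tab-separated numeric columns.  This is the on-disk format of every
#' analysis output.
#'
#' @param df data frame.
#' @param path output path.
#' @param digits significant digits used for numeric formatting.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, digits = 10) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con, sep = "\n")
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      formatC(col, digits = digits, format = "g")
    } else {
      as.character(col)
    }
  })
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv_table()]
#' @param path file path.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing '#' header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          col.names = cols, stringsAsFactors = FALSE)
  df
}
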