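## CHARMM/X-PLOR DCD binary trajectory format.  Fortran unformatted
## records (4-byte length markers), single-precision coordinates, and an
## optional per-frame unit-cell record of six doubles.  Only orthorhombic
## cells are supported; cell angles are written in degrees (X-PLOR style)
## and read either as degrees or as cosines (CHARMM style).

#' Write a DCD trajectory
#'
#' @param frames list of frames (each with `coords` N x 3 and `box`).
#' @param path output path.
#' @param title title string embedded in the header.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(frames, path, title = "generated trajectory") {
  if (!is.null(frames$coords)) frames <- list(frames)
  n_frames <- length(frames)
  if (n_frames == 0L) stop("no frames to write")
  natom <- nrow(frames[[1]]$coords)
  has_box <- !is.null(frames[[1]]$box)

  con <- file(path, open = "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  ## header record: "CORD" + 20 control integers (slot 10 is a float)
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(c(n_frames, 1L, 1L, n_frames, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4L, endian = "little")   # DELTA as C float
  wint(c(if (has_box) 1L else 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)

  ## title record
  t80 <- sprintf("%-80s", substr(title, 1, 80))
  wint(84L)
  wint(1L)
  writeChar(t80, con, nchars = 80L, eos = NULL)
  wint(84L)

  ## atom-count record
  wint(4L)
  wint(natom)
  wint(4L)

  for (fr in frames) {
    if (nrow(fr$coords) != natom) stop("inconsistent atom count across frames")
    if (has_box) {
      b <- fr$box
      wint(48L)
      writeBin(as.double(c(b[1], 90, b[2], 90, 90, b[3])), con,
               size = 8L, endian = "little")
      wint(48L)
    }
    for (d in 1:3) {
      wint(4L * natom)
      writeBin(as.double(fr$coords[, d]), con, size = 4L, endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' @param path path to a DCD file.
#' @return list of frames (`coords`, `box` or NULL, `index` local 0-based).
#' @export
read_dcd <- function(path) {
  if (!file.exists(path)) stop("DCD file not found: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  rint <- function(n = 1L) readBin(con, "integer", n = n, size = 4L, endian = "little")

  m <- rint()
  if (length(m) == 0L || m != 84L) {
    stop("not a DCD file (bad header record length): ", path)
  }
  magic <- readChar(con, nchars = 4L, useBytes = TRUE)
  if (magic != "CORD") stop("not a coordinate DCD file: ", path)
  icntrl_a <- rint(9L)
  readBin(con, "double", n = 1L, size = 4L, endian = "little")  # DELTA
  icntrl_b <- rint(10L)
  if (rint() != 84L) stop("corrupt DCD header in ", path)
  n_frames <- icntrl_a[1]
  has_box <- icntrl_b[1] == 1L

  tlen <- rint()
  ntitle <- rint()
  readChar(con, nchars = 80L * ntitle, useBytes = TRUE)
  if (rint() != tlen) stop("corrupt DCD title record in ", path)

  if (rint() != 4L) stop("corrupt DCD atom record in ", path)
  natom <- rint()
  rint()

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    box <- NULL
    if (has_box) {
      if (rint() != 48L) stop("corrupt cell record at frame ", i, " in ", path)
      cell <- readBin(con, "double", n = 6L, size = 8L, endian = "little")
      rint()
      ang <- cell[c(2, 4, 5)]
      if (all(abs(ang) <= 1)) ang <- acos(ang) * 180 / pi  # CHARMM cosines
      if (any(abs(ang - 90) > 1e-4)) {
        stop("triclinic boxes are not supported (frame ", i, " in ", path, ")")
      }
      box <- cell[c(1, 3, 6)]
    }
    coords <- matrix(NA_real_, natom, 3L)
    for (d in 1:3) {
      if (rint() != 4L * natom) {
        stop("corrupt coordinate record at frame ", i, " in ", path)
      }
      v <- readBin(con, "double", n = natom, size = 4L, endian = "little")
      if (length(v) != natom) stop("truncated frame ", i, " in ", path)
      rint()
      coords[, d] <- v
    }
    frames[[i]] <- new_frame(coords, box = box, index = i - 1L)
  }
  frames
}
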