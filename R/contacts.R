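## Contact and distribution analyses: group geometry statistics, residue
## contact maps, residence times, radial distribution functions.

#' Group distance / angle / dihedral statistics
#'
#' Each group (2-4 of them) is reduced to its mass-weighted COM per frame
#' and [measure_internal()] is applied; the 2-group distance uses the
#' minimum-image convention when box dimensions are available.
#'
#' @param frames list of frames.
#' @param group_sels list of 2-4 selection expressions.
#' @param atoms the [atom_table()].
#' @return list with `series` (`frame`, `time`, `value`), `mean`, and `sd`
#'   (population SD over frames).
#' @export
bond_statistics <- function(frames, group_sels, atoms) {
  ng <- length(group_sels)
  if (!ng %in% 2:4) stop("bond_statistics needs 2-4 groups")
  idx <- lapply(group_sels, parse_selection, atoms = atoms)
  for (k in seq_len(ng)) {
    if (length(idx[[k]]) == 0L) stop("empty group ", k)
  }
  rows <- lapply(frames, function(fr) {
    pts <- do.call(rbind, lapply(idx, function(gi) {
      center_of_mass(fr$coords[gi, , drop = FALSE], atoms$mass[gi])
    }))
    v <- if (ng == 2L && !is.null(fr$box)) {
      sqrt(sum(minimum_image_displacement(pts[1, ], pts[2, ], fr$box)^2))
    } else {
      measure_internal(pts)
    }
    data.frame(frame = fr$index, time = fr$time, value = v)
  })
  series <- do.call(rbind, rows)
  list(series = series, mean = mean(series$value),
       sd = sqrt(mean((series$value - mean(series$value))^2)))
}

heavy_atoms <- function(idx, atoms) idx[atoms$element[idx] != "H"]

#' Residue contact frequencies
#'
#' Two residues are in contact in a frame iff the minimum heavy-atom
#' distance between them is at most `cutoff`.  The output lists each
#' contacting pair with its contact frequency (fraction of frames),
#' sorted by frequency descending (ties by residue ids ascending), plus
#' the per-frame boolean series used by [contact_residence_time()].
#'
#' @param frames list of frames.
#' @param selA,selB selection expressions for the two sides.
#' @param atoms the [atom_table()].
#' @param cutoff heavy-atom distance cutoff (Angstrom; default 4.5).
#' @return data frame (`resA`, `resB`, `frequency`, `frames`
#'   comma-joined 0-based indices) with attribute `series` (named list of
#'   logical vectors, one per pair).
#' @export
residue_contacts <- function(frames, selA, selB, atoms, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ia <- heavy_atoms(parse_selection(selA, atoms), atoms)
  ib <- heavy_atoms(parse_selection(selB, atoms), atoms)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  if (length(intersect(ia, ib)) > 0L) {
    warning("selections overlap; self residue pairs are excluded")
  }
  keyA <- paste(atoms$segid[ia], atoms$resid[ia], sep = "/")
  keyB <- paste(atoms$segid[ib], atoms$resid[ib], sep = "/")
  resA <- unique(keyA); resB <- unique(keyB)

  hits <- list()
  for (t in seq_along(frames)) {
    fr <- frames[[t]]
    ca <- fr$coords[ia, , drop = FALSE]
    cb <- fr$coords[ib, , drop = FALSE]
    ## pairwise heavy-atom distances (sizes are modest at analysis scale)
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
    close <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(close) == 0L) next
    pairs <- unique(data.frame(a = keyA[close[, 1]], b = keyB[close[, 2]],
                               stringsAsFactors = FALSE))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      key <- paste(pairs$a[p], pairs$b[p], sep = "|")
      hits[[key]] <- c(hits[[key]], t)
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(resA = character(0), resB = character(0),
                      frequency = numeric(0), frames = character(0))
    attr(out, "series") <- list()
    return(out)
  }
  nfr <- length(frames)
  frame_index <- vapply(frames, function(fr) fr$index, integer(1))
  parts <- strsplit(names(hits), "|", fixed = TRUE)
  out <- data.frame(resA = vapply(parts, `[`, "", 1L),
                    resB = vapply(parts, `[`, "", 2L),
                    frequency = lengths(hits) / nfr,
                    frames = vapply(hits, function(h) {
                      paste(frame_index[h], collapse = ",")
                    }, character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-out$frequency, out$resA, out$resB)
  series <- lapply(hits, function(h) {
    v <- rep(FALSE, nfr); v[h] <- TRUE; v
  })
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "series") <- series[ord]
  out
}

#' Contact residence-time statistics
#'
#' Durations are the lengths of maximal runs of `TRUE` in each pair's
#' boolean contact series; runs touching either end of the trajectory are
#' counted as observed (no censoring correction).  SD is the population
#' standard deviation over runs; all-false series are omitted.
#'
#' @param series named list of logical vectors (as produced by
#'   [residue_contacts()]), or a single logical vector.
#' @return data frame (`pair`, `n_events`, `mean_frames`, `sd_frames`,
#'   `total_frames`).
#' @export
contact_residence_time <- function(series) {
  if (is.logical(series)) series <- list(pair = series)
  if (length(series) == 0L) stop("empty contact series")
  rows <- list()
  for (nm in names(series)) {
    s <- series[[nm]]
    r <- rle(s)
    dur <- r$lengths[r$values]
    if (length(dur) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair = nm, n_events = length(dur), mean_frames = mean(dur),
      sd_frames = sqrt(mean((dur - mean(dur))^2)),
      total_frames = sum(dur), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(pair = character(0), n_events = integer(0),
                      mean_frames = numeric(0), sd_frames = numeric(0),
                      total_frames = integer(0)))
  }
  do.call(rbind, rows)
}

#' Merge short gaps in a contact series
#'
#' Runs of `FALSE` of length at most `gap_tolerance` flanked by contacts
#' are treated as contact, merging the adjacent runs.
#'
#' @param s logical vector.
#' @param gap_tolerance maximum gap length to bridge (frames).
#' @return logical vector.
#' @export
bridge_contact_gaps <- function(s, gap_tolerance = 0L) {
  if (gap_tolerance < 1L) return(s)
  r <- rle(s)
  n <- length(r$lengths)
  for (k in seq_len(n)) {
    if (!r$values[k] && r$lengths[k] <= gap_tolerance && k > 1L && k < n) {
      r$values[k] <- TRUE
    }
  }
  inverse.rle(r)
}

#' Radial distribution function
#'
#' `g(r) = <n_AB(r)> / (N_A * rho_B * 4 pi r^2 dr)` with minimum-image
#' distances, `rho_B = N_B / V`, and self pairs excluded when the
#' selections overlap.
#'
#' @param frames list of frames.
#' @param selA,selB selection expressions.
#' @param atoms the [atom_table()].
#' @param bin_width bin width (Angstrom).
#' @param r_max maximum distance; must be at most half the smallest box
#'   length (minimum-image validity).
#' @return data frame (`r`, `g`) with attribute `mean_neighbors` (mean
#'   count of B within `r_max` of an A atom).
#' @export
radial_distribution <- function(frames, selA, selB, atoms, bin_width = 0.1,
                                r_max = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  ia <- parse_selection(selA, atoms)
  ib <- parse_selection(selB, atoms)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  box0 <- frames[[1]]$box
  if (is.null(box0)) stop("RDF requires box dimensions")
  if (is.null(r_max)) r_max <- min(box0) / 2
  if (r_max > min(box0) / 2 + 1e-9) {
    stop("r_max exceeds half the smallest box length (minimum-image validity)")
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- numeric(length(mids))
  total_within <- 0

  for (fr in frames) {
    box <- fr$box
    ca <- fr$coords[ia, , drop = FALSE]
    cb <- fr$coords[ib, , drop = FALSE]
    d2 <- matrix(0, length(ia), length(ib))
    for (d in 1:3) {
      dd <- outer(ca[, d], cb[, d], "-")
      dd <- dd - box[d] * floor(dd / box[d] + 0.5)
      d2 <- d2 + dd * dd
    }
    if (length(intersect(ia, ib)) > 0L) {
      self <- outer(ia, ib, "==")
      d2[self] <- Inf
    }
    r <- sqrt(d2[d2 <= r_max^2])
    total_within <- total_within + length(r)
    h <- graphics::hist(r, breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }

  nfr <- length(frames)
  V <- prod(box0)
  rho_b <- length(ib) / V
  shell <- 4 * pi * mids^2 * diff(breaks)
  g <- counts / nfr / (length(ia) * rho_b * shell)
  out <- data.frame(r = mids, g = g)
  attr(out, "mean_neighbors") <- total_within / nfr / length(ia)
  out
}
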