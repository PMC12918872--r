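## Membrane observables: leaflet assignment, area per lipid (periodic
## Voronoi), shell composition, deuterium order parameters, bilayer
## thickness, sterol tilt, area compressibility, z-density profiles,
## lateral diffusion, and group-position time series.

.kB <- 1.380649e-23  # J/K

## one Voronoi site per lipid: unique (segid, resid) among selected atoms;
## the site is the COM of the selected atoms of that lipid
lipid_sites <- function(frame, sel_idx, atoms) {
  if (length(sel_idx) == 0L) stop("empty lipid selection")
  lip <- paste(atoms$segid[sel_idx], atoms$resid[sel_idx])
  ids <- unique(lip)
  xyz <- matrix(NA_real_, length(ids), 3L)
  type <- character(length(ids))
  for (k in seq_along(ids)) {
    idx <- sel_idx[lip == ids[k]]
    xyz[k, ] <- center_of_mass(frame$coords[idx, , drop = FALSE], atoms$mass[idx])
    type[k] <- atoms$resname[idx[1]]
  }
  list(id = ids, xyz = xyz, type = type)
}

#' Assign lipids to bilayer leaflets
#'
#' A lipid belongs to the upper leaflet iff the z coordinate of its head
#' group (COM of atoms matched by `head_sel`) is at or above the membrane
#' midplane, taken as the mean head z over all selected lipids in this
#' frame (ties go upper).
#'
#' @param frame a frame.
#' @param head_sel selection expression for lipid head atoms.
#' @param atoms the [atom_table()].
#' @return data frame with `lipid` (segid/resid key), `type` (resname),
#'   `leaflet` ("upper"/"lower"), and site coordinates `x`, `y`, `z`.
#' @export
assign_leaflets <- function(frame, head_sel, atoms) {
  sel <- parse_selection(head_sel, atoms)
  if (length(sel) == 0L) stop("leaflet head selection matches no atoms")
  sites <- lipid_sites(frame, sel, atoms)
  mid <- mean(sites$xyz[, 3])
  data.frame(lipid = sites$id, type = sites$type,
             leaflet = ifelse(sites$xyz[, 3] >= mid, "upper", "lower"),
             x = sites$xyz[, 1], y = sites$xyz[, 2], z = sites$xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Per frame and leaflet, the xy positions of the lipid sites are
#' tessellated with [periodic_voronoi()]; a lipid's APL is its cell area,
#' so per-leaflet APLs sum exactly to the lateral box area.
#'
#' @param frames list of frames.
#' @param lipid_site_sel selection giving one site group per lipid
#'   (e.g. the phosphate).
#' @param atoms the [atom_table()].
#' @return data frame (`frame`, `leaflet`, `type`, `n_lipids`, `mean_apl`)
#'   with attribute `per_lipid`: data frame of every lipid's cell area.
#' @export
area_per_lipid <- function(frames, lipid_site_sel, atoms) {
  rows <- list(); per <- list()
  for (fr in frames) {
    if (is.null(fr$box)) stop("area_per_lipid requires box dimensions")
    lf <- assign_leaflets(fr, lipid_site_sel, atoms)
    for (side in c("upper", "lower")) {
      sub <- lf[lf$leaflet == side, , drop = FALSE]
      if (nrow(sub) == 0L) {
        warning("no lipids in ", side, " leaflet at frame ", fr$index)
        next
      }
      vd <- periodic_voronoi(cbind(sub$x, sub$y), fr$box[1:2])
      per[[length(per) + 1L]] <- data.frame(
        frame = fr$index, leaflet = side, lipid = sub$lipid,
        type = sub$type, apl = vd$areas, stringsAsFactors = FALSE)
      for (tp in unique(sub$type)) {
        rows[[length(rows) + 1L]] <- data.frame(
          frame = fr$index, leaflet = side, type = tp,
          n_lipids = sum(sub$type == tp),
          mean_apl = mean(vd$areas[sub$type == tp]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_lipid") <- do.call(rbind, per)
  out
}

#' Voronoi shell composition around a lipid type
#'
#' Shell 1 holds the Voronoi neighbors of each center-type site; shell k
#' holds the neighbors of shell k-1 not yet in any inner shell or the
#' center itself.  Counts are reported per lipid type, averaged over
#' centers, leaflets, and frames.
#'
#' @param frames list of frames.
#' @param lipid_site_sel selection giving one site per lipid.
#' @param center_type resname of the central lipid type.
#' @param atoms the [atom_table()].
#' @param n_shells number of shells (>= 1).
#' @return data frame (`shell`, `type`, `mean_count`).
#' @export
shell_composition <- function(frames, lipid_site_sel, center_type, atoms,
                              n_shells = 1L) {
  if (n_shells < 1L) stop("n_shells must be >= 1")
  acc <- list()  # accumulate per-center counts
  n_centers <- 0L
  for (fr in frames) {
    lf <- assign_leaflets(fr, lipid_site_sel, atoms)
    for (side in c("upper", "lower")) {
      sub <- lf[lf$leaflet == side, , drop = FALSE]
      centers <- which(sub$type == center_type)
      if (nrow(sub) < 2L || length(centers) == 0L) next
      vd <- periodic_voronoi(cbind(sub$x, sub$y), fr$box[1:2])
      for (c0 in centers) {
        n_centers <- n_centers + 1L
        seen <- c0
        current <- c0
        for (sh in seq_len(n_shells)) {
          nxt <- setdiff(sort(unique(unlist(vd$neighbors[current]))), seen)
          for (tp in unique(sub$type[nxt])) {
            key <- paste(sh, tp)
            acc[[key]] <- (acc[[key]] %||% 0) + sum(sub$type[nxt] == tp)
          }
          seen <- c(seen, nxt)
          current <- nxt
          if (length(current) == 0L) break
        }
      }
    }
  }
  if (n_centers == 0L) stop("no lipids of center type ", center_type)
  if (length(acc) == 0L) return(data.frame(shell = integer(0), type = character(0),
                                           mean_count = numeric(0)))
  parts <- strsplit(names(acc), " ", fixed = TRUE)
  out <- data.frame(shell = as.integer(vapply(parts, `[`, "", 1L)),
                    type = vapply(parts, `[`, "", 2L),
                    mean_count = unlist(acc, use.names = FALSE) / n_centers,
                    stringsAsFactors = FALSE)
  out[order(out$shell, out$type), , drop = FALSE]
}

#' Deuterium order parameter profile
#'
#' For each named chain carbon, `S_CD = <(3 cos^2 theta - 1)/2>` over
#' lipids, attached hydrogens, and frames, where theta is the angle of
#' the C-H vector to the +z membrane normal.  The magnitude `|S_CD|` is
#' reported, matching the convention of plotted profiles.
#'
#' @param frames list of frames.
#' @param chain_spec list with `carbons` (ordered carbon atom names),
#'   `hydrogens` (list of character vectors of H names per carbon), and
#'   optional `chain` label.
#' @param lipid_sel selection restricting which lipids contribute.
#' @param atoms the [atom_table()].
#' @return data frame (`chain`, `carbon_index`, `carbon`, `scd`), where
#'   `carbon_index` counts 2..n along the chain.
#' @export
scd_profile <- function(frames, chain_spec, lipid_sel, atoms) {
  sel <- parse_selection(lipid_sel, atoms)
  if (length(sel) == 0L) stop("empty lipid selection")
  lipids <- unique(paste(atoms$segid[sel], atoms$resid[sel]))
  lipkey <- paste(atoms$segid, atoms$resid)
  carbons <- chain_spec$carbons
  hyds <- chain_spec$hydrogens
  if (length(hyds) != length(carbons)) stop("chain_spec carbons/hydrogens mismatch")
  label <- chain_spec$chain %||% "sn-1"

  sums <- numeric(length(carbons))
  counts <- integer(length(carbons))
  for (ci in seq_along(carbons)) {
    c_idx <- which(lipkey %in% lipids & atoms$name == carbons[ci])
    h_idx_all <- lapply(chain_spec$hydrogens[[ci]], function(h) {
      which(lipkey %in% lipids & atoms$name == h)
    })
    if (length(c_idx) == 0L) stop("carbon ", carbons[ci], " not found in selection")
    if (all(lengths(h_idx_all) == 0L)) {
      stop("no hydrogens found for carbon ", carbons[ci],
           ": explicit hydrogens are required for S_CD")
    }
    for (fr in frames) {
      for (h_idx in h_idx_all) {
        if (length(h_idx) != length(c_idx)) next
        v <- fr$coords[h_idx, , drop = FALSE] - fr$coords[c_idx, , drop = FALSE]
        cos2 <- v[, 3]^2 / rowSums(v^2)
        sums[ci] <- sums[ci] + sum((3 * cos2 - 1) / 2)
        counts[ci] <- counts[ci] + length(cos2)
      }
    }
  }
  if (any(counts == 0L)) stop("no C-H pairs matched for some carbons")
  data.frame(chain = label, carbon_index = seq_along(carbons) + 1L,
             carbon = carbons, scd = abs(sums / counts),
             stringsAsFactors = FALSE)
}

#' Bilayer thickness time series
#'
#' `D_PP` per frame: mean z of the upper-leaflet phosphate selection minus
#' mean z of the lower-leaflet one, with leaflets split at the midplane of
#' the selection.
#'
#' @param frames list of frames.
#' @param phosphate_sel selection of phosphate (or head) atoms.
#' @param atoms the [atom_table()].
#' @return data frame (`frame`, `time`, `dpp`).
#' @export
membrane_thickness <- function(frames, phosphate_sel, atoms) {
  sel <- parse_selection(phosphate_sel, atoms)
  if (length(sel) == 0L) stop("empty phosphate selection")
  rows <- lapply(frames, function(fr) {
    z <- fr$coords[sel, 3]
    mid <- mean(z)
    up <- z[z >= mid]; lo <- z[z < mid]
    if (length(up) == 0L || length(lo) == 0L) {
      stop("phosphate selection occupies a single leaflet at frame ", fr$index)
    }
    data.frame(frame = fr$index, time = fr$time, dpp = mean(up) - mean(lo))
  })
  do.call(rbind, rows)
}

#' Sterol tilt angle
#'
#' Tilt `Theta = acos(|u . z|)` in `[0, 90]` degrees, with u the unit
#' vector from the tail atom to the head atom of each sterol.  Returns the
#' per-frame mean series plus a pooled histogram.
#'
#' @param frames list of frames.
#' @param vector_spec `c(tail_atom_name, head_atom_name)`.
#' @param sterol_sel selection of sterol residues.
#' @param atoms the [atom_table()].
#' @param bin_width histogram bin width in degrees.
#' @return list with `series` (`frame`, `time`, `mean_tilt`), `histogram`
#'   (`bin_center`, `count`, `density`), and `angles` (pooled, degrees).
#' @export
sterol_tilt <- function(frames, vector_spec, sterol_sel, atoms, bin_width = 2) {
  sel <- parse_selection(sterol_sel, atoms)
  if (length(sel) == 0L) stop("empty sterol selection")
  lipkey <- paste(atoms$segid, atoms$resid)
  sterols <- unique(lipkey[sel])
  tail_idx <- which(lipkey %in% sterols & atoms$name == vector_spec[1])
  head_idx <- which(lipkey %in% sterols & atoms$name == vector_spec[2])
  if (length(tail_idx) == 0L || length(head_idx) == 0L ||
      length(tail_idx) != length(head_idx)) {
    stop("tail/head atoms not found once per sterol")
  }
  pooled <- numeric(0)
  rows <- lapply(frames, function(fr) {
    v <- fr$coords[head_idx, , drop = FALSE] - fr$coords[tail_idx, , drop = FALSE]
    len <- sqrt(rowSums(v^2))
    ok <- len > 1e-9
    if (!all(ok)) warning("zero-length sterol vector skipped")
    theta <- acos(pmin(1, abs(v[ok, 3]) / len[ok])) * 180 / pi
    pooled <<- c(pooled, theta)
    data.frame(frame = fr$index, time = fr$time, mean_tilt = mean(theta))
  })
  breaks <- seq(0, 90 + bin_width, by = bin_width)
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  list(series = do.call(rbind, rows),
       histogram = data.frame(bin_center = h$mids, count = h$counts,
                              density = h$density),
       angles = pooled)
}

#' Area compressibility modulus from lateral-area fluctuations
#'
#' `K_A = kB * T * <A> / var(A)` with A the lateral box area per frame and
#' the population variance; the result is converted from J/Angstrom^2 to
#' mN/m.  A block-average standard error over 5 blocks is attached when
#' the series is long enough.
#'
#' @param area_series numeric vector of lateral areas (Angstrom^2).
#' @param temperature temperature in K.
#' @param n_blocks blocks for the error estimate.
#' @return list with `ka` (mN/m), `mean_area`, `var_area`, and `ka_se`
#'   (NA when fewer than 2 frames per block).
#' @export
area_compressibility <- function(area_series, temperature, n_blocks = 5L) {
  a <- as.numeric(area_series)
  if (length(a) < 2L) stop("need at least 2 frames for K_A")
  v <- mean((a - mean(a))^2)
  if (v <= 0) stop("constant area series: K_A undefined")
  ka_of <- function(x) {
    vv <- mean((x - mean(x))^2)
    .kB * temperature * mean(x) / vv * 1e23  # J/A^2 -> mN/m
  }
  ka <- ka_of(a)
  ka_se <- NA_real_
  if (length(a) >= 2L * n_blocks) {
    blocks <- split(a, cut(seq_along(a), n_blocks, labels = FALSE))
    vals <- vapply(blocks, ka_of, numeric(1))
    ka_se <- stats::sd(vals) / sqrt(n_blocks)
  }
  list(ka = ka, mean_area = mean(a), var_area = v, ka_se = ka_se)
}

#' Density profile along the membrane normal
#'
#' Histograms selected atoms along z (re-centered per frame on the
#' membrane midplane when `center_sel` is given), weighted per mode, and
#' divides by the bin volume `Lx * Ly * bin_width`; frame-averaged.
#'
#' @param frames list of frames.
#' @param group_sels named list of selection expressions.
#' @param atoms the [atom_table()].
#' @param bin_width bin width (Angstrom).
#' @param mode `"number"`, `"mass"`, or `"electron"` (electrons = atomic
#'   number - partial charge; falls back to number mode with a warning
#'   when charges are absent).
#' @param center_sel optional selection whose mean z defines the midplane.
#' @return data frame (`group`, `z`, `density`).
#' @export
z_density_profile <- function(frames, group_sels, atoms, bin_width = 1,
                              mode = c("number", "mass", "electron"),
                              center_sel = NULL) {
  mode <- match.arg(mode)
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (mode == "electron" && all(is.na(atoms$charge))) {
    warning("no partial charges: electron mode falling back to number mode")
    mode <- "number"
  }
  if (is.null(names(group_sels))) names(group_sels) <- group_sels
  idx <- lapply(group_sels, parse_selection, atoms = atoms)
  ctr <- if (!is.null(center_sel)) parse_selection(center_sel, atoms) else NULL

  Lz <- max(vapply(frames, function(fr) fr$box[3], numeric(1)))
  breaks <- seq(-Lz / 2, Lz / 2, by = bin_width)
  if (breaks[length(breaks)] < Lz / 2 - 1e-9) breaks <- c(breaks, Lz / 2)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  acc <- lapply(group_sels, function(...) numeric(length(mids)))

  for (fr in frames) {
    z0 <- if (!is.null(ctr)) mean(fr$coords[ctr, 3]) else 0
    volume <- fr$box[1] * fr$box[2] * bin_width
    for (g in names(group_sels)) {
      gi <- idx[[g]]
      z <- fr$coords[gi, 3] - z0
      ## wrap into [-Lz/2, Lz/2)
      z <- z - fr$box[3] * floor(z / fr$box[3] + 0.5)
      w <- switch(mode,
                  number = rep(1, length(gi)),
                  mass = atoms$mass[gi],
                  electron = element_number(atoms$element[gi]) -
                    ifelse(is.na(atoms$charge[gi]), 0, atoms$charge[gi]))
      bin <- findInterval(z, breaks, rightmost.closed = FALSE)
      ok <- bin >= 1L & bin <= length(mids)
      acc[[g]] <- acc[[g]] +
        as.numeric(tapply(w[ok], factor(bin[ok], levels = seq_along(mids)), sum,
                          default = 0)) / volume
    }
  }
  out <- do.call(rbind, lapply(names(group_sels), function(g) {
    data.frame(group = g, z = mids, density = acc[[g]] / length(frames),
               stringsAsFactors = FALSE)
  }))
  out
}

## unwrap per-particle trajectories by accumulating minimum-image increments
unwrap_positions <- function(pos_list, boxes, dims) {
  n <- length(pos_list)
  out <- pos_list
  for (t in 2:n) {
    step <- minimum_image_displacement(pos_list[[t - 1]], pos_list[[t]],
                                       boxes[[t]])
    out[[t]] <- out[[t - 1]] + step
  }
  out
}

msd_all_origins <- function(traj, dims) {
  ## traj: list over frames of P x d matrices (unwrapped); MSD(tau) is the
  ## mean over particles and all time origins of the squared displacement
  n <- length(traj)
  P <- nrow(traj[[1]])
  arr <- array(unlist(traj), dim = c(P, ncol(traj[[1]]), n))
  arr <- arr[, dims, , drop = FALSE]
  msd <- numeric(n - 1L)
  for (tau in seq_len(n - 1L)) {
    d <- arr[, , (1L + tau):n, drop = FALSE] - arr[, , 1L:(n - tau), drop = FALSE]
    msd[tau] <- sum(d * d) / (P * (n - tau))
  }
  msd
}

#' Lateral (xy) mean-square displacement of lipids
#'
#' Per-lipid COM xy trajectories are unwrapped by accumulating
#' minimum-image increments, then `MSD(tau) = <|r(t+tau) - r(t)|^2>` over
#' all time origins and lipids.
#'
#' @param frames list of frames (>= 2).
#' @param lipid_sel selection; one COM per (segid, resid) lipid.
#' @param atoms the [atom_table()].
#' @param subtract_com subtract the mean lateral drift of the selection
#'   before computing displacements.
#' @return data frame (`tau`, `msd`) in frames / Angstrom^2.
#' @export
lateral_msd <- function(frames, lipid_sel, atoms, subtract_com = FALSE) {
  msd_of_selection(frames, lipid_sel, atoms, dims = 1:2,
                   subtract_com = subtract_com)
}

msd_of_selection <- function(frames, sel_text, atoms, dims,
                             subtract_com = FALSE) {
  if (length(frames) < 2L) stop("need at least 2 frames for MSD")
  sel <- parse_selection(sel_text, atoms)
  if (length(sel) == 0L) stop("empty selection")
  lip <- paste(atoms$segid[sel], atoms$resid[sel])
  fac <- factor(lip, levels = unique(lip))
  m <- atoms$mass[sel]
  msum <- as.numeric(rowsum(m, fac))
  pos <- lapply(frames, function(fr) {
    rowsum(fr$coords[sel, , drop = FALSE] * m, fac) / msum
  })
  boxes <- lapply(frames, function(fr) {
    if (is.null(fr$box)) stop("MSD requires box dimensions for unwrapping")
    fr$box
  })
  un <- unwrap_positions(pos, boxes, dims)
  if (subtract_com) {
    un <- lapply(un, function(p) sweep(p, 2L, colMeans(p)))
  }
  data.frame(tau = seq_len(length(frames) - 1L),
             msd = msd_all_origins(un, dims))
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Least-squares slope of MSD(tau) over `fit_window` (fractions of the
#' maximum lag) divided by 4 (2-D Einstein relation).  The default window
#' keeps early lags only: long lags average few independent time origins
#' and dominate the variance of the fit.
#'
#' @param msd data frame (`tau`, `msd`) from [lateral_msd()].
#' @param fit_window `c(lo, hi)` fractions of the maximum lag.
#' @param time_step ps per frame.
#' @return diffusion coefficient in Angstrom^2/ps.
#' @export
lateral_diffusion <- function(msd, fit_window = c(0, 0.25), time_step = 1) {
  tmax <- max(msd$tau)
  keep <- msd$tau >= fit_window[1] * tmax & msd$tau <= fit_window[2] * tmax
  if (sum(keep) < 3L) stop("fewer than 3 lag points in the fit window")
  fit <- stats::lm(msd ~ tau, data = msd[keep, , drop = FALSE])
  unname(stats::coef(fit)["tau"]) / time_step / 4
}

#' Group center-of-mass position time series
#'
#' @param frames list of frames.
#' @param group_sels named list of selection expressions.
#' @param atoms the [atom_table()].
#' @return data frame (`frame`, `time`, then `<group>_x/_y/_z` triples).
#' @export
position_timeseries <- function(frames, group_sels, atoms) {
  if (is.null(names(group_sels))) names(group_sels) <- paste0("group", seq_along(group_sels))
  idx <- lapply(group_sels, parse_selection, atoms = atoms)
  for (g in names(idx)) if (length(idx[[g]]) == 0L) stop("empty group: ", g)
  rows <- lapply(frames, function(fr) {
    vals <- unlist(lapply(names(idx), function(g) {
      com <- center_of_mass(fr$coords[idx[[g]], , drop = FALSE],
                            atoms$mass[idx[[g]]])
      stats::setNames(com, paste0(g, c("_x", "_y", "_z")))
    }))
    cbind(data.frame(frame = fr$index, time = fr$time), as.data.frame(t(vals)))
  })
  do.call(rbind, rows)
}
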