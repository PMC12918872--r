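## Protein observables: RMSD, RMSF, DSSP secondary structure, pore radius
## profiles, and covariance analysis.

#' RMSD time series
#'
#' @param frames list of frames.
#' @param sel selection expression.
#' @param reference reference frame (a frame object) or 0-based index into
#'   `frames`.
#' @param atoms the [atom_table()].
#' @param fit superpose the selection onto the reference (Kabsch,
#'   mass-weighted) before computing the RMSD; otherwise raw coordinates.
#' @return data frame (`frame`, `time`, `rmsd`).
#' @export
rmsd_series <- function(frames, sel, reference = 0L, atoms, fit = TRUE) {
  idx <- parse_selection(sel, atoms)
  if (length(idx) == 0L) stop("empty selection")
  ref <- if (is.numeric(reference)) frames[[reference + 1L]] else reference
  refc <- ref$coords[idx, , drop = FALSE]
  w <- atoms$mass[idx]
  rows <- lapply(frames, function(fr) {
    mob <- fr$coords[idx, , drop = FALSE]
    if (nrow(mob) != nrow(refc)) stop("selection size mismatch with reference")
    r <- if (fit) {
      kabsch_superpose(mob, refc, w)$rmsd
    } else {
      sqrt(sum(w * rowSums((mob - refc)^2)) / sum(w))
    }
    data.frame(frame = fr$index, time = fr$time, rmsd = r)
  })
  do.call(rbind, rows)
}

#' Per-residue RMSF
#'
#' Two-pass alignment: frames are superposed onto the first frame, the
#' mean structure is computed, frames are re-superposed onto that mean,
#' and `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` per atom.  The residue value is
#' the mass-weighted mean over its selected atoms.
#'
#' @param frames list of frames (>= 2).
#' @param sel selection expression.
#' @param atoms the [atom_table()].
#' @param align superpose frames before measuring fluctuations (disable
#'   when the trajectory is already aligned or global motion is absent).
#' @return data frame (`segid`, `resid`, `rmsf`) with attribute
#'   `per_atom` (numeric vector of per-atom RMSF, Angstrom).
#' @export
rmsf_per_residue <- function(frames, sel, atoms, align = TRUE) {
  if (length(frames) < 2L) stop("need at least 2 frames for RMSF")
  idx <- parse_selection(sel, atoms)
  if (length(idx) == 0L) stop("empty selection")
  w <- atoms$mass[idx]

  if (align) {
    aligned <- superpose_trajectory(frames, idx, w)
    mean1 <- Reduce(`+`, aligned) / length(aligned)
    aligned <- lapply(aligned, function(m) kabsch_superpose(m, mean1, w)$transformed)
  } else {
    aligned <- lapply(frames, function(fr) fr$coords[idx, , drop = FALSE])
  }
  mu <- Reduce(`+`, aligned) / length(aligned)
  msf <- Reduce(`+`, lapply(aligned, function(m) rowSums((m - mu)^2))) /
    length(aligned)
  rmsf_atom <- sqrt(msf)

  key <- paste(atoms$segid[idx], atoms$resid[idx])
  uk <- unique(key)
  out <- do.call(rbind, lapply(uk, function(k) {
    sub <- key == k
    data.frame(segid = atoms$segid[idx][sub][1],
               resid = atoms$resid[idx][sub][1],
               rmsf = sum(w[sub] * rmsf_atom[sub]) / sum(w[sub]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "per_atom") <- rmsf_atom
  out
}

superpose_trajectory <- function(frames, idx, w) {
  ref <- frames[[1]]$coords[idx, , drop = FALSE]
  lapply(frames, function(fr) {
    kabsch_superpose(fr$coords[idx, , drop = FALSE], ref, w)$transformed
  })
}

## ---------------------------------------------------------------------
## DSSP (8-state) from backbone geometry.

## residue-level backbone extraction; amide H reconstructed when absent:
## H = N + 1.01 * unit(C_prev - O_prev)  (anti to the preceding carbonyl)
backbone_atoms <- function(frame, atoms) {
  prot <- which(atoms$resname %in% .standard_amino_acids)
  if (length(prot) == 0L) stop("no protein residues")
  key <- paste(atoms$segid[prot], atoms$resid[prot])
  uk <- unique(key)
  res <- vector("list", length(uk))
  for (r in seq_along(uk)) {
    sub <- prot[key == uk[r]]
    pick <- function(nm) {
      j <- sub[atoms$name[sub] == nm]
      if (length(j) >= 1L) frame$coords[j[1], ] else NULL
    }
    res[[r]] <- list(segid = atoms$segid[sub[1]], resid = atoms$resid[sub[1]],
                     N = pick("N"), CA = pick("CA"), C = pick("C"),
                     O = pick("O"), H = pick("HN") %||% pick("H"))
  }
  ## reconstruct missing amide hydrogens
  for (r in seq_along(res)) {
    if (is.null(res[[r]]$H) && r > 1L &&
        res[[r]]$segid == res[[r - 1L]]$segid &&
        !is.null(res[[r]]$N) && !is.null(res[[r - 1L]]$C) &&
        !is.null(res[[r - 1L]]$O)) {
      v <- res[[r - 1L]]$C - res[[r - 1L]]$O
      res[[r]]$H <- res[[r]]$N + 1.01 * v / sqrt(sum(v^2))
    }
  }
  res
}

## Kabsch-Sander hydrogen-bond energy (kcal/mol) between acceptor residue
## a (C=O) and donor residue d (N-H); Inf when atoms are missing.
ks_energy <- function(res, a, d) {
  A <- res[[a]]; D <- res[[d]]
  if (is.null(A$C) || is.null(A$O) || is.null(D$N) || is.null(D$H)) return(Inf)
  dist <- function(p, q) max(sqrt(sum((p - q)^2)), 1e-3)
  0.084 * 332 * (1 / dist(A$O, D$N) + 1 / dist(A$C, D$H) -
                 1 / dist(A$O, D$H) - 1 / dist(A$C, D$N))
}

#' DSSP secondary-structure assignment for one frame
#'
#' Implements the Kabsch-Sander electrostatic hydrogen-bond criterion
#' (bond iff E < -0.5 kcal/mol) with the standard 8-state pattern rules:
#' n-turns give G/H/I helices (two consecutive turns required), bridge
#' patterns give B (isolated) and E (ladder), remaining turns give T, and
#' high backbone curvature gives S.  Assignment priority H > G > I > E >
#' B > T > S > '-'.  Residues missing backbone atoms are coded '-'.
#'
#' @param frame a frame.
#' @param atoms the [atom_table()].
#' @return a `secondary_structure` list: `codes` (character vector),
#'   `string`, `resid`, `segid`.
#' @export
dssp_assign <- function(frame, atoms) {
  res <- backbone_atoms(frame, atoms)
  n <- length(res)
  complete <- vapply(res, function(r) {
    !is.null(r$N) && !is.null(r$CA) && !is.null(r$C) && !is.null(r$O)
  }, logical(1))
  if (!all(complete)) warning("residue(s) missing backbone atoms coded '-'")

  ## hbond[a, d]: CO of residue a accepts an H-bond from NH of residue d
  hb <- matrix(FALSE, n, n)
  same_seg <- function(i, j) res[[i]]$segid == res[[j]]$segid
  for (a in seq_len(n)) {
    for (d in seq_len(n)) {
      if (abs(a - d) < 2L && same_seg(a, d)) next
      if (ks_energy(res, a, d) < -0.5) hb[a, d] <- TRUE
    }
  }

  turn <- list()  # turn[[k]][i]: H-bond CO(i) -> NH(i+k)
  for (k in 3:5) {
    t <- rep(FALSE, n)
    for (i in seq_len(max(0L, n - k))) {
      if (same_seg(i, i + k) && hb[i, i + k]) t[i] <- TRUE
    }
    turn[[k]] <- t
  }

  codes <- rep("-", n)
  set_if <- function(i, code) {
    pri <- c("H" = 8, "G" = 7, "I" = 6, "E" = 5, "B" = 4, "T" = 3, "S" = 2, "-" = 1)
    for (j in i) {
      if (j >= 1L && j <= n && pri[code] > pri[codes[j]]) codes[j] <<- code
    }
  }

  ## bridges
  bridge <- matrix(FALSE, n, n)
  inner <- if (n >= 3L) 2:(n - 1L) else integer(0)
  for (i in inner) {
    for (j in inner) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i, j + 1L]) || (hb[i - 1L, j] && hb[j + 1L, i])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }

  ## helices first (highest priority): two consecutive n-turns
  for (spec in list(c(4L, "H"), c(3L, "G"), c(5L, "I"))) {
    k <- as.integer(spec[1]); code <- spec[2]
    for (i in seq_len(n)[-1]) {
      if (i <= n - k && turn[[k]][i - 1L] && turn[[k]][i]) {
        set_if(i:(i + k - 1L), code)
      }
    }
  }

  ## ladders: consecutive bridges -> E; isolated bridge -> B
  in_ladder <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!bridge[i, j]) next
      ext <- (i > 1L && j > 1L && bridge[i - 1L, j - 1L]) ||
             (i < n && j < n && bridge[i + 1L, j + 1L]) ||
             (i > 1L && j < n && bridge[i - 1L, j + 1L]) ||
             (i < n && j > 1L && bridge[i + 1L, j - 1L])
      if (ext) in_ladder[i] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    if (in_ladder[i]) set_if(i, "E")
    else if (any(bridge[i, ])) set_if(i, "B")
  }

  ## turns: residues strictly inside any n-turn
  for (k in 3:5) {
    for (i in which(turn[[k]])) set_if((i + 1L):(i + k - 1L), "T")
  }

  ## bends: CA(i-2)->CA(i) vs CA(i)->CA(i+2) angle > 70 degrees
  for (i in if (n >= 5L) 3:(n - 2L) else integer(0)) {
    r0 <- res[[i - 2L]]$CA; r1 <- res[[i]]$CA; r2 <- res[[i + 2L]]$CA
    if (is.null(r0) || is.null(r1) || is.null(r2)) next
    if (!same_seg(i - 2L, i + 2L)) next
    u <- r1 - r0; v <- r2 - r1
    ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                               sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (ang > 70) set_if(i, "S")
  }

  codes[!complete] <- "-"
  structure(list(codes = codes, string = paste(codes, collapse = ""),
                 resid = vapply(res, function(r) r$resid, integer(1)),
                 segid = vapply(res, function(r) r$segid, character(1))),
            class = "secondary_structure")
}

#' Pore radius profile along z
#'
#' Per z-bin, the pore radius is the minimum over selected atoms in the
#' bin of (lateral distance of the atom to the pore axis minus the vdW
#' radius of its element), clamped at 0 and averaged over frames.  The
#' axis defaults to the lateral centroid of the selection per frame.
#'
#' @param frames list of frames.
#' @param sel selection expression.
#' @param atoms the [atom_table()].
#' @param bin_width z bin width (Angstrom).
#' @param axis optional fixed `c(x, y)` axis position.
#' @return data frame (`z`, `radius`); empty bins have `NA` radius.
#' @export
pore_radius_profile <- function(frames, sel, atoms, bin_width = 1, axis = NULL) {
  idx <- parse_selection(sel, atoms)
  if (length(idx) == 0L) stop("empty selection")
  vdw <- element_vdw(atoms$element[idx])
  zall <- unlist(lapply(frames, function(fr) fr$coords[idx, 3]))
  breaks <- seq(floor(min(zall) / bin_width) * bin_width,
                max(zall) + bin_width, by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  sums <- numeric(length(mids)); counts <- integer(length(mids))
  for (fr in frames) {
    xy <- fr$coords[idx, 1:2, drop = FALSE]
    ax <- if (is.null(axis)) colMeans(xy) else axis
    rr <- sqrt((xy[, 1] - ax[1])^2 + (xy[, 2] - ax[2])^2) - vdw
    bin <- findInterval(fr$coords[idx, 3], breaks)
    for (b in unique(bin)) {
      if (b < 1L || b > length(mids)) next
      sums[b] <- sums[b] + max(0, min(rr[bin == b]))
      counts[b] <- counts[b] + 1L
    }
  }
  data.frame(z = mids, radius = ifelse(counts > 0L, sums / pmax(counts, 1L), NA))
}

#' Coordinate covariance analysis
#'
#' `C = <dx dx^T>` over frames with dx the 3N displacement from the mean
#' structure (after optional mass-weighted superposition onto it).
#'
#' @param frames list of frames (>= 2).
#' @param sel selection expression.
#' @param atoms the [atom_table()].
#' @param fit superpose frames before computing displacements.
#' @param eigen also return the eigendecomposition (descending).
#' @return list with `covariance` (3N x 3N, Angstrom^2), `mean_structure`,
#'   `atoms_idx`, and optionally `eigenvalues`/`eigenvectors`.
#' @export
covariance_analysis <- function(frames, sel, atoms, fit = TRUE, eigen = TRUE) {
  if (length(frames) < 2L) stop("need at least 2 frames for covariance")
  idx <- parse_selection(sel, atoms)
  if (length(idx) == 0L) stop("empty selection")
  w <- atoms$mass[idx]
  coords <- if (fit) {
    aligned <- superpose_trajectory(frames, idx, w)
    mean1 <- Reduce(`+`, aligned) / length(aligned)
    lapply(aligned, function(m) kabsch_superpose(m, mean1, w)$transformed)
  } else {
    lapply(frames, function(fr) fr$coords[idx, , drop = FALSE])
  }
  X <- t(vapply(coords, function(m) as.numeric(t(m)), numeric(3L * length(idx))))
  mu <- colMeans(X)
  D <- sweep(X, 2L, mu)
  C <- crossprod(D) / nrow(D)
  C <- (C + t(C)) / 2
  out <- list(covariance = C,
              mean_structure = matrix(mu, ncol = 3L, byrow = TRUE),
              atoms_idx = idx)
  if (eigen) {
    e <- eigen(C, symmetric = TRUE)
    out$eigenvalues <- e$values
    out$eigenvectors <- e$vectors
  }
  out
}
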