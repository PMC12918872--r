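## Shared geometric primitives.

#' Minimum-image displacement
#'
#' Component-wise displacement `b - a` wrapped into `[-L/2, L/2)` for an
#' orthorhombic box.
#'
#' @param a,b 3-vectors (or N x 3 matrices) in Angstrom.
#' @param box box lengths `c(Lx, Ly, Lz)`.
#' @return displacement of the same shape as the inputs.
#' @export
minimum_image_displacement <- function(a, b, box) {
  if (any(box <= 0)) stop("box components must be positive")
  d <- b - a
  if (is.matrix(d)) {
    sweep2 <- sweep(d, 2L, box, "/")
    d - sweep(floor(sweep2 + 0.5), 2L, box, "*")
  } else {
    d - box * floor(d / box + 0.5)
  }
}

#' Mass-weighted center of a coordinate group
#'
#' @param coords k x 3 matrix (Angstrom).
#' @param masses k masses (amu); all positive.
#' @return 3-vector, `sum(m_i x_i) / sum(m_i)`.
#' @export
center_of_mass <- function(coords, masses) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("center_of_mass: empty group")
  if (length(masses) != nrow(coords)) stop("masses/coords length mismatch")
  if (any(masses <= 0)) stop("masses must be positive")
  colSums(coords * masses) / sum(masses)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between `mobile` and `reference`.  The rotation comes from the SVD of
#' the weighted cross-covariance matrix with a determinant sign correction
#' so reflections are never returned.
#'
#' Convention: `transformed = (mobile - com_mobile) %*% rotation + com_ref`.
#'
#' @param mobile,reference k x 3 coordinate matrices.
#' @param weights k positive weights (default: unit weights).
#' @return list with `rotation` (3 x 3, det +1), `translation` (3-vector
#'   such that `transformed = mobile %*% rotation + translation`), `rmsd`
#'   (weighted, Angstrom), and `transformed` coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  k <- nrow(mobile)
  if (k < 1L) stop("kabsch_superpose: empty coordinate set")
  if (nrow(reference) != k) stop("mobile/reference size mismatch")
  if (is.null(weights)) weights <- rep(1, k)
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)

  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  if (k < 3L || sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    warning("degenerate (collinear or tiny) point set; superposition not unique")
  }
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)

  transformed <- sweep(P %*% R, 2L, cr, "+")
  resid <- transformed - reference
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R),
       rmsd = rmsd, transformed = transformed)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Distance, angle, or dihedral from 2-4 points
#'
#' Two points give the Euclidean distance (Angstrom); three give the angle
#' at the middle point in `[0, 180]` degrees; four give the signed torsion
#' in `(-180, 180]` degrees by the atan2 convention on the two plane
#' normals (IUPAC sign: positive clockwise looking from point 2 to 3).
#'
#' @param points 2-4 x 3 matrix.
#' @return scalar measurement.
#' @export
measure_internal <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!n %in% 2:4) stop("measure_internal needs 2, 3 or 4 points")
  if (n == 2L) return(sqrt(sum((points[2, ] - points[1, ])^2)))
  if (n == 3L) {
    u <- points[1, ] - points[2, ]
    v <- points[3, ] - points[2, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu < 1e-12 || nv < 1e-12) stop("coincident points: angle undefined")
    cosang <- sum(u * v) / (nu * nv)
    return(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  b1 <- points[2, ] - points[1, ]
  b2 <- points[3, ] - points[2, ]
  b3 <- points[4, ] - points[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("coincident/collinear points: dihedral undefined")
  }
  ang <- atan2(sum(cross3(n1, n2) * b2 / nb2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## ---------------------------------------------------------------------
## Periodic 2-D Voronoi tessellation by half-plane clipping against the
## 3 x 3 grid of periodic images.  Exact for sites inside the box; each
## central cell is the intersection of the bisector half-planes against
## every other (imaged) site, pruned nearest-first.

clip_halfplane <- function(poly, mid, dir) {
  ## keep {x : (x - mid) . dir >= 0}
  f <- (poly[, 1] - mid[1]) * dir[1] + (poly[, 2] - mid[2]) * dir[2]
  nv <- nrow(poly)
  inside <- f >= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(NA_real_, nv + 4L, 2L)
  k <- 0L
  for (j in seq_len(nv)) {
    jn <- if (j == nv) 1L else j + 1L
    if (inside[j]) {
      k <- k + 1L; out[k, ] <- poly[j, ]
    }
    if (inside[j] != inside[jn]) {
      t <- f[j] / (f[j] - f[jn])
      k <- k + 1L
      out[k, ] <- poly[j, ] + t * (poly[jn, ] - poly[j, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Periodic 2-D Voronoi tessellation
#'
#' Computes the Voronoi cell of each site under periodic boundary
#' conditions by replicating the sites into the 8 surrounding images and
#' clipping each central cell by the perpendicular-bisector half-planes,
#' nearest candidates first.  Cell areas sum to the box area by
#' construction.
#'
#' @param sites M x 2 matrix of xy positions (Angstrom); wrapped into the
#'   box internally.
#' @param box2d lateral box lengths `c(Lx, Ly)`.
#' @return list with `sites` (wrapped), `areas` (M, Angstrom^2), and
#'   `neighbors` (list of M integer vectors of site indices sharing a
#'   Voronoi edge; excludes self-image contacts).
#' @export
periodic_voronoi <- function(sites, box2d) {
  sites <- rbind(sites)
  M <- nrow(sites)
  if (M < 1L) stop("periodic_voronoi: no sites")
  Lx <- box2d[1]; Ly <- box2d[2]
  if (Lx <= 0 || Ly <= 0) stop("box must be positive")
  sites <- cbind(sites[, 1] %% Lx, sites[, 2] %% Ly)

  if (M == 1L) {
    return(list(sites = sites, areas = Lx * Ly, neighbors = list(integer(0))))
  }

  ## jitter exact duplicates
  key <- paste(round(sites[, 1] / 1e-9), round(sites[, 2] / 1e-9))
  dup <- duplicated(key)
  if (any(dup)) {
    warning("duplicate Voronoi sites jittered by 1e-6 Angstrom")
    sites[dup, ] <- sites[dup, , drop = FALSE] +
      matrix(stats::runif(2 * sum(dup), -1e-6, 1e-6), ncol = 2L)
  }

  shifts <- as.matrix(expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1)))
  imgs <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    cbind(sites[, 1] + shifts[s, 1] * Lx, sites[, 2] + shifts[s, 2] * Ly)
  }))
  img_site <- rep(seq_len(M), times = nrow(shifts))
  img_central <- rep(shifts[, 1] == 0 & shifts[, 2] == 0, each = M)

  areas <- numeric(M)
  neighbors <- vector("list", M)
  half <- max(Lx, Ly)

  for (i in seq_len(M)) {
    s <- sites[i, ]
    ## candidates: all images except this exact central point
    self <- which(img_central)[i]
    dx <- imgs[, 1] - s[1]; dy <- imgs[, 2] - s[2]
    d2 <- dx * dx + dy * dy
    ord <- order(d2)
    ord <- ord[ord != self]

    poly <- cbind(c(s[1] - half, s[1] + half, s[1] + half, s[1] - half),
                  c(s[2] - half, s[2] - half, s[2] + half, s[2] + half))
    used <- integer(0)
    for (j in ord) {
      rmax2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
      if (d2[j] > 4 * rmax2) break
      mid <- c((s[1] + imgs[j, 1]) / 2, (s[2] + imgs[j, 2]) / 2)
      dir <- c(s[1] - imgs[j, 1], s[2] - imgs[j, 2])
      newpoly <- clip_halfplane(poly, mid, dir)
      if (nrow(newpoly) < nrow(poly) ||
          !isTRUE(all.equal(newpoly, poly, tolerance = 1e-12))) {
        used <- c(used, j)
      }
      poly <- newpoly
      if (nrow(poly) < 3L) break
    }
    areas[i] <- polygon_area(poly)

    ## neighbors: candidates whose bisector carries a polygon edge of
    ## positive length (two *distinct* vertices equidistant from site and
    ## candidate; excludes degenerate corner contacts)
    nb <- integer(0)
    for (j in used) {
      ds <- sqrt((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
      dj <- sqrt((poly[, 1] - imgs[j, 1])^2 + (poly[, 2] - imgs[j, 2])^2)
      on_bis <- which(abs(ds - dj) < 1e-6)
      if (length(on_bis) >= 2L) {
        v <- poly[on_bis, , drop = FALSE]
        edge_len <- max(dist(v))
        if (edge_len > 1e-5) nb <- c(nb, img_site[j])
      }
    }
    neighbors[[i]] <- sort(unique(nb[nb != i]))
  }

  ## enforce symmetry of the neighbor relation (floating-point edge grazing)
  for (i in seq_len(M)) {
    for (j in neighbors[[i]]) {
      if (!(i %in% neighbors[[j]])) neighbors[[j]] <- sort(c(neighbors[[j]], i))
    }
  }
  list(sites = sites, areas = areas, neighbors = neighbors)
}
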