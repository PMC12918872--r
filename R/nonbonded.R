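## Geometric detectors for hydrogen bonds, salt bridges, pi stacking, and
## water bridges.  All cutoffs are flag-adjustable; the defaults are the
## common geometric criteria (donor-acceptor 3.5 Angstrom / D-H...A 150
## degrees for hydrogen bonds, 4.0 Angstrom N...O for salt bridges, 6.0
## Angstrom centroid distance for pi stacking).

res_key <- function(atoms, idx) {
  paste0(atoms$segid[idx], "/", atoms$resname[idx], atoms$resid[idx])
}

## donors: N/O/S/F heavy atoms carrying at least one hydrogen within the
## covalent-bond heuristic distance (< 1.2 Angstrom), same residue
find_donor_hydrogens <- function(frame, atoms, donor_idx, max_dh = 1.2) {
  h_all <- which(atoms$element == "H")
  out <- list()
  for (d in donor_idx) {
    if (!atoms$element[d] %in% c("N", "O", "S", "F")) next
    hs <- h_all[atoms$segid[h_all] == atoms$segid[d] &
                atoms$resid[h_all] == atoms$resid[d]]
    if (length(hs) == 0L) next
    dv <- frame$coords[hs, , drop = FALSE] -
      matrix(frame$coords[d, ], length(hs), 3L, byrow = TRUE)
    hs <- hs[sqrt(rowSums(dv^2)) < max_dh]
    if (length(hs) > 0L) out[[as.character(d)]] <- hs
  }
  out
}

#' Hydrogen-bond detection
#'
#' A hydrogen bond is recorded iff the donor-acceptor heavy-atom distance
#' is at most `d_cut` and the D-H...A angle is at least `angle_cut`.
#' Donors are N/O/S/F atoms of `donor_sel` with a covalently bound
#' hydrogen (name-independent distance heuristic); acceptors are N/O/S/F
#' atoms of `acceptor_sel`.  Records are sorted by frame index.
#'
#' @param frames list of frames.
#' @param donor_sel,acceptor_sel selection expressions.
#' @param atoms the [atom_table()].
#' @param d_cut donor-acceptor distance cutoff (Angstrom).
#' @param angle_cut D-H...A angle cutoff (degrees).
#' @return data frame (`frame`, `donor`, `hydrogen`, `acceptor`,
#'   `donor_res`, `acceptor_res`, `distance`, `angle`).
#' @export
hydrogen_bonds <- function(frames, donor_sel, acceptor_sel, atoms,
                           d_cut = 3.5, angle_cut = 150) {
  di <- parse_selection(donor_sel, atoms)
  ai <- parse_selection(acceptor_sel, atoms)
  ai <- ai[atoms$element[ai] %in% c("N", "O", "S", "F")]
  if (length(ai) == 0L) stop("no N/O/S/F acceptors in selection")
  rows <- list()
  for (fr in frames) {
    dh <- find_donor_hydrogens(fr, atoms, di)
    if (length(dh) == 0L) stop("no identifiable hydrogens on donor atoms")
    for (dch in names(dh)) {
      d <- as.integer(dch)
      acc <- ai[ai != d]
      if (length(acc) == 0L) next
      dv <- fr$coords[acc, , drop = FALSE] -
        matrix(fr$coords[d, ], length(acc), 3L, byrow = TRUE)
      dist_da <- sqrt(rowSums(dv^2))
      cand <- acc[dist_da <= d_cut & dist_da > 1e-6]
      for (a in cand) {
        for (h in dh[[dch]]) {
          if (h == a) next
          ang <- measure_internal(rbind(fr$coords[d, ], fr$coords[h, ],
                                        fr$coords[a, ]))
          if (ang >= angle_cut) {
            rows[[length(rows) + 1L]] <- data.frame(
              frame = fr$index,
              donor = atoms$name[d], hydrogen = atoms$name[h],
              acceptor = atoms$name[a],
              donor_res = res_key(atoms, d), acceptor_res = res_key(atoms, a),
              distance = sqrt(sum((fr$coords[a, ] - fr$coords[d, ])^2)),
              angle = ang, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(0), donor = character(0),
                      hydrogen = character(0), acceptor = character(0),
                      donor_res = character(0), acceptor_res = character(0),
                      distance = numeric(0), angle = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$frame, out$donor_res, out$acceptor_res), , drop = FALSE]
}

.basic_atoms <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                     HIS = c("ND1", "NE2"), HSD = c("ND1", "NE2"),
                     HSE = c("ND1", "NE2"), HSP = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Salt-bridge detection
#'
#' A salt bridge is recorded between two residues in a frame iff the
#' minimum distance between a basic nitrogen (Arg NH1/NH2/NE, Lys NZ, His
#' ND1/NE2, and the N-terminal amine) and an acidic oxygen (Asp OD1/OD2,
#' Glu OE1/OE2, and the C-terminal carboxylate O/OXT) is at most `d_cut`.
#' Pairs are sorted by interaction frequency (descending).
#'
#' @param frames list of frames.
#' @param atoms the [atom_table()].
#' @param d_cut N...O distance cutoff (Angstrom).
#' @param sel optional selection restricting the atoms considered.
#' @return data frame (`resA` basic, `resB` acidic, `frequency`, `frames`
#'   comma-joined 0-based frame indices).
#' @export
salt_bridges <- function(frames, atoms, d_cut = 4.0, sel = "protein") {
  prot <- parse_selection(sel, atoms)
  if (length(prot) == 0L) stop("no protein atoms selected")
  segres <- paste(atoms$segid, atoms$resid)

  basic <- prot[vapply(prot, function(i) {
    atoms$name[i] %in% (.basic_atoms[[atoms$resname[i]]] %||% character(0))
  }, logical(1))]
  acidic <- prot[vapply(prot, function(i) {
    atoms$name[i] %in% (.acidic_atoms[[atoms$resname[i]]] %||% character(0))
  }, logical(1))]
  ## termini per segment: first residue backbone N, last residue O/OXT
  for (sg in unique(atoms$segid[prot])) {
    sp <- prot[atoms$segid[prot] == sg &
               atoms$resname[prot] %in% .standard_amino_acids]
    if (length(sp) == 0L) next
    first_res <- min(atoms$resid[sp]); last_res <- max(atoms$resid[sp])
    basic <- union(basic, sp[atoms$resid[sp] == first_res & atoms$name[sp] == "N"])
    acidic <- union(acidic, sp[atoms$resid[sp] == last_res &
                               atoms$name[sp] %in% c("O", "OXT")])
  }
  if (length(basic) == 0L || length(acidic) == 0L) {
    return(data.frame(resA = character(0), resB = character(0),
                      frequency = numeric(0), frames = character(0)))
  }
  pair_frames <- list()
  for (fr in frames) {
    cb <- fr$coords[basic, , drop = FALSE]
    ca <- fr$coords[acidic, , drop = FALSE]
    d2 <- outer(rowSums(cb^2), rowSums(ca^2), "+") - 2 * cb %*% t(ca)
    hit <- which(d2 <= d_cut^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    keys <- unique(paste(res_key(atoms, basic[hit[, 1]]),
                         res_key(atoms, acidic[hit[, 2]]), sep = "|"))
    keys <- keys[vapply(strsplit(keys, "|", fixed = TRUE),
                        function(p) p[1] != p[2], logical(1))]
    for (k in keys) pair_frames[[k]] <- c(pair_frames[[k]], fr$index)
  }
  freq_sorted_pairs(pair_frames, length(frames))
}

freq_sorted_pairs <- function(pair_frames, nfr, extra = NULL) {
  if (length(pair_frames) == 0L) {
    out <- data.frame(resA = character(0), resB = character(0),
                      frequency = numeric(0), frames = character(0))
    if (!is.null(extra)) out[[extra$name]] <- character(0)
    return(out)
  }
  parts <- strsplit(names(pair_frames), "|", fixed = TRUE)
  out <- data.frame(resA = vapply(parts, `[`, "", 1L),
                    resB = vapply(parts, `[`, "", 2L),
                    frequency = lengths(pair_frames) / nfr,
                    frames = vapply(pair_frames, function(f) {
                      paste(sort(f), collapse = ",")
                    }, character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(extra)) out[[extra$name]] <- extra$value[names(pair_frames)]
  out <- out[order(-out$frequency, out$resA, out$resB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.ring_atoms <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  HSD = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  HSE = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2"))
)

ring_centroid_normal <- function(coords) {
  ctr <- colMeans(coords)
  cen <- sweep(coords, 2L, ctr)
  ## plane normal: singular vector of the smallest singular value
  sv <- svd(cen)
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Pi-stacking detection
#'
#' Aromatic rings (Phe/Tyr/His six- or five-membered; Trp contributes its
#' five- and six-membered rings separately) interact in a frame iff their
#' centroid distance is at most `centroid_cut`.  The interaction class
#' follows the acute interplanar angle `alpha` between SVD-fitted ring
#' normals: parallel (`alpha <= 30` degrees), t-shaped (`alpha >= 60`),
#' otherwise oblique.  Pairs are sorted by frequency.
#'
#' @param frames list of frames.
#' @param atoms the [atom_table()].
#' @param centroid_cut centroid distance cutoff (Angstrom).
#' @param sel optional selection restricting residues.
#' @return data frame (`resA`, `resB`, `frequency`, `frames`, `class`),
#'   ring labels appended to Trp residue keys.
#' @export
pi_stacking <- function(frames, atoms, centroid_cut = 6.0, sel = "protein") {
  prot <- parse_selection(sel, atoms)
  segres <- paste(atoms$segid, atoms$resid)
  aro <- unique(segres[prot][atoms$resname[prot] %in% names(.ring_atoms)])
  rings <- list()
  for (sr in aro) {
    idx <- which(segres == sr)
    rn <- atoms$resname[idx[1]]
    for (ring_name in names(.ring_atoms[[rn]])) {
      nm <- .ring_atoms[[rn]][[ring_name]]
      ridx <- idx[match(nm, atoms$name[idx])]
      if (anyNA(ridx)) {
        warning("incomplete aromatic ring skipped: ", sr)
        next
      }
      label <- res_key(atoms, idx[1])
      if (length(.ring_atoms[[rn]]) > 1L) label <- paste0(label, ":", ring_name)
      rings[[label]] <- ridx
    }
  }
  if (length(rings) < 2L) {
    return(freq_sorted_pairs(list(), length(frames),
                             extra = list(name = "class", value = character(0))))
  }
  pair_frames <- list(); pair_class <- character(0)
  labels <- names(rings)
  for (fr in frames) {
    geom <- lapply(rings, function(ridx) {
      ring_centroid_normal(fr$coords[ridx, , drop = FALSE])
    })
    for (i in seq_along(rings)) {
      for (j in seq_along(rings)) {
        if (j <= i) next
        ## skip ring pairs of the same residue
        if (sub(":ring[56]?$", "", labels[i]) == sub(":ring[56]?$", "", labels[j])) next
        dv <- geom[[j]]$centroid - geom[[i]]$centroid
        if (sqrt(sum(dv^2)) > centroid_cut) next
        cosa <- abs(sum(geom[[i]]$normal * geom[[j]]$normal))
        alpha <- acos(pmin(1, cosa)) * 180 / pi
        cls <- if (alpha <= 30) "pi_parallel"
               else if (alpha >= 60) "pi_tshaped" else "pi_oblique"
        key <- paste(labels[i], labels[j], sep = "|")
        pair_frames[[key]] <- c(pair_frames[[key]], fr$index)
        pair_class[key] <- cls
      }
    }
  }
  freq_sorted_pairs(pair_frames, length(frames),
                    extra = list(name = "class", value = pair_class))
}

#' Water-bridge detection
#'
#' Records (groupA residue, water, groupB residue, frame) whenever a
#' single water molecule simultaneously hydrogen-bonds (either direction,
#' same criteria as [hydrogen_bonds()]) to an atom of `selA` and an atom
#' of `selB` in a frame.  Chains through two or more waters do not count.
#'
#' @param frames list of frames.
#' @param selA,selB selection expressions (should exclude water).
#' @param atoms the [atom_table()].
#' @param d_cut,angle_cut hydrogen-bond criteria.
#' @return data frame (`frame`, `resA`, `water`, `resB`), sorted by frame.
#' @export
water_bridges <- function(frames, selA, selB, atoms, d_cut = 3.5,
                          angle_cut = 150) {
  wat <- parse_selection("water", atoms)
  if (length(wat) == 0L) stop("no water in system")
  hb_try <- function(dsel, asel, fr) {
    tryCatch(hydrogen_bonds(list(fr), dsel, asel, atoms, d_cut, angle_cut),
             error = function(e) NULL)
  }
  hb_to <- function(side_sel, fr) {
    ## residues of side_sel H-bonded to each water residue, either direction
    h1 <- hb_try(side_sel, "water", fr)
    h2 <- hb_try("water", side_sel, fr)
    rbind(if (!is.null(h1)) data.frame(res = h1$donor_res, water = h1$acceptor_res)
          else data.frame(res = character(0), water = character(0)),
          if (!is.null(h2)) data.frame(res = h2$acceptor_res, water = h2$donor_res)
          else data.frame(res = character(0), water = character(0)))
  }
  rows <- list()
  for (fr in frames) {
    a <- unique(hb_to(selA, fr))
    b <- unique(hb_to(selB, fr))
    if (nrow(a) == 0L || nrow(b) == 0L) next
    m <- merge(a, b, by = "water", suffixes = c("A", "B"))
    m <- m[m$resA != m$resB, , drop = FALSE]
    if (nrow(m) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      frame = fr$index, resA = m$resA, water = m$water, resB = m$resB,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(0), resA = character(0),
                      water = character(0), resB = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$frame, out$resA, out$resB), , drop = FALSE]
  rownames(out) <- NULL
  out
}
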