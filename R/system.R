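## Box-dimension series, 3-D solution diffusion, replicate confidence
## intervals.

#' Box-dimension time series
#'
#' @param frames list of frames with box records.
#' @return data frame (`frame`, `time`, `lx`, `ly`, `lz`, `volume`).
#' @export
system_size <- function(frames) {
  rows <- lapply(frames, function(fr) {
    if (is.null(fr$box)) stop("missing box record at frame ", fr$index)
    data.frame(frame = fr$index, time = fr$time, lx = fr$box[1],
               ly = fr$box[2], lz = fr$box[3],
               volume = prod(fr$box))
  })
  do.call(rbind, rows)
}

#' Solution (3-D) mean-square displacement and diffusion coefficient
#'
#' MSD over all time origins and particles after 3-D unwrapping; the
#' diffusion coefficient is the least-squares slope of MSD(tau) over the
#' middle `fit_window` of lags divided by 6 (Einstein relation).
#'
#' @param frames list of frames.
#' @param sel selection; one COM trajectory per (segid, resid) group.
#' @param atoms the [atom_table()].
#' @param fit_window `c(lo, hi)` fractions of the maximum lag used in the
#'   linear fit (default `c(0.2, 0.8)`).
#' @param time_step ps per frame (default 1) for unit conversion.
#' @return list with `msd` (data frame `tau`, `msd`), `D` (Angstrom^2/ps),
#'   and `D_cm2_s` (cm^2/s; 1 Angstrom^2/ps = 1e-4 cm^2/s).
#' @export
solution_msd <- function(frames, sel, atoms, fit_window = c(0.2, 0.8),
                         time_step = 1) {
  msd <- msd_of_selection(frames, sel, atoms, dims = 1:3)
  tmax <- max(msd$tau)
  keep <- msd$tau >= fit_window[1] * tmax & msd$tau <= fit_window[2] * tmax
  if (sum(keep) < 3L) stop("fewer than 3 lag points in the fit window")
  fit <- stats::lm(msd ~ tau, data = msd[keep, , drop = FALSE])
  slope <- unname(stats::coef(fit)["tau"]) / time_step  # A^2 per ps
  D <- slope / 6
  list(msd = msd, D = D, D_cm2_s = D * 1e-4)
}

#' Replicate mean with Student-t confidence interval
#'
#' Halfwidth `t_{(1+level)/2, k-1} * SE` with `SE = sd(values)/sqrt(k)`;
#' at `level = 0.90` and `k = 3` the multiplier is 2.92.
#'
#' @param values k replicate values (k >= 2).
#' @param level two-sided confidence level.
#' @return list with `mean`, `halfwidth`, `multiplier`, `se`.
#' @export
replicate_confidence_interval <- function(values, level = 0.90) {
  k <- length(values)
  if (k < 2L) stop("need at least 2 replicates")
  mult <- stats::qt((1 + level) / 2, df = k - 1L)
  se <- stats::sd(values) / sqrt(k)
  list(mean = mean(values), halfwidth = mult * se, multiplier = mult, se = se)
}
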