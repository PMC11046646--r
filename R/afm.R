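#' AFM retraction force-distance curve
#'
#' Distance is tip-surface separation in nm, increasing during retraction;
#' force is in pN with tension positive (loaders accept either sign via
#' `flip_force`).
#'
#' @param distance numeric vector (nm), strictly increasing.
#' @param force numeric vector (pN), same length, length >= 50.
#' @param retract_speed retraction speed (um/s), provenance.
#' @param label curve identifier.
#' @param flip_force negate the force column (for tension-negative inputs).
#' @return An object of class `FDCurve`.
#' @export
fd_curve <- function(distance, force, retract_speed = NA_real_, label = "",
                     flip_force = FALSE) {
  stopifnot(length(distance) == length(force), length(distance) >= 50)
  if (any(diff(distance) <= 0)) stop("distance must be strictly increasing")
  if (flip_force) force <- -force
  structure(list(distance = as.numeric(distance), force = as.numeric(force),
                 retract_speed = retract_speed, label = label,
                 baseline_corrected = FALSE, flag = NULL),
            class = "FDCurve")
}

# Theil-Sen style slope over the baseline region: median of pairwise slopes
# on a decimated subsample (robust to residual event samples)
robust_line <- function(x, y) {
  n <- length(x)
  idx <- if (n > 60) round(seq(1, n, length.out = 60)) else seq_len(n)
  xs <- x[idx]; ys <- y[idx]
  pr <- utils::combn(length(xs), 2)
  sl <- (ys[pr[2, ]] - ys[pr[1, ]]) / (xs[pr[2, ]] - xs[pr[1, ]])
  b <- median(sl, na.rm = TRUE)
  a <- median(ys - b * xs)
  c(intercept = a, slope = b)
}

#' Baseline-correct a force-distance curve
#'
#' Two-pass correction. Pass 1: the baseline level is the median of the final
#' 10% of samples (the post-rupture tail) and a robust line over that region
#' removes gross offset and drift. Pass 2: the last above-threshold event is
#' located on the coarsely corrected curve and the drift line is refitted
#' over the entire post-rupture tail (every sample more than 10 nm past the
#' rupture edge), which pins the extrapolated baseline at the front of the
#' curve far more precisely than the final 10% alone. Without any event the
#' refit uses the whole curve.
#'
#' @param curve an `FDCurve`.
#' @return The corrected `FDCurve` (`baseline_corrected = TRUE`). An
#'   all-constant curve is returned unchanged with flag `"constant"`.
#' @export
baseline_correct <- function(curve) {
  stopifnot(inherits(curve, "FDCurve"))
  f <- curve$force; d <- curve$distance
  if (diff(range(f)) == 0) {
    curve$flag <- "constant"
    curve$baseline_corrected <- TRUE
    return(curve)
  }
  n <- length(f)
  tail_idx <- seq.int(floor(n * 0.9) + 1, n)
  fit <- robust_line(d[tail_idx], f[tail_idx])
  f1 <- f - (fit["intercept"] + fit["slope"] * d)
  win <- last_event_window(smooth_force(f1), 40)
  base_idx <- if (is.null(win)) seq_len(n) else which(d > d[win[2]] + 10)
  if (length(base_idx) >= 20) {
    # the baseline region is event-free after pass 1, so a plain least-squares
    # line is both precise and safe here
    fit2 <- coef(lm(f1[base_idx] ~ d[base_idx]))
    f1 <- f1 - (fit2[1] + fit2[2] * d)
  }
  curve$force <- unname(f1)
  curve$baseline_corrected <- TRUE
  curve
}

fd_signature <- function(kind, k_pilus = NA_real_, f_adh = NA_real_,
                         plateau_force = NA_real_, plateau_len = NA_real_,
                         rupture_distance = NA_real_, fit_r2 = NA_real_) {
  structure(list(kind = kind, k_pilus = k_pilus, f_adh = f_adh,
                 plateau_force = plateau_force, plateau_len = plateau_len,
                 rupture_distance = rupture_distance, fit_r2 = fit_r2),
            class = "FDSignature")
}

#' @export
print.FDSignature <- function(x, ...) {
  cat(sprintf("FDSignature: %s (k = %.2f pN/nm, F_adh = %.1f pN, plateau = %.1f pN)\n",
              x$kind, x$k_pilus, x$f_adh, x$plateau_force))
  invisible(x)
}

# running-median smoothed force for event detection; fits always use the raw
# trace. Window 7 suppresses single-sample noise excursions across the
# threshold without displacing the rupture edge by more than ~3 samples.
smooth_force <- function(force) {
  if (length(force) < 9) return(force)
  as.numeric(stats::runmed(force, 7))
}

# push the event end forward onto the raw force: the running median retreats
# from an instantaneous rupture by ~half its window, which would bias the
# rupture distance and the extrapolated rupture force low
refine_event_end <- function(force_raw, i2, min_force, slack = 5) {
  upto <- min(length(force_raw), i2 + slack)
  cand <- which(force_raw[i2:upto] >= min_force)
  if (length(cand) == 0) return(i2)
  i2 + cand[length(cand)] - 1
}

# last TRUE run of flat_ok whose end lies within `slack` samples of the event
# end (the smoothed rupture edge blurs over ~3 samples); indices are shifted
# so they address the full curve starting at event index i1
edge_flat_run <- function(flat_ok, i1, slack = 5) {
  rr <- rle(flat_ok)
  re <- cumsum(rr$lengths)
  rs <- re - rr$lengths + 1
  ok <- which(rr$values & re >= length(flat_ok) - slack)
  if (length(ok) == 0) return(NULL)
  j <- ok[length(ok)]
  c(i1 - 1 + rs[j], i1 - 1 + re[j])
}

# locate the last contiguous above-threshold event (>= min_len samples, on
# the smoothed force) before the final return to baseline; returns
# c(start, end) indices plus the total number of qualifying events, or NULL
last_event_window <- function(force_smooth, min_force, min_len = 5) {
  above <- force_smooth >= min_force
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_len)
  if (length(runs) == 0) return(NULL)
  j <- runs[length(runs)]
  c(starts[j], ends[j], length(runs))
}

#' Classify the signature of a force-distance curve
#'
#' Scores the last contiguous above-threshold event before the final return
#' to baseline (single-pilus assumption; earlier events set a `multi_event`
#' attribute but are not decomposed). The event is a `plateau` when force
#' stays within a near-flat band (windowed slope at most `plateau_slope_max`)
#' over at least `min_plateau_len` nm at force >= `min_force`; a `nanospring`
#' when the rising segment fits a line with r^2 >= `spring_min_r2` and slope
#' >= `spring_min_slope` and ends in a sharp rupture (> 50% force drop within
#' 10 nm); `both` when a qualifying extended rise feeds a qualifying plateau;
#' otherwise `none`.
#'
#' @param curve a baseline-corrected `FDCurve`.
#' @param min_force event threshold (pN, default 40).
#' @param min_plateau_len minimal flat length (nm, default 50).
#' @param plateau_slope_max maximal plateau slope (pN/nm, default 0.2).
#' @param spring_min_slope minimal nanospring slope (pN/nm, default 0.5).
#' @param spring_min_r2 minimal linear-fit r^2 (default 0.9).
#' @return An `FDSignature`.
#' @export
classify_signature <- function(curve, min_force = 40, min_plateau_len = 50,
                               plateau_slope_max = 0.2,
                               spring_min_slope = 0.5, spring_min_r2 = 0.9) {
  stopifnot(inherits(curve, "FDCurve"))
  if (!curve$baseline_corrected) curve <- baseline_correct(curve)
  f <- curve$force; d <- curve$distance
  fs <- smooth_force(f)
  win <- last_event_window(fs, min_force)
  if (is.null(win)) return(fd_signature("none"))
  i1 <- win[1]; i2 <- refine_event_end(f, win[2], min_force)
  # extend the window back to the event toe (last low-force sample before rise)
  toe <- i1
  while (toe > 1 && fs[toe - 1] > 5) toe <- toe - 1
  rupture_distance <- d[i2]
  edge_force <- fs[i2]
  # rupture sharpness: force must fall by >50% of the edge force within 10 nm
  after <- which(d > d[i2] & d <= d[i2] + 10)
  sharp <- if (length(after) == 0) TRUE else min(fs[after]) < 0.5 * edge_force
  # flat top: contiguous run ending at the rupture edge with smoothed force
  # >= 85% of the event peak; slope measured by one line fit over that run
  peak <- max(fs[i1:i2])
  flat_ok <- fs[i1:i2] >= 0.85 * peak & fs[i1:i2] >= min_force
  flat_run <- edge_flat_run(flat_ok, i1)
  plateau_q <- FALSE
  plateau_len <- NA_real_
  if (!is.null(flat_run)) {
    plateau_len <- d[flat_run[2]] - d[flat_run[1]]
    if (plateau_len >= min_plateau_len) {
      seg <- flat_run[1]:flat_run[2]
      sl <- coef(lm(f[seg] ~ d[seg]))[2]
      plateau_q <- abs(sl) <= plateau_slope_max
    }
  }
  if (plateau_q) {
    plateau_force <- median(f[flat_run[1]:flat_run[2]])
    # an extended, shallower rise feeding the plateau upgrades it to "both"
    rise_idx <- toe:flat_run[1]
    if (length(rise_idx) >= 10 && d[flat_run[1]] - d[toe] >= 15) {
      fit <- lm(f[rise_idx] ~ d[rise_idx])
      k <- unname(coef(fit)[2])
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (is.finite(k) && k >= spring_min_slope && r2 >= spring_min_r2 && sharp) {
        return(fd_signature("both", k_pilus = k, f_adh = plateau_force,
                            plateau_force = plateau_force,
                            plateau_len = plateau_len,
                            rupture_distance = rupture_distance, fit_r2 = r2))
      }
    }
    if (sharp) {
      return(fd_signature("plateau", f_adh = plateau_force,
                          plateau_force = plateau_force,
                          plateau_len = plateau_len,
                          rupture_distance = rupture_distance))
    }
  }
  if (sharp) {
    # spring: linearity judged on the smoothed rise (15-97% of peak, so short
    # rises keep enough samples); slope and rupture force from the raw data
    ipk <- which.max(fs[i1:i2]) + i1 - 1
    seg <- which(fs[toe:ipk] >= 0.15 * peak & fs[toe:ipk] <= 0.97 * peak) + toe - 1
    if (length(seg) >= 8) {
      r22 <- suppressWarnings(summary(lm(fs[seg] ~ d[seg]))$r.squared)
      fit <- lm(f[seg] ~ d[seg])
      k2 <- unname(coef(fit)[2])
      if (is.finite(k2) && k2 >= spring_min_slope && r22 >= spring_min_r2) {
        cf <- coef(fit)
        f_adh <- unname(cf[1] + cf[2] * d[i2])
        return(fd_signature("nanospring", k_pilus = k2, f_adh = f_adh,
                            rupture_distance = rupture_distance, fit_r2 = r22))
      }
    }
  }
  fd_signature("none", rupture_distance = rupture_distance)
}

#' Fit the nanospring spring constant
#'
#' Least-squares slope of the rising segment between 20% and 95% of the peak
#' force (avoiding the nonlinear toe and the rupture edge); the adhesion /
#' rupture force is the baseline-referenced force immediately before rupture
#' (median of the last 5 samples, to suppress noise bias).
#'
#' @param curve a baseline-corrected `FDCurve` classified as nanospring.
#' @param min_force event threshold used to locate the event (pN).
#' @return list with `k_pilus` (pN/nm), `f_adh` (pN), `r2`,
#'   `rupture_distance` (nm).
#' @export
fit_nanospring <- function(curve, min_force = 40) {
  if (!curve$baseline_corrected) curve <- baseline_correct(curve)
  f <- curve$force; d <- curve$distance
  fs <- smooth_force(f)
  win <- last_event_window(fs, min_force)
  if (is.null(win)) stop("no above-threshold event in curve")
  i1 <- win[1]; i2 <- refine_event_end(f, win[2], min_force)
  toe <- i1
  while (toe > 1 && fs[toe - 1] > 5) toe <- toe - 1
  peak <- max(fs[i1:i2])
  ipk <- which.max(fs[i1:i2]) + i1 - 1
  seg <- which(fs[toe:ipk] >= 0.2 * peak & fs[toe:ipk] <= 0.95 * peak) + toe - 1
  if (length(seg) < 10) stop("rising segment has fewer than 10 samples")
  fit <- lm(f[seg] ~ d[seg])
  cf <- coef(fit)
  list(k_pilus = unname(cf[2]),
       f_adh = unname(cf[1] + cf[2] * d[i2]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       rupture_distance = d[i2])
}

#' Measure a constant-force plateau
#'
#' The plateau force is the median force over the flat window (force within
#' 85% of the event peak, ending at the rupture edge); the rupture force is
#' the force at the rupture edge.
#'
#' @param curve a baseline-corrected `FDCurve` classified as plateau.
#' @param min_force event threshold (pN).
#' @param min_plateau_len minimal accepted plateau length (nm).
#' @return list with `plateau_force` (pN), `plateau_len` (nm), `f_adh` (pN).
#' @export
measure_plateau <- function(curve, min_force = 40, min_plateau_len = 50) {
  if (!curve$baseline_corrected) curve <- baseline_correct(curve)
  f <- curve$force; d <- curve$distance
  fs <- smooth_force(f)
  win <- last_event_window(fs, min_force)
  if (is.null(win)) stop("no above-threshold event in curve")
  i1 <- win[1]; i2 <- win[2]
  peak <- max(fs[i1:i2])
  flat_ok <- fs[i1:i2] >= 0.85 * peak & fs[i1:i2] >= min_force
  run <- edge_flat_run(flat_ok, i1)
  if (is.null(run)) stop("no flat window at the rupture edge")
  flat <- run[1]:run[2]
  plateau_len <- d[flat[length(flat)]] - d[flat[1]]
  if (plateau_len < min_plateau_len) {
    stop(sprintf("plateau window %.1f nm is shorter than min_plateau_len %.1f nm",
                 plateau_len, min_plateau_len))
  }
  list(plateau_force = median(f[flat]), plateau_len = plateau_len,
       f_adh = fs[i2])
}

#' Read a two-column force-distance TSV
#' @param path TSV with header `distance_nm`, `force_pN`.
#' @param ... passed to [fd_curve()].
#' @return An `FDCurve`.
#' @export
read_fd_tsv <- function(path, ...) {
  df <- read.delim(path)
  fd_curve(df[[1]], df[[2]], label = basename(path), ...)
}

#' Write a force-distance curve as TSV
#' @param curve an `FDCurve`.
#' @param path output path.
#' @export
write_fd_tsv <- function(curve, path) {
  write.table(data.frame(distance_nm = curve$distance, force_pN = curve$force),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
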