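#' 2D filament trace
#'
#' An ordered contour of a single filament digitized from a 2D image, in
#' nanometres.
#'
#' @param x,y numeric coordinate vectors (nm), at least 3 points, consecutive
#'   points distinct.
#' @param pixel_size nm per pixel (provenance only).
#' @param label trace identifier.
#' @return An object of class `Trace2D`.
#' @export
trace2d <- function(x, y, pixel_size = NA_real_, label = "") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite coordinates")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) stop("consecutive trace points must be distinct")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 pixel_size = pixel_size, label = label),
            class = "Trace2D")
}

#' Contour length of a trace
#' @param trace a `Trace2D`.
#' @return contour length in nm.
#' @export
contour_length <- function(trace) {
  sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2))
}

#' Re-parameterize a trace at uniform arc-length spacing
#'
#' Linear interpolation onto the arc-length grid `0, ds, 2 ds, ...`; the far
#' endpoint is appended if the contour length is not an exact multiple of
#' `ds`, so endpoints are always preserved. Idempotent on already-uniform
#' traces.
#'
#' @param raw a `Trace2D`.
#' @param ds target spacing (nm), `0 < ds <= contour/2`.
#' @return A uniformly spaced `Trace2D`.
#' @export
discretize_trace <- function(raw, ds) {
  L <- contour_length(raw)
  if (!(ds > 0 && ds <= L / 2)) stop("need 0 < ds <= contour/2 (contour ", L, " nm)")
  s_raw <- c(0, cumsum(sqrt(diff(raw$x)^2 + diff(raw$y)^2)))
  s_new <- seq(0, L, by = ds)
  if (L - s_new[length(s_new)] > 1e-9 * max(1, L)) s_new <- c(s_new, L)
  x <- approx(s_raw, raw$x, xout = s_new)$y
  y <- approx(s_raw, raw$y, xout = s_new)$y
  trace2d(x, y, pixel_size = raw$pixel_size, label = raw$label)
}

# tangent angles along a uniformly discretized trace
trace_angles <- function(trace) {
  atan2(diff(trace$y), diff(trace$x))
}

# pooled tangent correlation <cos theta(s)> over all pairs at each lag.
# Returns data frame lag, s_nm, corr, n_pairs.
pooled_tancorr <- function(traces, ds, max_lag) {
  sums <- numeric(max_lag)
  counts <- numeric(max_lag)
  for (tr in traces) {
    th <- trace_angles(tr)
    n <- length(th)
    for (m in seq_len(min(max_lag, n - 1))) {
      d <- th[(1 + m):n] - th[1:(n - m)]
      sums[m] <- sums[m] + sum(cos(d))
      counts[m] <- counts[m] + (n - m)
    }
  }
  keep <- counts > 0
  data.frame(lag = which(keep), s_nm = which(keep) * ds,
             corr = sums[keep] / counts[keep], n_pairs = counts[keep])
}

# pooled mean squared end-to-end distance over all pairs at each lag
pooled_msd <- function(traces, ds, max_lag) {
  sums <- numeric(max_lag)
  counts <- numeric(max_lag)
  for (tr in traces) {
    n <- length(tr$x)
    for (m in seq_len(min(max_lag, n - 1))) {
      dx <- tr$x[(1 + m):n] - tr$x[1:(n - m)]
      dy <- tr$y[(1 + m):n] - tr$y[1:(n - m)]
      sums[m] <- sums[m] + sum(dx^2 + dy^2)
      counts[m] <- counts[m] + (n - m)
    }
  }
  keep <- counts > 0
  data.frame(lag = which(keep), s_nm = which(keep) * ds,
             msd = sums[keep] / counts[keep], n_pairs = counts[keep])
}

default_s_max_um <- function(traces) {
  lens <- vapply(traces, contour_length, 0)
  min(min(lens) / 2, 2 * mean(lens)) / 1000
}

pl_estimate <- function(lp_um, ci, method, s_max_um, n_traces, flag = NULL) {
  structure(list(lp = lp_um, ci_low = ci[1], ci_high = ci[2], method = method,
                 s_max_fit = s_max_um, n_traces = n_traces, flag = flag),
            class = "PLEstimate")
}

#' @export
print.PLEstimate <- function(x, ...) {
  cat(sprintf("PLEstimate (%s): Lp = %.2f um [%.2f, %.2f], %d traces, fit to %.2f um%s\n",
              x$method, x$lp, x$ci_low, x$ci_high, x$n_traces, x$s_max_fit,
              if (!is.null(x$flag)) paste0(" (", x$flag, ")") else ""))
  invisible(x)
}

tancorr_lp_from_curve <- function(tc, dim2d) {
  # truncate at first nonpositive correlation, then weighted log-linear fit
  # through the origin: log<cos theta> = -s / (2 Lp) in the 2D convention
  bad <- which(tc$corr <= 0)
  if (length(bad) > 0) tc <- tc[seq_len(bad[1] - 1), , drop = FALSE]
  if (nrow(tc) < 2) return(NA_real_)
  y <- log(tc$corr)
  w <- tc$n_pairs
  slope <- sum(w * tc$s_nm * y) / sum(w * tc$s_nm^2)
  if (slope >= 0) return(Inf)
  lp_nm <- if (dim2d) -1 / (2 * slope) else -1 / slope
  lp_nm / 1000
}

#' Persistence length by tangent-correlation decay
#'
#' Pools `<cos theta(s)>` over all tangent pairs separated by arc length `s`
#' across traces and fits the 2D-equilibrium worm-like-chain decay
#' `<cos theta(s)> = exp(-s / (2 Lp))` by weighted least squares on the
#' log-transformed correlations (weights proportional to pair counts).
#' The factor 2 is the planar-equilibrium convention appropriate for
#' filaments adsorbed to a surface at thermodynamic equilibrium; `dim = "3d"`
#' fits `exp(-s / Lp)` for projected, non-equilibrated data.
#'
#' @param traces list of `Trace2D`, uniformly discretized at `ds`.
#' @param ds discretization spacing (nm).
#' @param s_max fit range upper bound (micrometres). Default
#'   `min(shortest contour / 2, 2 * mean contour)`.
#' @param dim `"2d"` (default) or `"3d"` decay convention.
#' @param n_boot bootstrap replicates over traces for the 95% CI (default
#'   200; 0 disables).
#' @return A `PLEstimate` (lp and CI in micrometres). Straight ensembles give
#'   `lp = Inf` with flag `"straight"`.
#' @export
estimate_pl_tancorr <- function(traces, ds, s_max = NULL, dim = c("2d", "3d"),
                                n_boot = 200) {
  dim <- match.arg(dim)
  stopifnot(length(traces) >= 1)
  if (is.null(s_max)) s_max <- default_s_max_um(traces)
  if (s_max * 1000 < 10 * ds) stop("s_max must be at least 10 * ds")
  max_lag <- floor(s_max * 1000 / ds)
  tc <- pooled_tancorr(traces, ds, max_lag)
  lp <- tancorr_lp_from_curve(tc, dim == "2d")
  flag <- NULL
  if (is.infinite(lp)) flag <- "straight"
  if (any(tc$corr <= 0)) flag <- c(flag, "fit range truncated at nonpositive correlation")
  ci <- c(NA_real_, NA_real_)
  if (length(traces) < 3) {
    flag <- c(flag, "fewer than 3 traces: no CI")
  } else if (n_boot > 0 && is.finite(lp)) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(traces), replace = TRUE)
      tancorr_lp_from_curve(pooled_tancorr(traces[idx], ds, max_lag), dim == "2d")
    }, 0)
    ci <- unname(quantile(boots[is.finite(boots)], c(0.025, 0.975), na.rm = TRUE))
  }
  pl_estimate(lp, ci, "tancorr", s_max, length(traces),
              if (length(flag)) paste(flag, collapse = "; ") else NULL)
}

wlc_msd_2d <- function(s, lp) {
  # 2D worm-like chain mean squared end-to-end distance, decay constant 2 Lp
  4 * lp * (s - 2 * lp * (1 - exp(-s / (2 * lp))))
}

msd_lp_from_curve <- function(ms, straight_tol = 1e-6) {
  w <- ms$n_pairs
  obj <- function(loglp) {
    lp <- exp(loglp)
    sum(w * (ms$msd - wlc_msd_2d(ms$s_nm, lp))^2)
  }
  lo <- log(min(ms$s_nm) / 10); hi <- log(max(ms$s_nm) * 1e4)
  opt <- optimize(obj, c(lo, hi))
  lp_nm <- exp(opt$minimum)
  # rigid limit: <R^2> -> s^2; optimizer pinned at the upper bound means the
  # data carry no curvature signal
  if (opt$minimum > hi - 1e-3) return(Inf)
  lp_nm / 1000
}

#' Persistence length from mean-squared end-to-end distance
#'
#' Fits the pooled mean-squared end-to-end distance versus arc length to the
#' 2D worm-like-chain form
#' `<R^2(s)> = 4 Lp (s - 2 Lp (1 - exp(-s / (2 Lp))))`
#' by weighted nonlinear least squares (weights proportional to pair counts).
#' In the rigid limit `s << Lp` the form reduces to `<R^2> = s^2`, so straight
#' ensembles return the `Inf` sentinel.
#'
#' @inheritParams estimate_pl_tancorr
#' @return A `PLEstimate` (micrometres).
#' @export
estimate_pl_msd <- function(traces, ds, s_max = NULL, n_boot = 200) {
  stopifnot(length(traces) >= 1)
  if (is.null(s_max)) s_max <- default_s_max_um(traces)
  if (s_max * 1000 < 10 * ds) stop("s_max must be at least 10 * ds")
  max_lag <- floor(s_max * 1000 / ds)
  ms <- pooled_msd(traces, ds, max_lag)
  lp <- msd_lp_from_curve(ms)
  flag <- if (is.infinite(lp)) "straight" else NULL
  ci <- c(NA_real_, NA_real_)
  if (length(traces) < 3) {
    flag <- c(flag, "fewer than 3 traces: no CI")
  } else if (n_boot > 0 && is.finite(lp)) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(traces), replace = TRUE)
      msd_lp_from_curve(pooled_msd(traces[idx], ds, max_lag))
    }, 0)
    ci <- unname(quantile(boots[is.finite(boots)], c(0.025, 0.975), na.rm = TRUE))
  }
  pl_estimate(lp, ci, "msd", s_max, length(traces),
              if (length(flag)) paste(flag, collapse = "; ") else NULL)
}

#' Read filament traces from a block TSV
#'
#' One filament per block: a `# id` comment line starts each block, followed
#' by two tab-separated columns `x_nm`, `y_nm`.
#'
#' @param path TSV path.
#' @return list of `Trace2D`.
#' @export
read_traces_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur_id <- NULL; xs <- ys <- numeric(0)
  flush <- function() {
    if (!is.null(cur_id) && length(xs) >= 3) {
      out[[length(out) + 1]] <<- trace2d(xs, ys, label = cur_id)
    }
  }
  for (l in lines) {
    l <- trimws(l)
    if (l == "" || identical(l, "x_nm\ty_nm")) next
    if (startsWith(l, "#")) {
      flush()
      cur_id <- trimws(sub("^#", "", l))
      xs <- ys <- numeric(0)
    } else {
      parts <- as.numeric(strsplit(l, "\t")[[1]])
      xs <- c(xs, parts[1]); ys <- c(ys, parts[2])
    }
  }
  flush()
  if (length(out) == 0) stop("no traces found in ", path)
  out
}

#' Write filament traces as a block TSV
#' @param traces list of `Trace2D`.
#' @param path output path.
#' @export
write_traces_tsv <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    id <- if (nzchar(tr$label)) tr$label else sprintf("trace%04d", i)
    writeLines(sprintf("# %s", id), con)
    writeLines(sprintf("%.6f\t%.6f", tr$x, tr$y), con)
  }
  invisible(path)
}
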