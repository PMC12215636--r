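#' Construct a calibration curve object
#'
#' A calibration curve tabulates the conventional radiocarbon age (and its
#' one-sigma curve error) expected for material of a given calendar age.
#' Southern-hemisphere terrestrial samples are calibrated against SHCal20;
#' synthetic curves with the same structure are used throughout the test
#' suite.
#'
#' @param cal_bp calendar age grid, cal BP, strictly increasing, length >= 2.
#' @param c14_age conventional radiocarbon age (14C yr BP) at each knot.
#' @param c14_sigma one-sigma curve error (14C yr) at each knot; must be
#'   non-negative (files read with [load_curve()] must be strictly positive).
#' @param name curve label.
#' @return An object of class `cal_curve`.
#' @export
cal_curve <- function(cal_bp, c14_age, c14_sigma, name = "custom") {
  cal_bp <- as.numeric(cal_bp)
  c14_age <- as.numeric(c14_age)
  c14_sigma <- as.numeric(c14_sigma)
  if (length(cal_bp) < 2)
    stop("calibration curve needs at least 2 knots", call. = FALSE)
  if (length(c14_age) != length(cal_bp) || length(c14_sigma) != length(cal_bp))
    stop("cal_bp, c14_age and c14_sigma must have equal length", call. = FALSE)
  if (anyNA(cal_bp) || anyNA(c14_age) || anyNA(c14_sigma))
    stop("calibration curve contains missing values", call. = FALSE)
  if (any(diff(cal_bp) <= 0))
    stop("cal_bp grid must be strictly increasing (duplicate or unsorted ages)",
         call. = FALSE)
  if (any(c14_sigma < 0))
    stop("curve errors must be non-negative", call. = FALSE)
  structure(list(cal_bp = cal_bp, c14_age = c14_age, c14_sigma = c14_sigma,
                 name = name),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("Calibration curve '%s': %d knots, %s-%s cal BP\n",
              x$name, length(x$cal_bp), format(min(x$cal_bp)),
              format(max(x$cal_bp))))
  invisible(x)
}

#' Read a calibration curve from disk
#'
#' Reads the IntCal/SHCal20 distribution format: comment lines starting with
#' `#`, data lines with comma-separated columns `CAL BP, 14C age, Error`
#' (further columns ignored). A plain CSV dialect with a header row and the
#' same first three columns is also accepted. Rows are sorted by increasing
#' cal BP; duplicate calendar ages and non-positive errors are rejected.
#'
#' @param path path to the curve file.
#' @param dialect `"intcal"` (default) or `"csv"`.
#' @param name curve label; defaults to the file name.
#' @return A [cal_curve()] object.
#' @export
load_curve <- function(path, dialect = c("intcal", "csv"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("curve file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (dialect == "csv" && length(idx)) idx <- idx[-1]  # header row
  if (!length(idx)) stop("no data lines in curve file: ", path, call. = FALSE)
  parse_row <- function(i) {
    fields <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(fields) < 3)
      stop(sprintf("malformed curve line %d: fewer than 3 columns", i),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals))
      stop(sprintf("malformed curve line %d: non-numeric field", i),
           call. = FALSE)
    vals
  }
  m <- t(vapply(idx, parse_row, numeric(3)))
  if (any(m[, 3] <= 0))
    stop("curve error column must be strictly positive", call. = FALSE)
  if (anyDuplicated(m[, 1]))
    stop("duplicate calendar ages in curve file", call. = FALSE)
  ord <- order(m[, 1])
  cal_curve(m[ord, 1], m[ord, 2], m[ord, 3],
            name = name %||% basename(path))
}

#' Evaluate a calibration curve at calendar ages
#'
#' Linear interpolation of the curve mean and one-sigma error between
#' bracketing knots.
#'
#' @param curve a [cal_curve()].
#' @param cal_age calendar age(s), cal BP, within the curve span.
#' @return A list with numeric vectors `c14_age` and `c14_sigma`.
#' @export
curve_at <- function(curve, cal_age) {
  stopifnot(inherits(curve, "cal_curve"))
  rng <- range(curve$cal_bp)
  if (any(cal_age < rng[1] | cal_age > rng[2]))
    stop(sprintf("calendar age outside curve span [%g, %g] cal BP",
                 rng[1], rng[2]), call. = FALSE)
  list(c14_age = stats::approx(curve$cal_bp, curve$c14_age, cal_age)$y,
       c14_sigma = stats::approx(curve$cal_bp, curve$c14_sigma, cal_age)$y)
}

#' Construct a radiocarbon determination
#'
#' @param c14_age conventional radiocarbon age, 14C yr BP.
#' @param c14_error one-sigma laboratory measurement error, 14C yr, > 0.
#' @param lab_id optional laboratory code.
#' @return An object of class `c14_date`.
#' @export
c14_date <- function(c14_age, c14_error, lab_id = NA_character_) {
  if (!is.finite(c14_age) || !is.finite(c14_error) || c14_error <= 0)
    stop("c14_error must be a positive number", call. = FALSE)
  structure(list(c14_age = c14_age, c14_error = c14_error, lab_id = lab_id),
            class = "c14_date")
}

# Construct a calibrated-density object on a uniform calendar grid.
new_cal_density <- function(grid, density) {
  structure(list(grid = grid, density = density,
                 delta = if (length(grid) > 1) grid[2] - grid[1] else 1),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Calibrated density: %.0f +/- %.0f cal BP (median %.0f), grid step %g yr\n",
              s$mu, s$sigma, s$median, x$delta))
  invisible(x)
}

# Vectorised calibration workhorse: normalized posterior densities for many
# determinations on one shared calendar grid. Returns an n_dates x n_grid
# matrix whose rows integrate to 1 over the grid; rows with (numerically)
# no likelihood mass on the grid are returned as NA and reported via the
# "failed" attribute.
calibrate_matrix <- function(c14_ages, c14_errors, curve, grid) {
  cv <- curve_at(curve, grid)
  delta <- if (length(grid) > 1) grid[2] - grid[1] else 1
  # total sigma^2 per (date, grid point); likelihood of the measurement given
  # calendar age t under a Gaussian measurement + Gaussian curve error model
  var_tot <- outer(c14_errors^2, cv$c14_sigma^2, `+`)
  dev <- outer(c14_ages, cv$c14_age, `-`)
  ll <- exp(-dev^2 / (2 * var_tot)) / sqrt(var_tot)
  mass <- rowSums(ll) * delta
  failed <- !is.finite(mass) | mass < 1e-300
  out <- ll
  out[failed, ] <- NA_real_
  ok <- which(!failed)
  if (length(ok)) out[ok, ] <- ll[ok, , drop = FALSE] / mass[ok]
  attr(out, "failed") <- which(failed)
  out
}

#' Calibrate a radiocarbon determination
#'
#' Computes the posterior density of the sample's calendar age under a flat
#' calendar prior: the Gaussian measurement likelihood is combined with the
#' interpolated curve error, evaluated on a uniform calendar grid over the
#' curve span, normalized to integrate to 1, and truncated to the region
#' carrying non-negligible mass (per-point mass below `tail_cut` is dropped
#' and the remainder renormalized).
#'
#' @param date a [c14_date()] (or a list with `c14_age`, `c14_error`).
#' @param curve a [cal_curve()].
#' @param grid_step calendar grid step, yr (default 1).
#' @param grid optional explicit calendar grid (uniform, cal BP); overrides
#'   `grid_step` and suppresses tail truncation (used when many densities
#'   must share a grid).
#' @param tail_cut per-point mass threshold for tail truncation.
#' @return A `cal_density` object.
#' @export
calibrate <- function(date, curve, grid_step = 1, grid = NULL,
                      tail_cut = 1e-6) {
  stopifnot(grid_step > 0)
  explicit <- !is.null(grid)
  if (!explicit)
    grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  m <- calibrate_matrix(date$c14_age, date$c14_error, curve, grid)
  if (length(attr(m, "failed")))
    stop("calibration failed: no likelihood mass within the curve span",
         call. = FALSE)
  dens <- m[1, ]
  delta <- if (length(grid) > 1) grid[2] - grid[1] else 1
  if (!explicit) {
    keep <- which(dens * delta >= tail_cut)
    if (length(keep) >= 2) {
      sel <- keep[1]:keep[length(keep)]
      grid <- grid[sel]
      dens <- dens[sel]
    }
    dens <- dens / (sum(dens) * delta)
  }
  new_cal_density(grid, dens)
}

#' Summarize a calibrated density
#'
#' Mean, standard deviation and median of the calendar-age posterior, plus
#' highest-posterior-density (HPD) intervals at the requested level. HPD
#' intervals are found by the descending-density watershed: grid cells are
#' admitted in order of decreasing density until the requested mass is
#' reached; the marginal cell contributes fractionally so that the interval
#' masses sum to the level exactly. Interval bounds are reported at grid-cell
#' edges.
#'
#' @param object a `cal_density`.
#' @param level HPD mass, in (0, 1); default 0.954 (the conventional
#'   two-sigma level).
#' @param ... unused.
#' @return A list with `mu`, `sigma`, `median` (cal BP), `level` and `hpd`
#'   (data frame with columns `lo`, `hi` in cal BP and `mass`).
#' @export
summary.cal_density <- function(object, level = 0.954, ...) {
  g <- object$grid
  p <- object$density * object$delta      # per-cell mass
  mu <- sum(g * p)
  sigma <- sqrt(max(0, sum((g - mu)^2 * p)))
  cf <- cumsum(p)
  i <- which(cf >= 0.5)[1]
  below <- if (i > 1) cf[i - 1] else 0
  med <- g[i] - object$delta / 2 + object$delta * (0.5 - below) / p[i]
  list(mu = mu, sigma = sigma, median = med, level = level,
       hpd = hpd_intervals(g, p, object$delta, level))
}

hpd_intervals <- function(grid, mass, delta, level) {
  ord <- order(mass, decreasing = TRUE)
  cm <- cumsum(mass[ord])
  k <- which(cm >= level)[1]
  if (is.na(k)) k <- length(ord)
  frac <- if (k == 1) level / mass[ord[k]] else
    (level - cm[k - 1]) / mass[ord[k]]
  frac <- min(max(frac, 0), 1)
  included <- logical(length(grid))
  included[ord[seq_len(k)]] <- TRUE
  runs <- true_runs(included)
  marginal <- ord[k]
  out <- data.frame(lo = grid[runs[, "start"]] - delta / 2,
                    hi = grid[runs[, "end"]] + delta / 2,
                    mass = vapply(seq_len(nrow(runs)), function(r) {
                      cells <- runs[r, "start"]:runs[r, "end"]
                      m <- sum(mass[cells])
                      if (marginal %in% cells)
                        m <- m - (1 - frac) * mass[marginal]
                      m
                    }, numeric(1)))
  out[order(out$lo), , drop = FALSE]
}

#' Simulate a radiocarbon determination from a known calendar age
#'
#' The measurement is drawn from a normal distribution centred on the curve
#' value at the calendar age, with variance equal to the sum of the squared
#' curve error and the squared intended laboratory error, then rounded to the
#' nearest 14C year. The reported error is the laboratory error alone; the
#' curve error re-enters at calibration. This mirrors how simulated
#' determinations are produced for indirectly dated samples.
#'
#' @param cal_age true calendar age(s), cal BP, within the curve span.
#' @param curve a [cal_curve()].
#' @param meas_error one-sigma laboratory error to report, 14C yr (>= 0);
#'   default 30.
#' @param seed optional integer seed.
#' @return A data frame with columns `c14_age` and `c14_error`, one row per
#'   input age.
#' @export
simulate_date <- function(cal_age, curve, meas_error = 30, seed = NULL) {
  if (any(meas_error < 0)) stop("meas_error must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cv <- curve_at(curve, cal_age)
  sd_tot <- sqrt(cv$c14_sigma^2 + meas_error^2)
  m <- round(stats::rnorm(length(cal_age), cv$c14_age, sd_tot))
  data.frame(c14_age = m,
             c14_error = rep_len(meas_error, length(cal_age)))
}
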