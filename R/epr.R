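## SDSL-EPR readouts: central-line mobility, power saturation, accessibility,
## helical periodicity, closed-vs-open segment calling.

#' Mobility parameter from a CW spectrum
#'
#' Returns 1 / (peak-to-peak field width of the central resonance line) of a
#' first-derivative spectrum.  The central line is identified as the
#' derivative extremum pair bracketing the grid midpoint within a search
#' window; ties are broken toward the larger amplitude swing.
#'
#' @param spectrum an `EPRSpectrum` (list with `field`, `amplitude`)
#' @param window_G half-width of the central search window, Gauss
#' @return mobility parameter, 1/Gauss
#' @export
mobility_parameter <- function(spectrum, window_G = 8) {
  f <- spectrum$field; a <- spectrum$amplitude
  mid <- (f[1] + f[length(f)]) / 2
  sel <- which(f >= mid - window_G & f <= mid + window_G)
  if (length(sel) < 5) stop("no resolvable central line", call. = FALSE)
  left <- sel[f[sel] <= mid]; right <- sel[f[sel] >= mid]
  imax <- left[which.max(a[left])]
  imin <- right[which.min(a[right])]
  if (a[imax] <= 0 || a[imin] >= 0 || f[imin] <= f[imax])
    stop("no resolvable central line", call. = FALSE)
  width <- f[imin] - f[imax]
  1 / width
}

#' Fit a power-saturation curve
#'
#' Nonlinear least squares fit of
#' A(P) = scale sqrt(P) / (1 + (2^(1/eps) - 1) P / p_half)^eps.
#'
#' @param curve a `PowerSatCurve` (list with `power`, `amplitude`)
#' @return list(p_half, eps, scale, residual)
#' @export
fit_power_saturation <- function(curve) {
  P <- curve$power; A <- curve$amplitude
  if (length(P) < 6) stop("need >= 6 power points", call. = FALSE)
  obj <- function(par) {
    m <- power_sat_model(P, exp(par[1]), exp(par[2]), exp(par[3]))
    sum((m - A)^2)
  }
  ## starts: p_half near the amplitude maximum, a few eps seeds
  i0 <- which.max(A)
  s0 <- max(A[1] / sqrt(P[1]), 1e-6)
  best <- NULL
  for (eps0 in c(0.5, 1.5, 3)) for (ph0 in c(P[i0], 2 * P[i0], P[i0] / 2)) {
    fit <- stats::nlminb(log(c(ph0, eps0, s0)), obj,
                         control = list(iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("power-saturation fit did not converge", call. = FALSE)
  list(p_half = exp(best$par[1]), eps = exp(best$par[2]),
       scale = exp(best$par[3]), residual = sqrt(best$objective / length(P)))
}

#' NiEdda accessibility parameter
#'
#' Pi = reference_factor * (P1/2(NiEdda) - P1/2(N2)) / central linewidth.
#' A negative value (NiEdda P1/2 below the N2 control) is returned with a
#' warning.
#'
#' @param p_half_niedda,p_half_n2 half-saturation powers, mW
#' @param central_width central-line peak-to-peak width, Gauss
#' @param reference_factor normalisation constant (default 1; absolute
#'   values are comparable only within a run)
#' @return Pi, dimensionless
#' @export
accessibility_pi <- function(p_half_niedda, p_half_n2, central_width,
                             reference_factor = 1) {
  if (central_width <= 0 || p_half_niedda <= 0 || p_half_n2 <= 0)
    stop("powers and width must be > 0", call. = FALSE)
  if (p_half_niedda < p_half_n2)
    warning("NiEdda P1/2 below N2 control; returning negative accessibility")
  reference_factor * (p_half_niedda - p_half_n2) / central_width
}

#' Helical periodicity of a mobility profile
#'
#' Fraction of the detrended profile variance in a residue window explained
#' by the best-fitting sinusoid with angular period constrained to the
#' alpha-helical band (95-105 degrees/residue).  A pure 100 deg/residue
#' cosine gives ~1; a constant profile gives 0.
#'
#' @param profile a `MobilityProfile`
#' @param window inclusive residue interval, default c(116, 131)
#' @param band angular frequency band, degrees/residue
#' @return band power fraction in `[0, 1]`
#' @export
helical_periodicity <- function(profile, window = c(116L, 131L),
                                band = c(95, 105)) {
  sel <- profile$residue >= window[1] & profile$residue <= window[2]
  res <- profile$residue[sel]; v <- profile$value[sel]
  if (length(res) < 8) stop("window must span >= 8 residues", call. = FALSE)
  ## detrend (linear)
  fitl <- stats::lm.fit(cbind(1, res), v)
  y <- fitl$residuals
  tot <- sum(y^2)
  if (tot < 1e-20) return(0)
  freqs <- seq(band[1], band[2], by = 0.25) / 360    # cycles per residue
  best <- 0
  for (fr in freqs) {
    X <- cbind(cos(2 * pi * fr * res), sin(2 * pi * fr * res))
    ft <- stats::lm.fit(X, y)
    expl <- tot - sum(ft$residuals^2)
    best <- max(best, expl / tot)
  }
  best
}

#' Contiguous segments of increased open-state mobility
#'
#' Maximal runs of at least `min_run` residues where (open - closed) exceeds
#' `min_shift`.
#'
#' @param closed,open `MobilityProfile`s on the same residue set
#' @param min_shift threshold, 1/Gauss (default 0.03)
#' @param min_run minimum run length (default 3)
#' @return list of c(lo, hi) residue intervals (possibly empty)
#' @export
delta_mobility_segments <- function(closed, open, min_shift = 0.03,
                                    min_run = 3L) {
  if (!identical(closed$residue, open$residue))
    stop("profiles are on different residue sets", call. = FALSE)
  d <- open$value - closed$value
  above <- d > min_shift
  segs <- list()
  i <- 1L; n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run)
        segs[[length(segs) + 1L]] <- c(closed$residue[i], closed$residue[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  segs
}

## ---- CSV interfaces --------------------------------------------------------

#' Read/write EPR artefacts as CSV
#'
#' Spectra use columns `field_G,amplitude`; power-saturation curves use
#' `power_mW,amplitude`; mobility profiles use `residue,state,value`.
#'
#' @param x object to write
#' @param path file path
#' @return the path (writers, invisibly) or the parsed object (readers)
#' @export
write_spectrum_csv <- function(x, path) {
  utils::write.csv(data.frame(field_G = x$field, amplitude = x$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(field = d$field_G, amplitude = d$amplitude,
                 metadata = list(source = path)), class = "EPRSpectrum")
}

#' @rdname write_spectrum_csv
#' @export
write_powersat_csv <- function(x, path) {
  utils::write.csv(data.frame(power_mW = x$power, amplitude = x$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_powersat_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(power = d$power_mW, amplitude = d$amplitude,
                 relaxer = "unknown"), class = "PowerSatCurve")
}

#' @rdname write_spectrum_csv
#' @param profiles list of `MobilityProfile`s
#' @export
write_profiles_csv <- function(profiles, path) {
  d <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = p$residue, state = p$state, value = p$value)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_profiles_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$state), function(s)
    mobility_profile(s$residue, s$value, s$state[1]))
}
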