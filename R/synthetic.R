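#' Specification of an idealized pentameric channel geometry
#'
#' Describes the stylized closed-state geometry of a MscL-like homopentamer:
#' four alpha-helical segments per subunit (N-terminal amphipathic helix,
#' transmembrane helices TM1 and TM2, and the cytoplasmic C-terminal helix),
#' arranged with exact n-fold rotational symmetry about the z axis, plus the
#' bilayer plate.  Defaults are the rod dimensions used throughout the
#' package: radius 2.5 A; lengths N-term 18.65, TM1 47.33, TM2 42.51 and
#' C-term 36.06 A; bilayer thickness 35 A.
#'
#' @param n_subunits number of subunits (>= 3); default 5
#' @param rod_lengths named numeric vector of helix lengths in Angstrom with
#'   names `N-term`, `TM1`, `TM2`, `C-term`
#' @param rod_radius rod cross-section radius, Angstrom (< `bundle_radius`)
#' @param bundle_radius distance of the C-terminal helix axes from the
#'   symmetry axis, Angstrom (coiled-coil radius; default 8)
#' @param tm_tilt tilt of TM1 from the pore axis, degrees (default 25)
#' @param plate_thickness bilayer thickness, Angstrom (default 35)
#' @param plate_extent outer radius of the bilayer plate, Angstrom
#' @param seed integer or NULL; kept for interface uniformity (the ideal
#'   geometry is deterministic)
#' @return an object of class `PentamerSpec`
#' @export
pentamer_spec <- function(n_subunits = 5L,
                          rod_lengths = c(`N-term` = 18.65, TM1 = 47.33,
                                          TM2 = 42.51, `C-term` = 36.06),
                          rod_radius = 2.5,
                          bundle_radius = 8,
                          tm_tilt = 25,
                          plate_thickness = 35,
                          plate_extent = 120,
                          seed = NULL) {
  spec <- list(n_subunits = as.integer(n_subunits), rod_lengths = rod_lengths,
               rod_radius = rod_radius, bundle_radius = bundle_radius,
               tm_tilt = tm_tilt, plate_thickness = plate_thickness,
               plate_extent = plate_extent, seed = seed)
  class(spec) <- "PentamerSpec"
  validate_pentamer_spec(spec)
  spec
}

validate_pentamer_spec <- function(spec) {
  roles <- c("N-term", "TM1", "TM2", "C-term")
  if (!is.numeric(spec$n_subunits) || length(spec$n_subunits) != 1L ||
      spec$n_subunits < 3)
    stop("invalid PentamerSpec field 'n_subunits': must be a single count >= 3",
         call. = FALSE)
  if (!all(roles %in% names(spec$rod_lengths)))
    stop("invalid PentamerSpec field 'rod_lengths': needs names ",
         paste(roles, collapse = ", "), call. = FALSE)
  if (any(!is.finite(spec$rod_lengths)) || any(spec$rod_lengths <= 0))
    stop("invalid PentamerSpec field 'rod_lengths': all lengths must be > 0",
         call. = FALSE)
  for (f in c("rod_radius", "bundle_radius", "tm_tilt", "plate_thickness",
              "plate_extent")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("invalid PentamerSpec field '%s': must be a single positive number", f),
           call. = FALSE)
  }
  if (spec$rod_radius >= spec$bundle_radius)
    stop("invalid PentamerSpec field 'rod_radius': must be < bundle_radius",
         call. = FALSE)
  invisible(spec)
}

## C-terminal residue window used throughout (A110..S136 inclusive = 27)
.cterm_range <- c(110L, 136L)

## linear residue -> arc-fraction map along the C-terminal rod, 110 at the
## membrane-proximal (top) end
cterm_fraction <- function(res) {
  (res - .cterm_range[1]) / (.cterm_range[2] - .cterm_range[1])
}

#' Generate an idealized n-fold symmetric pentamer geometry
#'
#' Builds the coarse rod/plate representation of the closed channel: per
#' subunit a radial N-terminal rod at the cytoplasmic bilayer surface, a
#' tilted TM1, a nearly vertical TM2 whose cytoplasmic end protrudes below
#' the bilayer, and a C-terminal rod co-linear with the symmetry axis
#' direction at `bundle_radius`.  Belt interaction sites (top E118, middle
#' E124/R126/D127, bottom R135/S136) are placed on the C-terminal rod axis at
#' the linear residue->arc fractions.  The construction is exactly n-fold
#' symmetric by rotation of a single master subunit.
#'
#' @param spec a [pentamer_spec()]
#' @return a `CoarseGeometry` (see [coarse_geometry()])
#' @export
gen_ideal_pentamer <- function(spec) {
  validate_pentamer_spec(spec)
  n  <- spec$n_subunits
  L  <- spec$rod_lengths
  hz <- spec$plate_thickness / 2
  tilt1 <- spec$tm_tilt * pi / 180
  tilt2 <- 8 * pi / 180                 # TM2 near-vertical

  ## master subunit in the x-z plane (azimuth 0); columns: start xyz, end xyz
  r_ct  <- spec$bundle_radius
  ## TM1: centred on the membrane, leaning outward going up
  tm1_s <- c(r_ct, 0, -L[["TM1"]] * cos(tilt1) / 2)
  tm1_e <- c(r_ct + L[["TM1"]] * sin(tilt1), 0, L[["TM1"]] * cos(tilt1) / 2)
  ## TM2: top at the periplasmic surface, bottom protruding into the cytoplasm
  tm2_top_r <- r_ct + 14
  tm2_e <- c(tm2_top_r, 0, hz + 0.5)
  tm2_s <- c(tm2_top_r - L[["TM2"]] * sin(tilt2), 0,
             hz + 0.5 - L[["TM2"]] * cos(tilt2))
  ## N-term: radial, just below the cytoplasmic bilayer surface
  nt_z <- -(hz + 1.5)
  nt_s <- c(r_ct, 0, nt_z)
  nt_e <- c(r_ct + L[["N-term"]], 0, nt_z)
  ## C-term: vertical, top a little below the TM2 cytoplasmic end
  ct_top <- tm2_s[3] - 3
  ct_s <- c(r_ct, 0, ct_top)                    # start = membrane-proximal end
  ct_e <- c(r_ct, 0, ct_top - L[["C-term"]])

  master <- rbind(`N-term` = c(nt_s, nt_e), TM1 = c(tm1_s, tm1_e),
                  TM2 = c(tm2_s, tm2_e), `C-term` = c(ct_s, ct_e))

  rot_xy <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                              sin(th) * p[1] + cos(th) * p[2], p[3])
  rows <- vector("list", n * 4L)
  k <- 0L
  for (s in seq_len(n)) {
    th <- 2 * pi * (s - 1) / n
    for (role in rownames(master)) {
      k <- k + 1L
      a <- rot_xy(master[role, 1:3], th); b <- rot_xy(master[role, 4:6], th)
      rows[[k]] <- data.frame(role = role, subunit = s,
                              sx = a[1], sy = a[2], sz = a[3],
                              ex = b[1], ey = b[2], ez = b[3],
                              radius = spec$rod_radius,
                              stringsAsFactors = FALSE)
    }
  }
  rods <- do.call(rbind, rows)
  rods$rod_id <- seq_len(nrow(rods))

  belts <- belt_spec()
  belt_sites <- lapply(belts$residues, function(rr) {
    out <- lapply(seq_len(n), function(s) {
      th <- 2 * pi * (s - 1) / n
      do.call(rbind, lapply(names(rr), function(lab) {
        res <- rr[[lab]]
        f <- cterm_fraction(res)
        p0 <- ct_s + f * (ct_e - ct_s)
        p  <- rot_xy(p0, th)
        data.frame(subunit = s, residue = res, label = lab,
                   x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })

  ## tie loci: TM2 along its bilayer span, N-term everywhere, head of TM1
  tie_pairs <- rbind(
    data.frame(role = "TM2", locus = "span", stringsAsFactors = FALSE),
    data.frame(role = "N-term", locus = "all", stringsAsFactors = FALSE),
    data.frame(role = "TM1", locus = "head", stringsAsFactors = FALSE))

  ## plate opening: outer radial extent of the TM rods within the bilayer
  tm <- rods[rods$role %in% c("TM1", "TM2"), ]
  foot <- max(apply(tm, 1, function(r) {
    s <- as.numeric(r[c("sx", "sy", "sz")]); e <- as.numeric(r[c("ex", "ey", "ez")])
    tt <- seq(0, 1, length.out = 21)
    pts <- outer(tt, e - s) + matrix(s, 21, 3, byrow = TRUE)
    keep <- abs(pts[, 3]) <= hz
    if (!any(keep)) return(0)
    max(sqrt(pts[keep, 1]^2 + pts[keep, 2]^2))
  })) + spec$rod_radius

  coarse_geometry(
    rods = rods,
    plate = list(thickness = spec$plate_thickness, extent = spec$plate_extent,
                 z = 0, inner_radius = foot + 2.75, footprint_radius = foot),
    belt_sites = belt_sites,
    tie_pairs = tie_pairs,
    metadata = list(source = "gen_ideal_pentamer", n_subunits = n,
                    site_atom = "CA"))
}

#' Generate an atomistic donor/acceptor fixture with a planted number of
#' hydrogen bonds
#'
#' Builds point sets of donor groups (N with attached H) and acceptor groups
#' (carbonyl O with antecedent C) in which exactly `n_planted` donor-acceptor
#' pairs satisfy the geometric hydrogen-bond criterion (donor-acceptor
#' distance <= 3.5 A and deviation of the D-H...A angle from linearity
#' <= 30 degrees).  Decoy pairs violating exactly one criterion each are
#' added.  Groups are placed on a coarse spatial lattice so no accidental
#' cross-pair bonds arise; the ground-truth count is stored in the metadata.
#'
#' @param belt belt identifier tag ("top", "middle" or "bottom"); metadata only
#' @param n_planted number of true hydrogen bonds to plant (>= 0)
#' @param separation donor-acceptor distance of the planted bonds, Angstrom;
#'   must be <= the 3.5 A cutoff
#' @param seed integer RNG seed
#' @return an `AtomisticFixture`: list with data frames `donors`
#'   (nx,ny,nz,hx,hy,hz) and `acceptors` (ox,oy,oz,cx,cy,cz) and `meta`
#' @export
gen_belt_fixture <- function(belt = "bottom", n_planted = 5L,
                             separation = 2.9, seed = 1L) {
  if (!is.numeric(n_planted) || n_planted < 0)
    stop("'n_planted' must be >= 0", call. = FALSE)
  if (!is.numeric(separation) || separation <= 0)
    stop("'separation' must be > 0", call. = FALSE)
  if (separation > 3.5)
    stop("impossible geometry: planted bond separation ", separation,
         " A exceeds the 3.5 A cutoff", call. = FALSE)
  n_planted <- as.integer(n_planted)
  n_decoy_d <- max(2L, ceiling(n_planted / 2))   # distance violators
  n_decoy_a <- max(2L, ceiling(n_planted / 2))   # angle violators
  n_tot <- n_planted + n_decoy_d + n_decoy_a

  with_seed(seed, {
    ## lattice cells 14 A apart; all intra-group offsets < 6 A
    side <- ceiling(n_tot^(1/3))
    idx <- seq_len(n_tot) - 1L
    centers <- cbind(idx %% side, (idx %/% side) %% side,
                     idx %/% (side * side)) * 14
    centers <- centers + matrix(runif(3 * n_tot, -1, 1), n_tot, 3)

    rand_unit <- function() {
      v <- rnorm(3); v / sqrt(sum(v * v))
    }
    ## unit vector at exactly `ang` radians from unit vector u
    tilted_unit <- function(u, ang) {
      p <- rnorm(3); p <- p - sum(p * u) * u
      p <- p / sqrt(sum(p * p))
      cos(ang) * u + sin(ang) * p
    }
    dev_angle <- function(D, H, A) {
      v1 <- H - D; v2 <- A - H
      cc <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(1, pmax(-1, cc))) * 180 / pi
    }
    make_group <- function(center, dist, dev_lo, dev_hi) {
      ## rejection-sample an (N,H,O) geometry with deviation in [dev_lo, dev_hi]
      repeat {
        u <- rand_unit()
        Dp <- center
        Ap <- center + dist * u
        phi <- runif(1, 0, 25) * pi / 180
        Hp <- Dp + 1.0 * tilted_unit(u, phi)
        dv <- dev_angle(Dp, Hp, Ap)
        if (dev_lo == 0 && dv <= dev_hi) break
        if (dev_lo > 0) {
          ## angle violator: put H far off the line
          phi <- runif(1, 55, 85) * pi / 180
          Hp <- Dp + 1.0 * tilted_unit(u, phi)
          dv <- dev_angle(Dp, Hp, Ap)
          if (dv > dev_lo && dv < 170) break
        }
      }
      Cp <- Ap + 1.24 * tilted_unit(-u, runif(1, 0, 10) * pi / 180)
      list(D = Dp, H = Hp, A = Ap, C = Cp)
    }

    kinds <- c(rep("bond", n_planted), rep("far", n_decoy_d),
               rep("bent", n_decoy_a))
    groups <- lapply(seq_len(n_tot), function(i) {
      switch(kinds[i],
        bond = make_group(centers[i, ], separation, 0, 29.0),
        far  = make_group(centers[i, ], runif(1, 3.6, 5.0), 0, 29.0),
        bent = make_group(centers[i, ], separation, 35, NA))
    })
    donors <- do.call(rbind, lapply(groups, function(g)
      data.frame(nx = g$D[1], ny = g$D[2], nz = g$D[3],
                 hx = g$H[1], hy = g$H[2], hz = g$H[3])))
    acceptors <- do.call(rbind, lapply(groups, function(g)
      data.frame(ox = g$A[1], oy = g$A[2], oz = g$A[3],
                 cx = g$C[1], cy = g$C[2], cz = g$C[3])))
    structure(list(donors = donors, acceptors = acceptors,
                   meta = list(belt = belt, n_planted = n_planted,
                               separation = separation, seed = seed)),
              class = "AtomisticFixture")
  })
}

#' Generate a synthetic first-derivative CW EPR spectrum
#'
#' Produces a nitroxide-like three-line first-derivative spectrum on a
#' uniform field grid.  Each absorption line is a Lorentzian (or optionally
#' Gaussian) of fixed double integral; the central line's derivative
#' peak-to-peak width equals `center_linewidth` by construction
#' (for a Lorentzian, peak-to-peak width = FWHM/sqrt(3)).
#'
#' @param center_linewidth peak-to-peak width of the central line, Gauss (> 0)
#' @param hyperfine_splitting spacing of the outer lines from the centre,
#'   Gauss (default 15.5, a typical nitroxide isotropic splitting)
#' @param amplitude double integral (area) of each absorption line, a.u.
#' @param noise_sd additive Gaussian noise on the derivative amplitude, a.u.
#' @param seed integer RNG seed (used only when `noise_sd > 0`)
#' @param field_center centre field, Gauss
#' @param sweep total sweep width, Gauss
#' @param step field grid step, Gauss (must resolve the linewidth)
#' @param shape "lorentzian" (default) or "gaussian"
#' @param outer_amplitude area factor for the two hyperfine satellites
#'   (default 1; 0 gives a single-line spectrum, useful for definitional
#'   width round-trips free of satellite-tail interference)
#' @return an `EPRSpectrum`: list(field, amplitude, metadata)
#' @export
gen_cw_spectrum <- function(center_linewidth, hyperfine_splitting = 15.5,
                            amplitude = 1, noise_sd = 0, seed = 1L,
                            field_center = 3350, sweep = 100, step = 0.05,
                            shape = c("lorentzian", "gaussian"),
                            outer_amplitude = 1) {
  shape <- match.arg(shape)
  if (!is.numeric(center_linewidth) || center_linewidth <= 0)
    stop("'center_linewidth' must be > 0", call. = FALSE)
  if (step > center_linewidth / 5)
    stop("field grid too coarse to resolve the linewidth (need step <= width/5)",
         call. = FALSE)
  field <- seq(field_center - sweep / 2, field_center + sweep / 2, by = step)
  centers <- field_center + c(-1, 0, 1) * hyperfine_splitting
  widthf  <- c(1.2, 1, 1.2)          # outer lines slightly broadened
  areaf   <- c(outer_amplitude, 1, outer_amplitude)
  amp <- numeric(length(field))
  for (i in 1:3) {
    if (areaf[i] == 0) next
    w <- center_linewidth * widthf[i]
    x <- field - centers[i]
    if (shape == "lorentzian") {
      g <- w * sqrt(3) / 2           # HWHM so that pp width = w
      ## derivative of area-normalised Lorentzian a/(pi) * g/(x^2+g^2)
      amp <- amp + areaf[i] * amplitude * (-2 * g * x / (pi * (x^2 + g^2)^2))
    } else {
      s <- w / 2                     # derivative extrema at +/- sigma
      amp <- amp + areaf[i] * amplitude *
        (-x / (s^3 * sqrt(2 * pi))) * exp(-x^2 / (2 * s^2))
    }
  }
  if (noise_sd > 0)
    amp <- amp + with_seed(seed, rnorm(length(amp), 0, noise_sd))
  structure(list(field = field, amplitude = amp,
                 metadata = list(center_linewidth = center_linewidth,
                                 hyperfine_splitting = hyperfine_splitting,
                                 shape = shape, noise_sd = noise_sd,
                                 seed = seed, labelling = "full")),
            class = "EPRSpectrum")
}

#' Generate a synthetic power-saturation curve
#'
#' Central-line amplitude versus microwave power following the standard
#' inhomogeneity-exponent saturation model
#' A(P) = scale * sqrt(P) / (1 + (2^(1/eps) - 1) P / p_half)^eps,
#' so that the extrapolated unsaturated amplitude is halved at `p_half`.
#'
#' @param p_half half-saturation power, mW (> 0)
#' @param eps_inhomogeneity inhomogeneity exponent (0.5 homogeneous ..
#'   1.5 inhomogeneous); default 1.5
#' @param scale amplitude scale, a.u.
#' @param noise_sd additive amplitude noise, a.u.
#' @param seed integer RNG seed
#' @param powers strictly positive ascending power grid, mW
#' @param relaxer "N2" or "NiEdda" metadata tag
#' @return a `PowerSatCurve`: list(power, amplitude, relaxer, truth)
#' @export
gen_power_sat_curve <- function(p_half = 5, eps_inhomogeneity = 1.5,
                                scale = 1, noise_sd = 0, seed = 1L,
                                powers = 0.05 * 2^seq(0, 10, by = 1 / 3),
                                relaxer = c("N2", "NiEdda")) {
  relaxer <- match.arg(relaxer)
  if (!is.numeric(p_half) || p_half <= 0)
    stop("'p_half' must be > 0", call. = FALSE)
  if (any(powers <= 0) || is.unsorted(powers, strictly = TRUE))
    stop("'powers' must be a strictly positive ascending grid", call. = FALSE)
  A <- power_sat_model(powers, p_half, eps_inhomogeneity, scale)
  if (noise_sd > 0)
    A <- A + with_seed(seed, rnorm(length(A), 0, noise_sd))
  structure(list(power = powers, amplitude = A, relaxer = relaxer,
                 truth = list(p_half = p_half, eps = eps_inhomogeneity,
                              scale = scale, noise_sd = noise_sd, seed = seed)),
            class = "PowerSatCurve")
}

## closed-form saturation model shared by generator and fitter
power_sat_model <- function(P, p_half, eps, scale) {
  scale * sqrt(P) / (1 + (2^(1 / eps) - 1) * P / p_half)^eps
}

#' Specification of synthetic closed/open mobility profiles
#'
#' Encodes the statistical structure of the per-residue mobility parameter
#' (inverse central linewidth) along the C-terminal segment: high-mobility
#' loop segments at the two ends, alpha-helical periodicity (3.6
#' residues/turn, i.e. 100 deg/residue) in the helical core, and an
#' open-state mobility increase confined to the top segment.
#'
#' @param residue_range inclusive residue interval, default c(110, 136)
#' @param loop_segments list of high-mobility intervals, default
#'   list(c(110,116), c(134,136))
#' @param helical_segment interval with periodic mobility, default c(116,131)
#' @param open_shift_segment interval where open exceeds closed, default
#'   c(110, 119)
#' @param noise_sd per-residue Gaussian noise, 1/Gauss; default 0.01
#' @param seed integer RNG seed
#' @return an `EPRProfileSpec`
#' @export
epr_profile_spec <- function(residue_range = c(110L, 136L),
                             loop_segments = list(c(110L, 116L), c(134L, 136L)),
                             helical_segment = c(116L, 131L),
                             open_shift_segment = c(110L, 119L),
                             noise_sd = 0.01, seed = 1L) {
  spec <- list(residue_range = as.integer(residue_range),
               loop_segments = lapply(loop_segments, as.integer),
               helical_segment = as.integer(helical_segment),
               open_shift_segment = as.integer(open_shift_segment),
               noise_sd = noise_sd, seed = seed)
  class(spec) <- "EPRProfileSpec"
  validate_epr_profile_spec(spec)
  spec
}

validate_epr_profile_spec <- function(spec) {
  rr <- spec$residue_range
  inside <- function(seg) seg[1] >= rr[1] && seg[2] <= rr[2] && seg[1] <= seg[2]
  segs <- c(spec$loop_segments, list(spec$helical_segment,
                                     spec$open_shift_segment))
  if (!all(vapply(segs, inside, logical(1))))
    stop("all segments must lie within residue_range", call. = FALSE)
  if (length(spec$loop_segments) >= 2) {
    for (i in seq_along(spec$loop_segments))
      for (j in seq_along(spec$loop_segments))
        if (i < j) {
          a <- spec$loop_segments[[i]]; b <- spec$loop_segments[[j]]
          if (a[1] <= b[2] && b[1] <= a[2])
            stop("overlapping contradictory loop segments", call. = FALSE)
        }
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(spec)
}

#' Generate matched closed/open per-residue mobility profiles
#'
#' The closed profile has a 0.20 1/G baseline, elevated (+0.25) loop
#' segments, and a 0.05-amplitude cosine with period 3.6 residues
#' (100 deg/residue) across the helical segment.  The open profile equals
#' the closed profile plus a +0.08 1/G shift confined to
#' `open_shift_segment`.  Independent Gaussian noise of sd `noise_sd` is
#' added to each profile.
#'
#' @param spec an [epr_profile_spec()]
#' @return list(closed = MobilityProfile, open = MobilityProfile)
#' @export
gen_mobility_profiles <- function(spec) {
  validate_epr_profile_spec(spec)
  res <- seq(spec$residue_range[1], spec$residue_range[2])
  base <- rep(0.20, length(res))
  for (seg in spec$loop_segments)
    base[res >= seg[1] & res <= seg[2]] <- base[res >= seg[1] & res <= seg[2]] + 0.25
  hs <- spec$helical_segment
  inh <- res >= hs[1] & res <= hs[2]
  base[inh] <- base[inh] + 0.05 * cos(2 * pi * (res[inh] - hs[1]) / 3.6)
  shift <- numeric(length(res))
  os <- spec$open_shift_segment
  shift[res >= os[1] & res <= os[2]] <- 0.08
  with_seed(spec$seed, {
    closed <- base + if (spec$noise_sd > 0) rnorm(length(res), 0, spec$noise_sd) else 0
    open   <- base + shift +
      if (spec$noise_sd > 0) rnorm(length(res), 0, spec$noise_sd) else 0
    list(closed = mobility_profile(res, closed, "closed"),
         open   = mobility_profile(res, open, "open"))
  })
}

#' Construct a per-residue mobility profile
#'
#' @param residue integer residue numbers (unique, sorted)
#' @param value mobility parameter values, 1/Gauss (> 0)
#' @param state "closed" or "open"
#' @return a `MobilityProfile`
#' @export
mobility_profile <- function(residue, value, state = c("closed", "open")) {
  state <- match.arg(state)
  if (anyDuplicated(residue) || is.unsorted(residue))
    stop("residues must be unique and sorted", call. = FALSE)
  if (length(residue) != length(value))
    stop("residue/value length mismatch", call. = FALSE)
  if (any(value <= 0))
    stop("mobility values must be > 0", call. = FALSE)
  structure(list(residue = as.integer(residue), value = as.numeric(value),
                 state = state), class = "MobilityProfile")
}
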