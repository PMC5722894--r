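#' Physical environment for interaction models
#'
#' Presets: `vacuum` (eps_r 1, no ions, no water-mediated hydrogen bonding),
#' `water` (eps_r 78.5, no ions) and `salt-water` (eps_r 78.5, 0.3 M KCl),
#' all at 298 K.
#'
#' @param name one of "vacuum", "water", "salt-water"
#' @param relative_permittivity override eps_r
#' @param ionic_strength override ionic strength, mol/L
#' @param temperature override temperature, K
#' @param hbond_water_mediated override the top-belt water bridge switch
#' @return an `Environment`
#' @export
environment_preset <- function(name = c("salt-water", "water", "vacuum"),
                               relative_permittivity = NULL,
                               ionic_strength = NULL,
                               temperature = 298,
                               hbond_water_mediated = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    "vacuum"     = list(eps = 1,    I = 0,   hb = FALSE),
    "water"      = list(eps = 78.5, I = 0,   hb = TRUE),
    "salt-water" = list(eps = 78.5, I = 0.3, hb = TRUE))
  env <- list(name = name,
              relative_permittivity = relative_permittivity %||% defaults$eps,
              ionic_strength = ionic_strength %||% defaults$I,
              temperature = temperature,
              hbond_water_mediated = hbond_water_mediated %||% defaults$hb)
  if (env$relative_permittivity < 1) stop("permittivity must be >= 1", call. = FALSE)
  if (env$ionic_strength < 0) stop("ionic strength must be >= 0", call. = FALSE)
  if (env$name == "vacuum" && (env$ionic_strength != 0 || env$hbond_water_mediated))
    stop("vacuum implies zero ionic strength and no water-mediated H-bonds",
         call. = FALSE)
  class(env) <- "Environment"
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse Debye screening length
#'
#' kappa = sqrt(2 N_A e^2 I / (eps0 eps_r k_B T)) with the ionic strength
#' converted to mol/m^3; returns 1/nm.  kappa = 0 for zero ionic strength.
#'
#' @param env an [environment_preset()]
#' @return inverse screening length, 1/nm
#' @examples
#' debye_kappa(environment_preset("salt-water"))  # ~1.80 nm^-1
#' @export
debye_kappa <- function(env) {
  if (env$temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  I_m3 <- env$ionic_strength * 1000
  k2 <- 2 * .const$N_A * .const$e_C^2 * I_m3 /
    (.const$eps0 * env$relative_permittivity * .const$k_B * env$temperature)
  sqrt(k2) * 1e-9
}

#' Screened Coulomb pair energy
#'
#' U(r) = 332.06 q1 q2 / (eps_r r) * exp(-kappa r) in kcal/mol, with r in
#' Angstrom and charges in elementary units; reduces to the bare Coulomb
#' energy when kappa = 0.
#'
#' @param q1,q2 charges, e
#' @param r separation, Angstrom (> 0)
#' @param env an [environment_preset()]
#' @return energy, kcal/mol
#' @export
screened_coulomb_energy <- function(q1, q2, r, env) {
  if (any(r <= 0)) stop("separation must be > 0", call. = FALSE)
  kA <- debye_kappa(env) / 10          # 1/nm -> 1/Angstrom
  .const$coulomb_kcalA * q1 * q2 / (env$relative_permittivity * r) * exp(-kA * r)
}

#' DSSP electrostatic hydrogen-bond energy
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol for a
#' backbone-style donor group (N, H) and acceptor group (C=O); a hydrogen
#' bond is conventionally assigned when E < -0.5 kcal/mol.
#'
#' @param n_xyz,h_xyz,c_xyz,o_xyz numeric length-3 coordinates, Angstrom
#' @return energy, kcal/mol
#' @export
dssp_hbond_energy <- function(n_xyz, h_xyz, c_xyz, o_xyz) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  pts <- list(n_xyz, h_xyz, c_xyz, o_xyz)
  for (i in 1:3) for (j in (i + 1):4)
    if (d(pts[[i]], pts[[j]]) < 1e-6)
      stop("coincident points in hydrogen-bond geometry", call. = FALSE)
  r <- c(ON = d(o_xyz, n_xyz), CH = d(c_xyz, h_xyz),
         OH = d(o_xyz, h_xyz), CN = d(c_xyz, n_xyz))
  0.084 * 332 * (1 / r[["ON"]] + 1 / r[["CH"]] - 1 / r[["OH"]] - 1 / r[["CN"]])
}

#' DSSP energy of the canonical linear hydrogen bond
#'
#' Reference geometry: r_ON = 2.9 A with H on the N-O line 1.0 A from N and
#' the carbonyl C 1.24 A behind O on the same line.  Used to calibrate the
#' depth of the belt hydrogen-bond wells.
#' @return energy, kcal/mol (about -2.92)
#' @export
canonical_hbond_energy <- function() {
  n <- c(0, 0, 0); h <- c(1.0, 0, 0); o <- c(2.9, 0, 0); cc <- c(4.14, 0, 0)
  dssp_hbond_energy(n, h, cc, o)
}

## Morse well: U(r) = De ((1 - exp(-a (r - r0)))^2 - 1); U(r0) = -De, U(inf) = 0
morse_energy <- function(r, De, a, r0) De * ((1 - exp(-a * (r - r0)))^2 - 1)
morse_force  <- function(r, De, a, r0) {
  ## -dU/dr
  e <- exp(-a * (r - r0))
  -2 * De * a * e * (1 - e)
}

## smooth effective charge-centre distance: r_eff ~ r - delta, floored
## smoothly at r_min (softplus, sharpness beta)
smooth_reff <- function(r, delta, r_min = 2.0, beta = 2.0) {
  r_min + log1p(exp(beta * (r - delta - r_min))) / beta
}
smooth_reff_d <- function(r, delta, r_min = 2.0, beta = 2.0) {
  plogis(beta * (r - delta - r_min))
}

## Belt interaction energy models -------------------------------------------
##
## Each belt's interface energy is expressed as a function of a single
## separation coordinate r (the site-to-site distance):
##  * middle: sum of screened-Coulomb terms over the charge pairs
##    E124-R126 and D127-R126 of adjacent subunits, each evaluated at the
##    side-chain charge-centre distance r_eff = r - (offset_a + offset_b)
##    (smoothly floored at 2 A);
##  * top: water-mediated hydrogen-bond well (Morse, depth = |canonical DSSP
##    energy|, width parameter 0.5 1/A -- a water bridge is long-range and
##    soft), active only when the environment supports water-mediated
##    bonding;
##  * bottom: direct hydrogen-bond well (Morse, DSSP-calibrated depth, width
##    parameter 2.0 1/A).
middle_pairs <- function(belts) {
  list(c("E124", "R126"), c("D127", "R126"))
}

res_charge <- function(belts, lab) {
  belts$charges[[substr(lab, 1, 1)]]
}
res_offset <- function(belts, lab) {
  belts$charge_offsets[[substr(lab, 1, 1)]]
}

#' Belt interface energy model
#'
#' @param belt "top", "middle" or "bottom"
#' @param r separation coordinate(s), Angstrom
#' @param env an [environment_preset()]
#' @param belts a [belt_spec()]
#' @param r0 reference (closed-state) separation for the hydrogen-bond wells
#' @param pair optional character(2): restrict the middle-belt sum to one
#'   charge pair
#' @return energy, kcal/mol
#' @export
belt_energy <- function(belt, r, env, belts = belt_spec(), r0 = NULL,
                        pair = NULL) {
  switch(belt,
    middle = {
      pairs <- if (is.null(pair)) middle_pairs(belts) else list(pair)
      kA <- debye_kappa(env) / 10
      Reduce(`+`, lapply(pairs, function(p) {
        delta <- res_offset(belts, p[1]) + res_offset(belts, p[2])
        q <- res_charge(belts, p[1]) * res_charge(belts, p[2])
        re <- smooth_reff(r, delta)
        .const$coulomb_kcalA * q / (env$relative_permittivity * re) * exp(-kA * re)
      }))
    },
    top = {
      if (!env$hbond_water_mediated) return(r * 0)
      De <- abs(canonical_hbond_energy())
      morse_energy(r, De, 0.5, r0)
    },
    bottom = {
      De <- abs(canonical_hbond_energy())
      morse_energy(r, De, 2.0, r0)
    },
    stop("unknown belt '", belt, "'", call. = FALSE))
}

## analytic -dU/dr of belt_energy
belt_force <- function(belt, r, env, belts = belt_spec(), r0 = NULL,
                       pair = NULL) {
  switch(belt,
    middle = {
      pairs <- if (is.null(pair)) middle_pairs(belts) else list(pair)
      kA <- debye_kappa(env) / 10
      Reduce(`+`, lapply(pairs, function(p) {
        delta <- res_offset(belts, p[1]) + res_offset(belts, p[2])
        q <- res_charge(belts, p[1]) * res_charge(belts, p[2])
        re <- smooth_reff(r, delta)
        dre <- smooth_reff_d(r, delta)
        U <- .const$coulomb_kcalA * q / (env$relative_permittivity * re) * exp(-kA * re)
        U * (1 / re + kA) * dre            # -dU/dr = -(dU/dre)*(dre/dr)
      }))
    },
    top = {
      if (!env$hbond_water_mediated) return(r * 0)
      De <- abs(canonical_hbond_energy())
      morse_force(r, De, 0.5, r0)
    },
    bottom = {
      De <- abs(canonical_hbond_energy())
      morse_force(r, De, 2.0, r0)
    },
    stop("unknown belt '", belt, "'", call. = FALSE))
}

#' Build a nonlinear connector force-displacement table for a belt
#'
#' Tabulates force(r) = -dU/dr of the belt's interface energy model on a
#' separation grid (negative force = attractive).  The reference separation
#' r0 is taken from the mean adjacent-subunit site distance in `sites`.
#'
#' @param belt "top", "middle" or "bottom"
#' @param belts a [belt_spec()]
#' @param sites belt site map (e.g. `geom$belt_sites`)
#' @param env an [environment_preset()]
#' @param grid separation grid, Angstrom, strictly increasing and positive;
#'   default spans 0.5 r0 .. 3 r0 with 49 points
#' @param pair optional middle-belt charge pair restriction
#' @return a `ForceDisplacementTable`: list(belt, grid, force, r0, env,
#'   model, energy) where `energy` is the analytic energy closure
#' @export
build_connector_table <- function(belt, belts, sites, env, grid = NULL,
                                  pair = NULL) {
  if (!belt %in% c("top", "middle", "bottom"))
    stop("unknown belt '", belt, "'", call. = FALSE)
  bs <- sites[[belt]]
  if (is.null(bs) || nrow(bs) == 0)
    stop("no sites for belt '", belt, "'", call. = FALSE)
  r0 <- mean_adjacent_separation(bs, pair = pair)
  ## 0.05 A spacing keeps trapezoidal force->energy integration of the
  ## sharpest well (bottom belt, alpha = 2/A) below 0.5% error
  if (is.null(grid)) grid <- seq(0.5 * r0, 3 * r0, by = 0.05)
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing and positive", call. = FALSE)
  en <- function(r) belt_energy(belt, r, env, belts, r0 = r0, pair = pair)
  fo <- belt_force(belt, grid, env, belts, r0 = r0, pair = pair)
  structure(list(belt = belt, grid = grid, force = fo, r0 = r0,
                 env = env$name, model = if (belt == "middle")
                   "screened-coulomb" else "dssp-morse",
                 pair = pair, energy = en),
            class = "ForceDisplacementTable")
}

## mean site-to-site distance over adjacent subunit pairs; for a cross pair
## (labels a, b) uses a_i -> b_{i+1}, otherwise same-label neighbours
mean_adjacent_separation <- function(bs, pair = NULL) {
  n <- max(bs$subunit)
  labs <- unique(bs$label)
  pick <- function(s, lab) {
    row <- bs[bs$subunit == s & bs$label == lab, ]
    c(row$x[1], row$y[1], row$z[1])
  }
  d <- c()
  if (!is.null(pair)) {
    for (s in seq_len(n)) {
      s2 <- s %% n + 1
      d <- c(d, sqrt(sum((pick(s, pair[1]) - pick(s2, pair[2]))^2)))
    }
  } else {
    for (lab in labs) for (s in seq_len(n)) {
      s2 <- s %% n + 1
      d <- c(d, sqrt(sum((pick(s, lab) - pick(s2, lab))^2)))
    }
  }
  mean(d)
}

#' Interpolate a connector table
#'
#' Piecewise-linear in force between grid points; zero force beyond the grid
#' maximum (screened/well decay); clamped to the first value below the grid
#' minimum.
#'
#' @param table a [build_connector_table()] result
#' @param r separation(s), Angstrom
#' @return force, kcal/(mol Angstrom)
#' @export
table_force <- function(table, r) {
  g <- table$grid; f <- table$force
  out <- approx(g, f, xout = pmin(pmax(r, g[1]), g[length(g)]),
                rule = 2)$y
  out[r > g[length(g)]] <- 0
  out
}

#' Export a connector table as CSV
#' @param table a `ForceDisplacementTable`
#' @param path output file
#' @return the path, invisibly
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(data.frame(separation_A = table$grid, force = table$force),
                   path, row.names = FALSE)
  invisible(path)
}
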