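#' Material parameter set for the channel model
#'
#' Defaults are the published coarse-grained values: helix Young's moduli
#' N-term 0.35 GPa, TM1 2.6 GPa, TM2 3.4 GPa, C-term 7.7 GPa (from steered
#' MD); helix Poisson ratio 0.48 (almost incompressible); bilayer Young's
#' modulus 4.3 MPa (patch fluorometry).  The bilayer transverse contraction
#' ratio is not published; the default 0.1 reflects that the patch-scale
#' softness of the bilayer is mostly undulational and carries little
#' thickness change (see the methods vignette).
#'
#' @param young_modulus named vector of helix moduli, Pa
#' @param poisson_ratio helix Poisson ratio (0 <= nu < 0.5)
#' @param bilayer_young_modulus bilayer modulus, Pa
#' @param bilayer_poisson bilayer transverse contraction ratio
#' @return a `MaterialSet`
#' @export
material_set <- function(young_modulus = c(`N-term` = 0.35e9, TM1 = 2.6e9,
                                           TM2 = 3.4e9, `C-term` = 7.7e9),
                         poisson_ratio = 0.48,
                         bilayer_young_modulus = 4.3e6,
                         bilayer_poisson = 0.1) {
  if (any(young_modulus <= 0) || bilayer_young_modulus <= 0)
    stop("moduli must be > 0", call. = FALSE)
  for (nu in c(poisson_ratio, bilayer_poisson))
    if (nu < 0 || nu >= 0.5)
      stop("Poisson ratios must satisfy 0 <= nu < 0.5", call. = FALSE)
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio,
                 bilayer_young_modulus = bilayer_young_modulus,
                 bilayer_poisson = bilayer_poisson), class = "MaterialSet")
}

#' Calibrate the transmembrane wall contact stiffness
#'
#' The beam idealisation loses the hoop continuity of the transmembrane
#' helix wall, so adjacent TM2 rods are coupled by elastic "wall" springs.
#' Their stiffness is fixed, in closed form, by requiring that the radial
#' expansion of the wall under the gating tension equal the field-consensus
#' in-plane protein area expansion of MscL gating (default 20 nm^2 from
#' electrophysiological Boltzmann analyses), balanced against the analytic
#' radial compliance of the annular bilayer plate.  This anchors the wall to
#' an independent experimental quantity instead of tuning it.
#'
#' @param plate plate definition from a `CoarseGeometry`
#' @param materials a [material_set()]
#' @param n_subunits number of subunits
#' @param gating_tension tension at which the expansion is anchored, mN/m
#' @param area_expansion_nm2 in-plane protein area expansion at gating, nm^2
#' @return list(k_wall, delta_r, u_free): spring stiffness
#'   (kcal/(mol A^2)) and the anchor displacements (A)
#' @export
calibrate_wall_stiffness <- function(plate, materials, n_subunits = 5L,
                                     gating_tension = 9.5,
                                     area_expansion_nm2 = 20) {
  a <- plate$inner_radius; b <- plate$extent; t <- plate$thickness
  E <- pa_to_internal(materials$bilayer_young_modulus)
  nu <- materials$bilayer_poisson
  sigma <- tension_to_internal(gating_tension) / t
  u_free <- 2 * sigma * a * b^2 / (E * (b^2 - a^2))
  k_mem <- E / (a * ((a^2 + b^2) / (b^2 - a^2) + nu))   # rim pressure per u
  Rp <- plate$footprint_radius %||% (a - 2.75)
  dR <- sqrt(Rp^2 + area_expansion_nm2 * 100 / pi) - Rp
  n <- n_subunits
  if (u_free <= dR) return(list(k_wall = 0, delta_r = dR, u_free = u_free))
  k_w <- t * (2 * pi * a / n) * k_mem * (u_free - dR) /
    (4 * sin(pi / n)^2 * dR)
  list(k_wall = k_w, delta_r = dR, u_free = u_free)
}

#' Numerically calibrate the wall stiffness against the assembled model
#'
#' The closed-form [calibrate_wall_stiffness()] balances the wall ring
#' against the bilayer alone; the assembled model adds the belt connectors
#' and covalent linkers, which stiffen the protein side.  This routine
#' solves the full model at the gating tension and adjusts the wall spring
#' constant (secant iteration) until the radial expansion of the
#' channel/bilayer interface equals the same independent anchor, the
#' field-consensus gating area expansion (default 20 nm^2).  Calibration is
#' always performed in the physiological salt-water environment; the
#' resulting stiffness describes the protein wall and is reused unchanged in
#' the other environments.
#'
#' @inheritParams calibrate_wall_stiffness
#' @param geometry a `CoarseGeometry`
#' @param rel_tol relative tolerance on the anchor displacement
#' @param max_iter secant iterations
#' @return list(k_wall, delta_r, achieved, iterations)
#' @export
calibrate_wall_numeric <- function(geometry, materials,
                                   gating_tension = 9.5,
                                   area_expansion_nm2 = 20,
                                   rel_tol = 0.02, max_iter = 10L) {
  env <- environment_preset("salt-water")
  belts <- belt_spec()
  tables <- lapply(c(top = "top", middle = "middle", bottom = "bottom"),
                   function(b) build_connector_table(b, belts,
                                                     geometry$belt_sites, env))
  cal0 <- calibrate_wall_stiffness(geometry$plate, materials,
                                   length(unique(geometry$rods$subunit)),
                                   gating_tension, area_expansion_nm2)
  dR <- cal0$delta_r
  rim_u <- function(k) {
    m <- assemble(geometry, materials, tables, env,
                  wall = list(enable = TRUE, k_wall = k,
                              gating_tension = gating_tension,
                              area_expansion_nm2 = area_expansion_nm2))
    s <- solve_tension(m, gating_tension, n_increments = 10L, tol = 1e-6)
    wall_expansion(m, s)
  }
  ## u(k) is monotone decreasing; a failed (diverged) solve means the wall
  ## was too soft and counts as u = +Inf
  safe_u <- function(k) tryCatch({
    v <- rim_u(k); if (is.finite(v)) v else Inf
  }, error = function(e) Inf)
  k_hi <- max(cal0$k_wall, 1e-3)
  u_hi <- safe_u(k_hi); it <- 1L
  while (u_hi > dR && it < max_iter) {      # too soft: stiffen
    k_hi <- 4 * k_hi; u_hi <- safe_u(k_hi); it <- it + 1L
  }
  k_lo <- k_hi; u_lo <- u_hi
  while (u_lo < dR && it < max_iter) {      # too stiff: soften
    k_lo <- k_lo / 4; u_lo <- safe_u(k_lo); it <- it + 1L
  }
  ## bisection in log k on the bracket [k_lo (u >= dR), k_hi (u <= dR)]
  k_mid <- sqrt(k_lo * k_hi); u_mid <- safe_u(k_mid); it <- it + 1L
  while (abs(u_mid - dR) > rel_tol * dR && it < max_iter + 8L) {
    if (u_mid > dR) k_lo <- k_mid else k_hi <- k_mid
    k_mid <- sqrt(k_lo * k_hi); u_mid <- safe_u(k_mid); it <- it + 1L
  }
  list(k_wall = k_mid, delta_r = dR, achieved = u_mid, iterations = it)
}

#' Radial expansion of the transmembrane wall
#'
#' Mean radial displacement of the TM2 mid-membrane nodes (the wall ring the
#' contact springs act on); the quantity the gating area-expansion anchor
#' constrains.
#'
#' @param model solved `MechModel`
#' @param sol `MechSolution`
#' @return mean radial displacement, Angstrom
#' @export
wall_expansion <- function(model, sol) {
  rods <- model$meta$rods
  tm2 <- which(rods$role == "TM2")
  mean(vapply(tm2, function(k) {
    ids <- model$meta$rod_nodes[[k]]
    nd <- ids[which.min(abs(model$nodes[ids, 3]))]
    p <- model$nodes[nd, 1:2]
    sum(sol$displacements[nd, 1:2] * p / sqrt(sum(p^2)))
  }, numeric(1)))
}

## ---- meshing ---------------------------------------------------------------

## annular plate mesh in the z = z0 plane; returns nodes and CCW triangles
mesh_annulus <- function(a, b, z0 = 0, n_rings = 10L, n_sectors = 40L) {
  if (a <= 0 || b <= a) stop("mesh generation failure: need 0 < a < b",
                             call. = FALSE)
  radii <- a * (b / a)^(seq(0, 1, length.out = n_rings + 1L))
  th <- 2 * pi * (seq_len(n_sectors) - 1L) / n_sectors
  nodes <- do.call(rbind, lapply(radii, function(r)
    cbind(r * cos(th), r * sin(th), z0)))
  id <- function(i, j) i * n_sectors + ((j - 1L) %% n_sectors) + 1L
  tris <- list()
  for (i in 0:(n_rings - 1L)) for (j in seq_len(n_sectors)) {
    A <- id(i, j); B <- id(i + 1L, j); C <- id(i + 1L, j + 1L); D <- id(i, j + 1L)
    tris[[length(tris) + 1L]] <- c(A, B, C)
    tris[[length(tris) + 1L]] <- c(A, C, D)
  }
  list(nodes = nodes, tris = tris,
       inner_ids = id(0L, seq_len(n_sectors)),
       outer_ids = id(n_rings, seq_len(n_sectors)),
       radii = radii, n_sectors = n_sectors)
}

## ---- channel model assembly ------------------------------------------------

#' Assemble the coarse channel model
#'
#' Discretizes every rod into beam elements, meshes the bilayer as an
#' annular Mindlin plate with a central opening matched to the transmembrane
#' rod footprint, ties the plate to the TM2 rods, the N-terminal rods and
#' the head of TM1 (rigid translational coupling to the nearest plate node),
#' joins consecutive rods of each subunit with short covalent linker beams,
#' attaches the three belt connector tables between adjacent subunits, and
#' adds the calibrated wall contact springs between adjacent TM2 rods.
#'
#' @param geometry a `CoarseGeometry`
#' @param materials a [material_set()]
#' @param tables named list with elements `top`, `middle`, `bottom`
#'   (each a [build_connector_table()] result)
#' @param env an [environment_preset()]
#' @param n_el_per_rod beam elements per rod (>= 4)
#' @param plate_rings,plate_sectors plate mesh resolution (sectors should be
#'   a multiple of the symmetry order)
#' @param formulation beam formulation
#' @param wall list(enable, gating_tension, area_expansion_nm2) controlling
#'   the wall contact springs
#' @return a `MechModel` with channel metadata in `$meta`
#' @export
assemble <- function(geometry, materials, tables, env,
                     n_el_per_rod = 5L, plate_rings = 10L, plate_sectors = 40L,
                     formulation = c("timoshenko", "euler"),
                     wall = list(enable = TRUE, gating_tension = 9.5,
                                 area_expansion_nm2 = 20)) {
  formulation <- match.arg(formulation)
  validate_coarse_geometry(geometry)
  for (b in c("top", "middle", "bottom"))
    if (is.null(tables[[b]]))
      stop("no connector table supplied for belt '", b, "'", call. = FALSE)
  if (n_el_per_rod < 4) stop("need >= 4 beam elements per rod", call. = FALSE)

  rods <- geometry$rods
  plate <- geometry$plate
  hz <- plate$thickness / 2

  ## rod nodes
  node_list <- list(); rod_nodes <- list()
  nid <- 0L
  for (k in seq_len(nrow(rods))) {
    s <- as.numeric(rods[k, c("sx", "sy", "sz")])
    e <- as.numeric(rods[k, c("ex", "ey", "ez")])
    tt <- seq(0, 1, length.out = n_el_per_rod + 1L)
    pts <- outer(1 - tt, s) + outer(tt, e)
    ids <- nid + seq_len(nrow(pts))
    nid <- nid + nrow(pts)
    node_list[[k]] <- pts
    rod_nodes[[k]] <- ids
  }
  rod_node_mat <- do.call(rbind, node_list)
  n_rod_nodes <- nrow(rod_node_mat)

  ## plate mesh appended after rod nodes
  msh <- mesh_annulus(plate$inner_radius, plate$extent, plate$z,
                      plate_rings, plate_sectors)
  nodes <- rbind(rod_node_mat, msh$nodes)
  plate_off <- n_rod_nodes

  model <- fe_new_model(nodes)
  E_int <- pa_to_internal(materials$young_modulus)
  nu_r <- materials$poisson_ratio
  Eb <- pa_to_internal(materials$bilayer_young_modulus)
  nub <- materials$bilayer_poisson

  ## beams along each rod
  n_beam <- 0L
  for (k in seq_len(nrow(rods))) {
    ids <- rod_nodes[[k]]
    Ei <- E_int[[rods$role[k]]]
    for (i in seq_len(length(ids) - 1L)) {
      model <- fe_add_beam(model, ids[i], ids[i + 1L], Ei, nu_r,
                           rods$radius[k], formulation,
                           tag = paste0(rods$role[k], ":", rods$subunit[k]))
      n_beam <- n_beam + 1L
    }
  }

  ## covalent linkers between consecutive rods of a subunit
  rod_row <- function(role, s) which(rods$role == role & rods$subunit == s)
  end_node <- function(k, which_end)
    rod_nodes[[k]][if (which_end == "start") 1L else length(rod_nodes[[k]])]
  link_def <- list(c("N-term", "start", "TM1", "start"),
                   c("TM1", "end", "TM2", "end"),
                   c("TM2", "start", "C-term", "start"))
  for (s in unique(rods$subunit)) for (ld in link_def) {
    k1 <- rod_row(ld[1], s); k2 <- rod_row(ld[3], s)
    if (!length(k1) || !length(k2)) next
    Eln <- mean(c(E_int[[ld[1]]], E_int[[ld[3]]]))
    model <- fe_add_beam(model, end_node(k1, ld[2]), end_node(k2, ld[4]),
                         Eln, nu_r, 2.5, formulation,
                         tag = paste0("linker:", s))
    n_beam <- n_beam + 1L
  }

  ## plate triangles
  for (tr in msh$tris)
    model <- fe_add_tri(model, plate_off + tr[1], plate_off + tr[2],
                        plate_off + tr[3], Eb, nub, plate$thickness)

  ## outer rim: suppress vertical motion and tangential drift (radial free)
  k_pen <- 1e4 * Eb * plate$thickness
  for (j in msh$outer_ids) {
    nd <- plate_off + j
    model <- fe_fix(model, nd, 3L)
    xy <- nodes[nd, 1:2]
    tang <- c(-xy[2], xy[1], 0) / sqrt(sum(xy^2))
    model <- fe_penalty(model, nd, tang, k_pen)
  }

  ## ties: rod nodes -> nearest plate node (translations)
  plate_ids <- plate_off + seq_len(nrow(msh$nodes))
  nearest_plate <- function(p) {
    d2 <- (nodes[plate_ids, 1] - p[1])^2 + (nodes[plate_ids, 2] - p[2])^2 +
      (nodes[plate_ids, 3] - p[3])^2
    plate_ids[which.min(d2)]
  }
  n_tied <- 0L
  for (k in seq_len(nrow(rods))) {
    locus <- geometry$tie_pairs$locus[match(rods$role[k],
                                            geometry$tie_pairs$role)]
    if (is.na(locus)) next
    ids <- rod_nodes[[k]]
    pick <- switch(locus,
      all  = ids,
      span = ids[abs(nodes[ids, 3]) <= hz + 1],
      head = ids[length(ids)],
      integer(0))
    for (nd in pick) {
      model <- fe_tie(model, nd, nearest_plate(nodes[nd, ]))
      n_tied <- n_tied + 1L
    }
  }

  ## belt connectors between adjacent subunits
  subs <- sort(unique(rods$subunit)); nsub <- length(subs)
  site_attach <- function(bs_row) {
    k <- rod_row("C-term", bs_row$subunit)
    ids <- rod_nodes[[k]]
    p <- c(bs_row$x, bs_row$y, bs_row$z)
    d2 <- rowSums((nodes[ids, , drop = FALSE] -
                     matrix(p, length(ids), 3, byrow = TRUE))^2)
    nd <- ids[which.min(d2)]
    list(node = nd, offset = p - nodes[nd, ])
  }
  belt_pairs <- list(top = c("E118", "E118"), middle = c("E124", "R126"),
                     bottom = c("R135", "S136"))
  belt_conn_idx <- list(top = integer(0), middle = integer(0),
                        bottom = integer(0))
  for (b in names(belt_pairs)) {
    bs <- geometry$belt_sites[[b]]
    pr <- belt_pairs[[b]]
    for (s in subs) {
      s2 <- s %% nsub + 1L
      r1 <- bs[bs$subunit == s & bs$label == pr[1], ]
      r2 <- bs[bs$subunit == s2 & bs$label == pr[2], ]
      if (nrow(r1) == 0 || nrow(r2) == 0)
        stop("belt sites missing for belt '", b, "'", call. = FALSE)
      model <- fe_add_connector(model, site_attach(r1[1, ]),
                                site_attach(r2[1, ]),
                                table = tables[[b]], tag = b)
      belt_conn_idx[[b]] <- c(belt_conn_idx[[b]], length(model$connectors))
    }
  }

  ## wall contact springs between adjacent TM2 rods at membrane mid-height
  wall_k <- 0
  if (isTRUE(wall$enable)) {
    wall_k <- wall$k_wall %||%
      calibrate_wall_stiffness(plate, materials, nsub,
                               wall$gating_tension %||% 9.5,
                               wall$area_expansion_nm2 %||% 20)$k_wall
    mid_node <- function(s) {
      ids <- rod_nodes[[rod_row("TM2", s)]]
      ids[which.min(abs(nodes[ids, 3]))]
    }
    for (s in subs) {
      s2 <- s %% nsub + 1L
      model <- fe_add_connector(model,
                                list(node = mid_node(s), offset = c(0, 0, 0)),
                                list(node = mid_node(s2), offset = c(0, 0, 0)),
                                k = wall_k, tag = "wall")
    }
  }

  idx <- dof_index(model)
  n_nodes <- nrow(nodes)
  model$meta <- list(
    geometry = geometry, materials = materials, env = env$name,
    rods = rods, rod_nodes = rod_nodes,
    plate_ids = plate_ids, plate_off = plate_off, mesh = msh,
    belt_conn_idx = belt_conn_idx, wall_k = wall_k,
    n_beam_elements = n_beam, n_plate_elements = length(msh$tris),
    n_subunits = nsub,
    dof = list(n_total = 6L * n_nodes,
               n_constrained = 3L * n_tied + length(model$fixed),
               n_free = length(unique(as.vector(idx))) -
                 length(intersect(model$fixed, as.vector(idx)))))
  model
}

#' Solve the channel model under membrane tension
#'
#' Applies the tension as an outward in-plane edge traction on the plate's
#' outer rim and runs the incremental Newton solution.
#'
#' @param model an [assemble()]d `MechModel`
#' @param tension membrane tension, mN/m (>= 0)
#' @param n_increments load increments
#' @param tol relative residual tolerance
#' @param trace print convergence
#' @return a `MechSolution` (see [fe_solve()])
#' @export
solve_tension <- function(model, tension, n_increments = 20L, tol = 1e-8,
                          trace = FALSE) {
  if (!is.numeric(tension) || tension < 0)
    stop("'tension' must be >= 0", call. = FALSE)
  msh <- model$meta$mesh
  gam <- tension_to_internal(tension)
  b <- max(msh$radii)
  arc <- 2 * pi * b / msh$n_sectors
  model$loads <- numeric(6L * nrow(model$nodes))
  for (j in msh$outer_ids) {
    nd <- model$meta$plate_off + j
    xy <- model$nodes[nd, 1:2]
    rad <- c(xy / sqrt(sum(xy^2)), 0)
    model <- fe_load(model, nd, gam * arc * rad)
  }
  sol <- fe_solve(model, n_increments = n_increments, tol = tol, trace = trace)
  sol$tension <- tension
  sol$model_loads <- model$loads     # the load vector actually applied
  sol
}

#' Path energy balance of a converged solution
#'
#' Trapezoidal external + connector work along the load path compared with
#' the stored linear-elastic energy; used as a solver consistency check.
#'
#' @param model the solved `MechModel`
#' @param sol its `MechSolution`
#' @return list(work, elastic, rel_gap)
#' @export
solution_energy_balance <- function(model, sol) {
  idx <- sol$idx
  K <- assemble_linear(model)
  loads <- sol$model_loads %||% model$loads
  c0 <- conn_eval(model, idx, numeric(length(sol$u)), want_tangent = FALSE)
  us <- c(list(numeric(length(sol$u))),
          lapply(sol$increments, `[[`, "u"))
  lam <- c(0, vapply(sol$increments, `[[`, numeric(1), "lambda"))
  W <- 0
  for (i in seq_len(length(us) - 1L)) {
    du <- us[[i + 1L]] - us[[i]]
    F1 <- lam[i] * loads +
      conn_eval(model, idx, us[[i]], want_tangent = FALSE)$F - c0$F
    F2 <- lam[i + 1L] * loads +
      conn_eval(model, idx, us[[i + 1L]], want_tangent = FALSE)$F - c0$F
    W <- W + sum((F1 + F2) / 2 * du)
  }
  u <- sol$u
  elastic <- 0.5 * sum(u * as.numeric(K %*% u))
  list(work = W, elastic = elastic,
       rel_gap = abs(W - elastic) / max(abs(elastic), 1e-12))
}
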