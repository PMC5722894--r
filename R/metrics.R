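## Structural readouts from geometries and solved models.

## deformed node positions for a rod (reference + solution displacement)
rod_polyline <- function(model, sol, k) {
  ids <- model$meta$rod_nodes[[k]]
  P <- model$nodes[ids, , drop = FALSE]
  if (!is.null(sol)) P <- P + sol$displacements[ids, , drop = FALSE]
  P
}

## interpolate a polyline at height z (first crossing); NA if outside
polyline_at_z <- function(P, z) {
  for (i in seq_len(nrow(P) - 1L)) {
    z1 <- P[i, 3]; z2 <- P[i + 1L, 3]
    if ((z1 - z) * (z2 - z) <= 0 && z1 != z2) {
      t <- (z - z1) / (z2 - z1)
      return(P[i, ] + t * (P[i + 1L, ] - P[i, ]))
    }
  }
  c(NA_real_, NA_real_, NA_real_)
}

#' Pore diameter from the TM1 rods
#'
#' D = 2 (min over z in the transmembrane region of the distance from the
#' pore axis to the nearest TM1 rod axis at that height, minus the rod
#' radius).  The pore axis is the vertical axis through the centroid of the
#' TM1 rod nodes; deformed axes are used when a solution is supplied.  The z
#' range is scanned at 0.5 A steps.
#'
#' @param model an [assemble()]d `MechModel` (carries geometry and node maps)
#' @param sol optional `MechSolution`
#' @param z_step scan resolution, Angstrom
#' @return pore diameter, Angstrom
#' @export
pore_diameter <- function(model, sol = NULL, z_step = 0.5) {
  rods <- model$meta$rods
  tm1 <- which(rods$role == "TM1")
  if (length(tm1) < 3) stop("need >= 3 TM1 rods", call. = FALSE)
  polys <- lapply(tm1, function(k) rod_polyline(model, sol, k))
  hz <- model$meta$geometry$plate$thickness / 2
  zlo <- max(-hz, min(vapply(polys, function(P) min(P[, 3]), numeric(1))))
  zhi <- min(hz, max(vapply(polys, function(P) max(P[, 3]), numeric(1))))
  axis_xy <- colMeans(do.call(rbind, polys))[1:2]
  zs <- seq(zlo, zhi, by = z_step)
  dmin <- Inf
  for (z in zs) {
    pts <- t(vapply(polys, polyline_at_z, numeric(3), z = z))
    pts <- pts[is.finite(pts[, 1]), , drop = FALSE]
    if (nrow(pts) < length(polys)) next
    ## pore axis must lie inside the rod polygon at this height
    ang <- atan2(pts[, 2] - axis_xy[2], pts[, 1] - axis_xy[1])
    if (max(diff(sort(ang))) > pi &&
        (2 * pi - (max(sort(ang)) - min(sort(ang)))) > pi)
      stop("pore axis lies outside the TM1 rod polygon", call. = FALSE)
    d <- min(sqrt((pts[, 1] - axis_xy[1])^2 + (pts[, 2] - axis_xy[2])^2))
    dmin <- min(dmin, d)
  }
  if (!is.finite(dmin))
    stop("TM1 rods do not span the transmembrane region", call. = FALSE)
  2 * (dmin - rods$radius[tm1[1]])
}

#' Mean deformed bilayer thickness near the channel
#'
#' Transverse strain is recovered from the in-plane membrane strains of each
#' plate element under the plane-stress coupling
#' eps_z = -nu/(1-nu) (eps_xx + eps_yy); the deformed thickness is averaged
#' over elements whose centroid lies within two protein radii of the pore
#' axis.
#'
#' @param sol a converged `MechSolution`
#' @param model the solved `MechModel`
#' @return thickness, Angstrom
#' @export
membrane_thickness <- function(sol, model) {
  if (!is.null(sol) && !sol$converged)
    stop("membrane thickness requires a converged solution", call. = FALSE)
  geom <- model$meta$geometry
  t0 <- geom$plate$thickness
  if (is.null(sol)) return(t0)
  Rp <- geom$plate$footprint_radius %||% geom$plate$inner_radius
  nu <- model$meta$materials$bilayer_poisson
  msh <- model$meta$mesh
  off <- model$meta$plate_off
  vals <- c()
  for (tr in msh$tris) {
    nds <- off + tr
    xy <- model$nodes[nds, 1:2]
    ctr <- colMeans(xy)
    if (sqrt(sum(ctr^2)) > 2 * Rp) next
    x <- xy[, 1]; y <- xy[, 2]
    b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
    cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
    A2 <- x[1] * b[1] + x[2] * b[2] + x[3] * b[3]
    ux <- sol$displacements[nds, 1]; uy <- sol$displacements[nds, 2]
    exx <- sum(b * ux) / A2
    eyy <- sum(cc * uy) / A2
    vals <- c(vals, t0 * (1 - nu / (1 - nu) * (exx + eyy)))
  }
  mean(vals)
}

#' Mean belt separation
#'
#' Mean over adjacent-subunit pairs of the site-to-site Euclidean distance
#' for the same-residue sites of a belt (deformed positions when a solution
#' is given).
#'
#' @param model an [assemble()]d `MechModel`
#' @param sol optional `MechSolution` (or a displacement vector state)
#' @param belt "top", "middle" or "bottom"
#' @return separation, Angstrom
#' @export
belt_separation <- function(model, sol = NULL, belt) {
  bs <- model$meta$geometry$belt_sites[[belt]]
  if (is.null(bs)) stop("unknown belt '", belt, "'", call. = FALSE)
  n <- model$meta$n_subunits
  site_pos <- function(row) {
    p <- c(row$x, row$y, row$z)
    if (is.null(sol)) return(p)
    k <- which(model$meta$rods$role == "C-term" &
                 model$meta$rods$subunit == row$subunit)
    ids <- model$meta$rod_nodes[[k]]
    d2 <- rowSums((model$nodes[ids, , drop = FALSE] -
                     matrix(p, length(ids), 3, byrow = TRUE))^2)
    nd <- ids[which.min(d2)]
    dvec <- p - model$nodes[nd, ]
    p + sol$displacements[nd, ] + cross3(sol$rotations[nd, ], dvec)
  }
  d <- c()
  for (lab in unique(bs$label)) for (s in seq_len(n)) {
    s2 <- s %% n + 1L
    p1 <- site_pos(bs[bs$subunit == s & bs$label == lab, ][1, ])
    p2 <- site_pos(bs[bs$subunit == s2 & bs$label == lab, ][1, ])
    d <- c(d, sqrt(sum((p1 - p2)^2)))
  }
  mean(d)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Belt separation along the load path
#'
#' @param model solved `MechModel`
#' @param sol `MechSolution`
#' @param belt belt id
#' @return numeric vector, separation at each increment (load factor order)
#' @export
belt_separation_history <- function(model, sol, belt) {
  vapply(sol$increments, function(inc) {
    tmp <- sol
    nid <- nrow(model$nodes)
    idx <- sol$idx
    tmp$displacements <- matrix(inc$u[t(idx[, 1:3])], nid, 3, byrow = TRUE)
    tmp$rotations <- matrix(inc$u[t(idx[, 4:6])], nid, 3, byrow = TRUE)
    belt_separation(model, tmp, belt)
  }, numeric(1))
}

#' Count geometric hydrogen bonds in an atomistic fixture
#'
#' Counts donor-acceptor pairs with donor-acceptor distance <= `dist_cutoff`
#' and deviation of the D-H...A angle from linearity <= `angle_cutoff`
#' (both inclusive).
#'
#' @param fixture an `AtomisticFixture` (see [gen_belt_fixture()])
#' @param dist_cutoff Angstrom, default 3.5
#' @param angle_cutoff degrees, default 30
#' @return integer count
#' @export
count_hbonds <- function(fixture, dist_cutoff = 3.5, angle_cutoff = 30) {
  don <- fixture$donors; acc <- fixture$acceptors
  if (is.null(don$hx)) stop("donor without hydrogen position", call. = FALSE)
  if (nrow(don) == 0 || nrow(acc) == 0) return(0L)
  D <- as.matrix(don[, c("nx", "ny", "nz")])
  H <- as.matrix(don[, c("hx", "hy", "hz")])
  A <- as.matrix(acc[, c("ox", "oy", "oz")])
  n <- 0L
  eps <- 1e-9                      # inclusive boundaries, rounding-safe
  for (i in seq_len(nrow(D))) {
    dv <- sqrt(colSums((t(A) - D[i, ])^2))
    cand <- which(dv <= dist_cutoff + eps)
    for (j in cand) {
      v1 <- H[i, ] - D[i, ]; v2 <- A[j, ] - H[i, ]
      ccos <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      dev <- acos(pmin(1, pmax(-1, ccos))) * 180 / pi
      if (dev <= angle_cutoff + eps) n <- n + 1L
    }
  }
  n
}

#' Per-residue radial displacement and dissociated segment
#'
#' Interpolates the radial (away-from-axis) displacement along each
#' C-terminal rod at the residue arc positions, averages over subunits, and
#' reports the maximal residue interval starting at 110 whose displacement
#' exceeds a threshold (default twice the median displacement of residues
#' 125-136).
#'
#' @param model solved `MechModel`
#' @param sol `MechSolution`
#' @param residues integer residue numbers (default 110:136)
#' @param threshold absolute threshold, Angstrom, or NULL for the 2 x distal
#'   median rule (floored at `floor_A`, which guards against a distal median
#'   near or below zero)
#' @param floor_A minimum threshold, Angstrom (default 0.5, the scale of
#'   incidental elastic drift of the assembled bundle)
#' @return list(residue, radial_displacement, threshold, segment) where
#'   segment is c(lo, hi) or NULL
#' @export
dissociation_profile <- function(model, sol, residues = 110:136,
                                 threshold = NULL, floor_A = 0.5) {
  if (length(residues) == 0) stop("empty residue map", call. = FALSE)
  rods <- model$meta$rods
  ct <- which(rods$role == "C-term")
  prof <- matrix(0, length(ct), length(residues))
  for (m in seq_along(ct)) {
    k <- ct[m]
    ids <- model$meta$rod_nodes[[k]]
    P0 <- model$nodes[ids, , drop = FALSE]
    U <- sol$displacements[ids, , drop = FALSE]
    tt <- seq(0, 1, length.out = length(ids))
    for (q in seq_along(residues)) {
      f <- cterm_fraction(residues[q])
      p0 <- c(approx(tt, P0[, 1], f)$y, approx(tt, P0[, 2], f)$y,
              approx(tt, P0[, 3], f)$y)
      uu <- c(approx(tt, U[, 1], f)$y, approx(tt, U[, 2], f)$y,
              approx(tt, U[, 3], f)$y)
      rad <- p0[1:2] / sqrt(sum(p0[1:2]^2))
      prof[m, q] <- sum(uu[1:2] * rad)
    }
  }
  disp <- colMeans(prof)
  if (is.null(threshold)) {
    distal <- disp[residues >= 125 & residues <= 136]
    threshold <- max(2 * stats::median(distal), floor_A)
  }
  segment <- NULL
  if (any(disp > threshold) && disp[1] > threshold) {
    hi <- which(cumsum(disp <= threshold) == 0)
    segment <- c(residues[1], residues[max(hi)])
  }
  list(residue = residues, radial_displacement = disp,
       threshold = threshold, segment = segment)
}

#' Assemble a gating report
#'
#' @param model_closed,model_open assembled models (usually identical)
#' @param sol_closed,sol_open solutions at zero and gating tension
#' @return a `GatingReport` list
#' @export
gating_report <- function(model_closed, sol_closed, model_open, sol_open) {
  belts <- c("top", "middle", "bottom")
  seps <- lapply(belts, function(b)
    c(closed = belt_separation(model_closed, sol_closed, b),
      open = belt_separation(model_open, sol_open, b)))
  names(seps) <- belts
  dis <- dissociation_profile(model_open, sol_open)
  structure(list(
    pore_diameter_closed = pore_diameter(model_closed, sol_closed),
    pore_diameter_open = pore_diameter(model_open, sol_open),
    membrane_thickness_closed = membrane_thickness(sol_closed, model_closed),
    membrane_thickness_open = membrane_thickness(sol_open, model_open),
    belt_separations = seps,
    dissociated_segment = dis$segment,
    dissociation = dis), class = "GatingReport")
}

#' @export
print.GatingReport <- function(x, ...) {
  cat("Gating report\n")
  cat(sprintf("  pore diameter     : %6.2f -> %6.2f A\n",
              x$pore_diameter_closed, x$pore_diameter_open))
  cat(sprintf("  bilayer thickness : %6.2f -> %6.2f A\n",
              x$membrane_thickness_closed, x$membrane_thickness_open))
  for (b in names(x$belt_separations))
    cat(sprintf("  %-6s belt sep   : %6.2f -> %6.2f A\n", b,
                x$belt_separations[[b]]["closed"],
                x$belt_separations[[b]]["open"]))
  if (is.null(x$dissociated_segment)) cat("  dissociated segment: none\n")
  else cat(sprintf("  dissociated segment: [%d, %d]\n",
                   x$dissociated_segment[1], x$dissociated_segment[2]))
  invisible(x)
}
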