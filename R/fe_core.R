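## Finite-element core: 3D Timoshenko/Euler-Bernoulli beams, flat Mindlin
## plate triangles (membrane + bending + transverse shear), rigid
## translational ties, nonlinear point-to-point connectors, incremental
## Newton solution.  All quantities in internal units (Angstrom, kcal/mol).
##
## Node degrees of freedom: [ux uy uz, theta_x theta_y theta_z].

#' Create an empty FE model
#'
#' Low-level constructor used by [assemble()] and by the element benchmarks;
#' nodes can be added up-front, elements/constraints/loads via the `fe_add_*`
#' helpers.
#'
#' @param nodes numeric matrix (n x 3) of node coordinates, Angstrom
#' @return a `MechModel`
#' @export
fe_new_model <- function(nodes) {
  nodes <- as.matrix(nodes)
  structure(list(
    nodes = nodes,
    beams = list(), tris = list(), connectors = list(),
    tie_master = seq_len(nrow(nodes)),   # translation-dof master per node
    fixed = integer(0),                  # fixed global dofs
    penalties = list(),                  # list(node, dir, k)
    ground_springs = list(),             # list(dof, k) diagonal grounding
    loads = numeric(6 * nrow(nodes)),
    meta = list()), class = "MechModel")
}

#' @rdname fe_new_model
#' @param model a `MechModel`
#' @param n1,n2 node indices
#' @param E,nu Young's modulus (internal units) and Poisson ratio
#' @param radius circular section radius, Angstrom
#' @param formulation "timoshenko" or "euler"
#' @param tag free-form element label
#' @export
fe_add_beam <- function(model, n1, n2, E, nu, radius,
                        formulation = c("timoshenko", "euler"), tag = "") {
  formulation <- match.arg(formulation)
  A <- pi * radius^2
  I <- pi * radius^4 / 4
  model$beams[[length(model$beams) + 1L]] <-
    list(n1 = n1, n2 = n2, E = E, G = E / (2 * (1 + nu)), A = A,
         Iy = I, Iz = I, J = 2 * I, As = 0.9 * A,
         formulation = formulation, tag = tag)
  model
}

#' @rdname fe_new_model
#' @param n3 third node of the triangle (counter-clockwise order)
#' @param thickness plate thickness, Angstrom
#' @export
fe_add_tri <- function(model, n1, n2, n3, E, nu, thickness, tag = "plate") {
  model$tris[[length(model$tris) + 1L]] <-
    list(n = c(n1, n2, n3), E = E, nu = nu, t = thickness, tag = tag)
  model
}

#' @rdname fe_new_model
#' @param slave,master node indices: slave translations follow the master
#' @export
fe_tie <- function(model, slave, master) {
  model$tie_master[slave] <- model$tie_master[master]
  model
}

#' @rdname fe_new_model
#' @param node node index
#' @param comps dof components to fix (1..6)
#' @export
fe_fix <- function(model, node, comps = 1:6) {
  model$fixed <- union(model$fixed, (node - 1L) * 6L + comps)
  model
}

#' @rdname fe_new_model
#' @param force length-3 force applied at the node's translations
#' @export
fe_load <- function(model, node, force) {
  i <- (node - 1L) * 6L
  model$loads[i + 1:3] <- model$loads[i + 1:3] + force
  model
}

#' @rdname fe_new_model
#' @param dir unit direction of a grounded translational penalty spring
#' @param k spring stiffness
#' @export
fe_penalty <- function(model, node, dir, k) {
  model$penalties[[length(model$penalties) + 1L]] <-
    list(node = node, dir = dir / sqrt(sum(dir^2)), k = k)
  model
}

#' @rdname fe_new_model
#' @param site1,site2 lists `list(node =, offset =)`: attachment node and
#'   rigid lever arm (Angstrom) from node to site
#' @param table a `ForceDisplacementTable`, or NULL for a linear spring
#' @param k linear spring stiffness (used when `table` is NULL)
#' @param tag connector label (e.g. belt name)
#' @export
fe_add_connector <- function(model, site1, site2, table = NULL, k = NULL,
                             tag = "") {
  X1 <- model$nodes[site1$node, ] + site1$offset
  X2 <- model$nodes[site2$node, ] + site2$offset
  model$connectors[[length(model$connectors) + 1L]] <-
    list(s1 = site1, s2 = site2, table = table, k = k,
         r_ref = sqrt(sum((X1 - X2)^2)), tag = tag)
  model
}

## ---- element matrices ------------------------------------------------------

skew3 <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0),
                            3, 3)

beam_stiffness_local <- function(E, G, A, Iy, Iz, J, As, L, formulation) {
  k <- matrix(0, 12, 12)
  k[c(1, 7), c(1, 7)] <- E * A / L * matrix(c(1, -1, -1, 1), 2)
  k[c(4, 10), c(4, 10)] <- G * J / L * matrix(c(1, -1, -1, 1), 2)
  phi_y <- if (formulation == "timoshenko") 12 * E * Iz / (G * As * L^2) else 0
  phi_z <- if (formulation == "timoshenko") 12 * E * Iy / (G * As * L^2) else 0
  a <- E * Iz / ((1 + phi_y) * L^3)
  kb <- a * matrix(c(
    12, 6 * L, -12, 6 * L,
    6 * L, (4 + phi_y) * L^2, -6 * L, (2 - phi_y) * L^2,
    -12, -6 * L, 12, -6 * L,
    6 * L, (2 - phi_y) * L^2, -6 * L, (4 + phi_y) * L^2), 4, 4, byrow = TRUE)
  ii <- c(2, 6, 8, 12)
  k[ii, ii] <- k[ii, ii] + kb
  b <- E * Iy / ((1 + phi_z) * L^3)
  kb2 <- b * matrix(c(
    12, -6 * L, -12, -6 * L,
    -6 * L, (4 + phi_z) * L^2, 6 * L, (2 - phi_z) * L^2,
    -12, 6 * L, 12, 6 * L,
    -6 * L, (2 - phi_z) * L^2, 6 * L, (4 + phi_z) * L^2), 4, 4, byrow = TRUE)
  jj <- c(3, 5, 9, 11)
  k[jj, jj] <- k[jj, jj] + kb2
  k
}

beam_stiffness_global <- function(el, nodes) {
  p1 <- nodes[el$n1, ]; p2 <- nodes[el$n2, ]
  L <- sqrt(sum((p2 - p1)^2))
  t <- (p2 - p1) / L
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- ref - sum(ref * t) * t; n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t[2] * n1[3] - t[3] * n1[2], t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  R <- rbind(t, n1, n2)
  Tm <- matrix(0, 12, 12)
  for (b in 0:3) Tm[b * 3 + 1:3, b * 3 + 1:3] <- R
  kl <- beam_stiffness_local(el$E, el$G, el$A, el$Iy, el$Iz, el$J, el$As, L,
                             el$formulation)
  t(Tm) %*% kl %*% Tm
}

## Mindlin flat-shell triangle in the global x-y plane (the bilayer is
## horizontal).  18x18 in node dof order [ux uy uz tx ty tz] x 3.
tri_stiffness <- function(el, nodes, drill = 1e-3) {
  xy <- nodes[el$n, 1:2]
  x <- xy[, 1]; y <- xy[, 2]
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  A2 <- x[1] * b[1] + x[2] * b[2] + x[3] * b[3]
  A <- A2 / 2
  if (A <= 0) stop("triangle with non-positive area (node order must be CCW)")
  dNdx <- b / A2; dNdy <- cc / A2
  E <- el$E; nu <- el$nu; th <- el$t
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  ## membrane (constant strain)
  Bm <- matrix(0, 3, 6)
  for (i in 1:3) {
    Bm[1, 2 * i - 1] <- dNdx[i]; Bm[2, 2 * i] <- dNdy[i]
    Bm[3, 2 * i - 1] <- dNdy[i]; Bm[3, 2 * i] <- dNdx[i]
  }
  Km <- th * A * t(Bm) %*% D %*% Bm
  ## bending: normal slopes phi_x = theta_y, phi_y = -theta_x
  Bb <- matrix(0, 3, 9)          # bending dofs per node: (w, tx, ty)
  for (i in 1:3) {
    txc <- 3 * i - 1; tyc <- 3 * i
    Bb[1, tyc] <- dNdx[i]
    Bb[2, txc] <- -dNdy[i]
    Bb[3, tyc] <- dNdy[i]; Bb[3, txc] <- -dNdx[i]
  }
  Kb <- A * t(Bb) %*% (th^3 / 12 * D) %*% Bb
  ## transverse shear (3 mid-edge points, exact for the linear fields)
  Ds <- (5 / 6) * (E / (2 * (1 + nu))) * th
  gp <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5))
  Ks <- matrix(0, 9, 9)
  for (g in 1:3) {
    N <- gp[g, ]
    Bs <- matrix(0, 2, 9)
    for (i in 1:3) {
      wc <- 3 * i - 2; txc <- 3 * i - 1; tyc <- 3 * i
      Bs[1, wc] <- dNdx[i]; Bs[1, tyc] <- -N[i]
      Bs[2, wc] <- dNdy[i]; Bs[2, txc] <- N[i]
    }
    Ks <- Ks + (A / 3) * t(Bs) %*% Bs
  }
  Ks <- Ds * Ks
  K <- matrix(0, 18, 18)
  mcols <- c(1, 2, 7, 8, 13, 14)
  K[mcols, mcols] <- Km
  bcols <- c(3, 4, 5, 9, 10, 11, 15, 16, 17)
  K[bcols, bcols] <- K[bcols, bcols] + Kb + Ks
  dcols <- c(6, 12, 18)
  K[dcols, dcols] <- K[dcols, dcols] + diag(drill * E * th * A, 3)
  K
}

## ---- assembly --------------------------------------------------------------

## global dof index per (node, comp), honouring translational ties
dof_index <- function(model) {
  n <- nrow(model$nodes)
  idx <- matrix(seq_len(6L * n), nrow = n, ncol = 6, byrow = TRUE)
  tm <- model$tie_master
  for (nd in seq_len(n))
    if (tm[nd] != nd) idx[nd, 1:3] <- idx[tm[nd], 1:3]
  idx
}

node_dofs <- function(idx, nd) idx[nd, ]

assemble_linear <- function(model) {
  idx <- dof_index(model)
  n_dof <- 6L * nrow(model$nodes)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  push <- function(dofs, K) {
    nz <- which(K != 0, arr.ind = TRUE)
    list(i = dofs[nz[, 1]], j = dofs[nz[, 2]], v = K[nz])
  }
  trip <- list()
  for (el in model$beams) {
    K <- beam_stiffness_global(el, model$nodes)
    dofs <- c(node_dofs(idx, el$n1), node_dofs(idx, el$n2))
    trip[[length(trip) + 1L]] <- push(dofs, K)
  }
  for (el in model$tris) {
    K <- tri_stiffness(el, model$nodes)
    dofs <- c(node_dofs(idx, el$n[1]), node_dofs(idx, el$n[2]),
              node_dofs(idx, el$n[3]))
    trip[[length(trip) + 1L]] <- push(dofs, K)
  }
  for (p in model$penalties) {
    K <- p$k * (p$dir %o% p$dir)
    dofs <- idx[p$node, 1:3]
    trip[[length(trip) + 1L]] <- push(dofs, K)
  }
  for (g in model$ground_springs)
    trip[[length(trip) + 1L]] <- list(i = g$dof, j = g$dof, v = g$k)
  ii <- unlist(lapply(trip, `[[`, "i"))
  jj <- unlist(lapply(trip, `[[`, "j"))
  vv <- unlist(lapply(trip, `[[`, "v"))
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n_dof, n_dof),
                            symmetric = FALSE)
  ## tiny uniform regularisation stabilises incidental floating rotations
  reg <- 1e-9 * max(abs(Matrix::diag(K)))
  K + Matrix::Diagonal(n_dof, reg)
}

## connector kinematics: site position map  x = X + u_node + theta x d
conn_B <- function(d) cbind(diag(3), -skew3(d))

## evaluate all connectors: returns applied force vector (length n_dof) and
## tangent triplets; f_ref: per-connector reference (tare) force vectors
conn_eval <- function(model, idx, u, tare_vecs = NULL, want_tangent = TRUE) {
  n_dof <- 6L * nrow(model$nodes)
  Fap <- numeric(n_dof)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  details <- vector("list", length(model$connectors))
  for (ci in seq_along(model$connectors)) {
    cn <- model$connectors[[ci]]
    d1 <- cn$s1$offset; d2 <- cn$s2$offset
    B1 <- conn_B(d1); B2 <- conn_B(d2)
    dofs1 <- node_dofs(idx, cn$s1$node); dofs2 <- node_dofs(idx, cn$s2$node)
    X1 <- model$nodes[cn$s1$node, ] + d1
    X2 <- model$nodes[cn$s2$node, ] + d2
    x1 <- X1 + B1 %*% u[dofs1]
    x2 <- X2 + B2 %*% u[dofs2]
    w <- as.numeric(x1 - x2)
    r <- sqrt(sum(w^2))
    if (!is.finite(r) || r < 1e-9) { r <- 1e-9; w <- c(1e-9, 0, 0) }
    nvec <- w / r
    if (!is.null(cn$table)) {
      f  <- table_force(cn$table, r)
      fp <- conn_table_slope(cn$table, r)
    } else {
      ## linear spring, same sign convention as the tables: f = -dV/dr,
      ## negative (attractive/restoring) when stretched past r_ref
      f  <- -cn$k * (r - cn$r_ref)
      fp <- -cn$k
    }
    Cmat <- cbind(B1, -B2)                       # 3 x 12
    g <- as.numeric(t(Cmat) %*% nvec)            # d r / d u
    Fl <- f * g                                  # applied force on the 12 dofs
    dofs <- c(dofs1, dofs2)
    Fap[dofs] <- Fap[dofs] + Fl
    if (want_tangent) {
      M <- fp * (nvec %o% nvec) + (f / r) * (diag(3) - nvec %o% nvec)
      Kc <- t(Cmat) %*% M %*% Cmat
      nz <- which(Kc != 0, arr.ind = TRUE)
      ti <- c(ti, dofs[nz[, 1]]); tj <- c(tj, dofs[nz[, 2]]); tv <- c(tv, Kc[nz])
    }
    details[[ci]] <- list(r = r, f = f, tag = cn$tag)
  }
  list(F = Fap, ti = ti, tj = tj, tv = tv, details = details)
}

## slope of the interpolated table at r (piecewise constant)
conn_table_slope <- function(table, r) {
  g <- table$grid
  if (r >= g[length(g)] || r <= g[1]) return(0)
  i <- findInterval(r, g)
  (table$force[i + 1] - table$force[i]) / (g[i + 1] - g[i])
}

#' Solve an assembled FE model by incremental Newton iteration
#'
#' External loads are applied in `n_increments` equal steps; at each step the
#' residual (internal minus external force) is driven below
#' `tol * max(||F_ext||, 1e-8)` by damped Newton iteration.  Connector forces
#' are evaluated from their tables at the current site separations; the
#' reference configuration is treated as self-equilibrated, i.e. the
#' connector forces present at zero displacement are subtracted as a constant
#' balancing load.
#'
#' @param model a `MechModel`
#' @param n_increments number of load increments (>= 1)
#' @param tol relative residual tolerance
#' @param max_iter Newton iterations per increment
#' @param trace logical: print per-increment convergence
#' @return a `MechSolution`: list(u, displacements, rotations, increments,
#'   residual, converged, idx)
#' @export
fe_solve <- function(model, n_increments = 20L, tol = 1e-8, max_iter = 50L,
                     trace = FALSE) {
  idx <- dof_index(model)
  n_dof <- 6L * nrow(model$nodes)
  K <- assemble_linear(model)
  fixed <- model$fixed
  ## dofs made redundant by ties never appear in idx; exclude them as well
  active <- sort(setdiff(unique(as.vector(idx)), fixed))
  u <- numeric(n_dof)
  Fext <- model$loads
  ## tare: applied connector force at u = 0
  c0 <- conn_eval(model, idx, u, want_tangent = FALSE)
  F0 <- c0$F
  increments <- list()
  converged_all <- TRUE
  res_norm <- 0
  ## try to equilibrate at load factor lam starting from state u0;
  ## returns list(u, res, it, ok)
  newton_at <- function(lam, u0) {
    target <- lam * Fext
    ref <- max(sqrt(sum(target[active]^2)), 1e-8)
    u <- u0
    rn <- Inf
    for (it in seq_len(max_iter)) {
      ce <- conn_eval(model, idx, u)
      R <- as.numeric(K %*% u) - (ce$F - F0) - target
      rn <- sqrt(sum(R[active]^2))
      if (trace)
        message(sprintf("  lam %.4f it %d |R| = %.3e", lam, it, rn))
      if (!is.finite(rn)) return(list(u = u0, res = rn, it = it, ok = FALSE))
      if (rn <= tol * ref) return(list(u = u, res = rn, it = it, ok = TRUE))
      J <- K
      if (length(ce$ti))
        J <- J - Matrix::sparseMatrix(i = ce$ti, j = ce$tj, x = ce$tv,
                                      dims = c(n_dof, n_dof))
      du <- numeric(n_dof)
      sol <- tryCatch(Matrix::solve(J[active, active], -R[active]),
                      error = function(e) NULL)
      if (is.null(sol))
        stop("singular stiffness: insufficient boundary conditions",
             call. = FALSE)
      du[active] <- as.numeric(sol)
      if (any(!is.finite(du)))
        return(list(u = u, res = rn, it = it, ok = FALSE))
      ## trust region on the displacement update
      mx <- max(abs(du))
      if (mx > 10) du <- du * (10 / mx)
      ## backtracking line search
      step <- 1
      for (ls in 1:10) {
        u_try <- u + step * du
        ce2 <- conn_eval(model, idx, u_try, want_tangent = FALSE)
        R2 <- as.numeric(K %*% u_try) - (ce2$F - F0) - lam * Fext
        rn2 <- sqrt(sum(R2[active]^2))
        if (is.finite(rn2) && (rn2 < rn || ls == 10)) break
        step <- step / 2
      }
      u <- u + step * du
      if (any(!is.finite(u)))
        return(list(u = u0, res = rn, it = it, ok = FALSE))
    }
    list(u = u, res = rn, it = max_iter, ok = FALSE)
  }
  lam <- 0
  dlam_base <- 1 / n_increments
  dlam <- dlam_base
  dlam_min <- dlam_base / 64
  while (lam < 1 - 1e-12) {
    lam_try <- min(lam + dlam, 1)
    st <- newton_at(lam_try, u)
    if (st$ok) {
      lam <- lam_try
      u <- st$u
      res_norm <- st$res
      increments[[length(increments) + 1L]] <-
        list(lambda = lam, iterations = st$it, residual = st$res,
             converged = TRUE, u = u)
      if (dlam < dlam_base) dlam <- min(2 * dlam, dlam_base)
    } else {
      dlam <- dlam / 2
      if (dlam < dlam_min) {
        res_norm <- st$res
        increments[[length(increments) + 1L]] <-
          list(lambda = lam_try, iterations = st$it, residual = st$res,
               converged = FALSE, u = st$u)
        converged_all <- FALSE
        break
      }
    }
  }
  disp <- matrix(0, nrow(model$nodes), 3)
  rot  <- matrix(0, nrow(model$nodes), 3)
  for (nd in seq_len(nrow(model$nodes))) {
    disp[nd, ] <- u[idx[nd, 1:3]]
    rot[nd, ]  <- u[idx[nd, 4:6]]
  }
  structure(list(u = u, displacements = disp, rotations = rot,
                 increments = increments, residual = res_norm,
                 converged = converged_all, idx = idx),
            class = "MechSolution")
}
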