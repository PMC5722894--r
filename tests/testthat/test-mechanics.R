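test_that("tension_to_stress reproduces the published equivalence", {
  expect_equal(tension_to_stress(9.5, 36.1), 2.63e6, tolerance = 2e-3)
  expect_equal(tension_to_stress(0, 35), 0)
  expect_equal(tension_to_stress(9.5, 35), 2.714e6, tolerance = 1e-3)
  expect_error(tension_to_stress(9.5, 0), "positive")
  expect_error(tension_to_stress(-1, 35), ">= 0")
})

test_that("unit conversions are consistent", {
  expect_equal(internal_to_pa(pa_to_internal(4.3e6)), 4.3e6, tolerance = 1e-12)
  expect_equal(pa_to_internal(6.9477e9), 1, tolerance = 1e-4)
  ## tension / thickness -> stress, in either unit system
  t_int <- tension_to_internal(9.5) / 35
  expect_equal(internal_to_pa(t_int), tension_to_stress(9.5, 35),
               tolerance = 1e-12)
})

test_that("beams match the Euler-Bernoulli and axial closed forms", {
  L <- 40; r <- 2.5; E <- 1.0; nu <- 0.3; nseg <- 8
  nodes <- cbind(seq(0, L, length.out = nseg + 1), 0, 0)
  P <- 1e-3
  I <- pi * r^4 / 4
  ## transverse tip load (Euler-Bernoulli flag)
  m <- fe_new_model(nodes)
  for (i in 1:nseg) m <- fe_add_beam(m, i, i + 1, E, nu, r, "euler")
  m <- fe_fix(m, 1, 1:6)
  m <- fe_load(m, nseg + 1, c(0, P, 0))
  sol <- fe_solve(m, n_increments = 1)
  expect_equal(sol$displacements[nseg + 1, 2], P * L^3 / (3 * E * I),
               tolerance = 0.01)
  ## axial load, any formulation, exact
  m2 <- fe_new_model(nodes)
  for (i in 1:nseg) m2 <- fe_add_beam(m2, i, i + 1, E, nu, r, "timoshenko")
  m2 <- fe_fix(m2, 1, 1:6)
  m2 <- fe_load(m2, nseg + 1, c(P, 0, 0))
  s2 <- fe_solve(m2, n_increments = 1)
  expect_equal(s2$displacements[nseg + 1, 1], P * L / (E * pi * r^2),
               tolerance = 1e-6)
  ## Timoshenko deflects more than Euler-Bernoulli for a stubby beam
  m3 <- fe_new_model(nodes)
  for (i in 1:nseg) m3 <- fe_add_beam(m3, i, i + 1, E, nu, r, "timoshenko")
  m3 <- fe_fix(m3, 1, 1:6)
  m3 <- fe_load(m3, nseg + 1, c(0, P, 0))
  s3 <- fe_solve(m3, n_increments = 1)
  expect_gt(s3$displacements[nseg + 1, 2], sol$displacements[nseg + 1, 2])
})

test_that("plate under uniform biaxial stress matches plane-stress strain", {
  nx <- 6; Lp <- 40; Ep <- 2e-3; nup <- 0.3; th <- 35
  xs <- seq(0, Lp, length.out = nx + 1)
  grid <- expand.grid(x = xs, y = xs)
  mp <- fe_new_model(cbind(grid$x, grid$y, 0))
  id <- function(i, j) (j - 1) * (nx + 1) + i
  for (i in 1:nx) for (j in 1:nx) {
    mp <- fe_add_tri(mp, id(i, j), id(i + 1, j), id(i + 1, j + 1), Ep, nup, th)
    mp <- fe_add_tri(mp, id(i, j), id(i + 1, j + 1), id(i, j + 1), Ep, nup, th)
  }
  sig <- 1e-4; el <- Lp / nx
  for (j in 1:(nx + 1)) {
    w <- if (j == 1 || j == nx + 1) 0.5 else 1
    mp <- fe_load(mp, id(nx + 1, j), c(sig * th * el * w, 0, 0))
    mp <- fe_load(mp, id(1, j), c(-sig * th * el * w, 0, 0))
    mp <- fe_load(mp, id(j, nx + 1), c(0, sig * th * el * w, 0))
    mp <- fe_load(mp, id(j, 1), c(0, -sig * th * el * w, 0))
  }
  mp <- fe_fix(mp, id(1, 1), c(1, 2, 3))
  mp <- fe_fix(mp, id(nx + 1, 1), c(2, 3))
  mp <- fe_fix(mp, id(1, nx + 1), 3)
  sp <- fe_solve(mp, n_increments = 1)
  strain <- (sp$displacements[id(nx + 1, 4), 1] -
               sp$displacements[id(1, 4), 1]) / Lp
  expect_equal(strain, sig * (1 - nup) / Ep, tolerance = 0.01)
})

test_that("assemble builds the advertised discretization and bookkeeping", {
  fx <- channel_fixture()
  model <- fx$model
  expect_gte(model$meta$n_beam_elements, 80L)  # 20 rods x >= 4 elements
  expect_equal(model$meta$n_subunits, 5L)
  d <- model$meta$dof
  expect_equal(d$n_free, d$n_total - d$n_constrained)
  ## channel boundary gap
  expect_lte(model$meta$geometry$plate$inner_radius -
               model$meta$geometry$plate$footprint_radius, 3.0)
  ## a missing belt table is reported by name
  expect_error(assemble(fx$geom, material_set(),
                        fx$tabs[c("top", "bottom")], fx$env),
               "middle")
})

test_that("zero tension gives an identically zero displacement field", {
  fx <- channel_fixture()
  sol <- solve_tension(fx$model, 0, n_increments = 1)
  expect_true(sol$converged)
  expect_equal(max(abs(sol$u)), 0)
  ## metrics agree between 'no solution' and a zero-load solution
  expect_equal(pore_diameter(fx$model, NULL), pore_diameter(fx$model, sol))
  for (b in c("top", "middle", "bottom"))
    expect_equal(belt_separation(fx$model, NULL, b),
                 belt_separation(fx$model, sol, b))
  expect_equal(membrane_thickness(sol, fx$model), 35)
})

test_that("the solved open state is 5-fold symmetric under symmetric input", {
  fx <- channel_fixture()
  sol <- solve_tension(fx$model, 9.5, n_increments = 5, tol = 1e-10)
  expect_true(sol$converged)
  th <- 2 * pi / 5
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rods <- fx$model$meta$rods
  for (role in c("TM1", "C-term")) for (s in 1:5) {
    k1 <- which(rods$role == role & rods$subunit == s)
    k2 <- which(rods$role == role & rods$subunit == s %% 5 + 1)
    u1 <- sol$displacements[fx$model$meta$rod_nodes[[k1]], ]
    u2 <- sol$displacements[fx$model$meta$rod_nodes[[k2]], ]
    expect_lt(max(abs(u1 %*% t(R) - u2)), 1e-6)
  }
})

test_that("loading is monotone and path work matches stored energy", {
  fx <- channel_fixture()
  sol <- solve_tension(fx$model, 9.5, n_increments = 10, tol = 1e-9)
  expect_true(sol$converged)
  hist_top <- belt_separation_history(fx$model, sol, "top")
  expect_true(all(diff(c(belt_separation(fx$model, NULL, "top"), hist_top))
                  > -1e-6))
  eb <- solution_energy_balance(fx$model, sol)
  expect_lt(eb$rel_gap, 0.02)
})

test_that("non-convergence is flagged rather than thrown", {
  ## a single unstable connector chain: soft beam pulled past a Morse well
  g <- gen_ideal_pentamer(pentamer_spec())
  env <- environment_preset("salt-water")
  tb <- build_connector_table("bottom", belt_spec(), g$belt_sites, env)
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0))
  m <- fe_new_model(nodes)
  m <- fe_add_beam(m, 1, 2, 1e-6, 0.3, 0.5)
  m <- fe_fix(m, 1, 1:6)
  m <- fe_add_connector(m, list(node = 2, offset = c(0, 0, 0)),
                        list(node = 1, offset = c(0, 0, 0)), table = tb)
  m <- fe_load(m, 2, c(50, 0, 0))
  sol <- fe_solve(m, n_increments = 4, max_iter = 8)
  expect_s3_class(sol, "MechSolution")
  expect_type(sol$converged, "logical")
})
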