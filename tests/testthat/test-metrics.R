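## hand-made geometry: n vertical rods at radius rho
vertical_tm1_rods <- function(n = 5, rho = 10, radius = 2.5, L = 40) {
  do.call(rbind, lapply(seq_len(n), function(s) {
    th <- 2 * pi * (s - 1) / n
    data.frame(role = "TM1", subunit = s,
               sx = rho * cos(th), sy = rho * sin(th), sz = -L / 2,
               ex = rho * cos(th), ey = rho * sin(th), ez = L / 2,
               radius = radius, rod_id = s, stringsAsFactors = FALSE)
  }))
}

test_that("pore diameter: vertical rods, tilted rods, rotation invariance", {
  m <- fake_rod_model(vertical_tm1_rods(rho = 10))
  expect_equal(pore_diameter(m, NULL), 2 * (10 - 2.5), tolerance = 1e-9)

  ## tilted rods: radius shrinks linearly with z; oracle = fine z-scan
  rods <- vertical_tm1_rods(rho = 12)
  rods$sx <- 8 * cos(2 * pi * (rods$subunit - 1) / 5)
  rods$sy <- 8 * sin(2 * pi * (rods$subunit - 1) / 5)
  mt <- fake_rod_model(rods, n_per_rod = 9L)
  fine <- local({
    dmin <- Inf
    for (z in seq(-17.5, 17.5, by = 0.05)) {
      f <- (z + 20) / 40
      r <- 8 + f * 4
      dmin <- min(dmin, r)
    }
    2 * (dmin - 2.5)
  })
  expect_equal(pore_diameter(mt, NULL), fine, tolerance = 0.1)

  ## rigid rotation about the pore axis leaves the diameter unchanged
  th <- 0.3
  rot <- rods
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  S <- as.matrix(rods[, c("sx", "sy", "sz")]) %*% t(R)
  E <- as.matrix(rods[, c("ex", "ey", "ez")]) %*% t(R)
  rot[, c("sx", "sy", "sz")] <- S; rot[, c("ex", "ey", "ez")] <- E
  expect_equal(pore_diameter(fake_rod_model(rot, 9L), NULL),
               pore_diameter(mt, NULL), tolerance = 1e-9)

  ## fewer than 3 rods is an error
  expect_error(pore_diameter(fake_rod_model(vertical_tm1_rods(n = 2)), NULL),
               "TM1")
})

test_that("belt separation equals the chord length on a symmetric pentamer", {
  fx <- channel_fixture()
  rho <- pentamer_spec()$bundle_radius
  for (b in c("top", "bottom"))
    expect_equal(belt_separation(fx$model, NULL, b), 2 * rho * sin(pi / 5),
                 tolerance = 1e-9)
  expect_error(belt_separation(fx$model, NULL, "side"), "unknown belt")
})

test_that("membrane thickness recovers the plane-stress closed form", {
  ## bare annular plate under uniform biaxial stress sigma: traction on both
  ## rims gives a uniform stress field, thickness = t (1 - 2 nu sigma / E)
  a <- 30; b <- 90; Ep <- 6e-4; nup <- 0.1; th <- 35
  msh <- bundlegate:::mesh_annulus(a, b, 0, 8L, 40L)
  m <- fe_new_model(msh$nodes)
  for (tr in msh$tris)
    m <- fe_add_tri(m, tr[1], tr[2], tr[3], Ep, nup, th)
  sig <- 5e-5
  arc_out <- 2 * pi * b / 40; arc_in <- 2 * pi * a / 40
  for (j in msh$outer_ids) {
    xy <- msh$nodes[j, 1:2]; rad <- c(xy / sqrt(sum(xy^2)), 0)
    m <- fe_load(m, j, sig * th * arc_out * rad)
  }
  for (j in msh$inner_ids) {
    xy <- msh$nodes[j, 1:2]; rad <- c(xy / sqrt(sum(xy^2)), 0)
    m <- fe_load(m, j, -sig * th * arc_in * rad)
  }
  for (j in msh$outer_ids) {
    m <- fe_fix(m, j, 3L)
    xy <- msh$nodes[j, 1:2]
    m <- fe_penalty(m, j, c(-xy[2], xy[1], 0), 1e4 * Ep * th)
  }
  sol <- fe_solve(m, n_increments = 1)
  ## wrap into the metric's expected shape
  model <- list(nodes = msh$nodes,
                meta = list(geometry = list(plate = list(thickness = th,
                                                         footprint_radius = b / 2)),
                            materials = list(bilayer_poisson = nup),
                            mesh = msh, plate_off = 0L))
  got <- membrane_thickness(sol, model)
  expect_equal(got, th * (1 - 2 * nup * sig / Ep), tolerance = 0.01)
  ## non-converged solutions are rejected
  sol$converged <- FALSE
  expect_error(membrane_thickness(sol, model), "converged")
})

test_that("count_hbonds equals the brute-force oracle and is inclusive", {
  fx0 <- gen_belt_fixture(n_planted = 0, seed = 2)
  expect_equal(count_hbonds(fx0), 0L)
  fx <- gen_belt_fixture(n_planted = 7, seed = 1)
  expect_equal(count_hbonds(fx), 7L)
  ## boundary case: exactly 3.5 A and exactly 30 deg is counted
  dev <- 30 * pi / 180
  donors <- data.frame(nx = 0, ny = 0, nz = 0,
                       hx = cos(dev), hy = sin(dev), hz = 0)
  acceptors <- data.frame(ox = cos(dev) + 2.5 * cos(2 * dev),
                          oy = sin(dev) + 2.5 * sin(2 * dev), oz = 0,
                          cx = 99, cy = 99, cz = 0)
  ## H at angle dev from x-axis; A placed so H->A makes angle dev with D->H,
  ## i.e. deviation-from-linearity exactly 30 deg; check D-A distance <= 3.5
  fx_b <- structure(list(donors = donors, acceptors = acceptors,
                         meta = list()), class = "AtomisticFixture")
  dDA <- sqrt(sum((c(donors$nx, donors$ny) -
                     c(acceptors$ox, acceptors$oy))^2))
  expect_lte(dDA, 3.5)
  expect_equal(count_hbonds(fx_b), 1L)
  expect_equal(count_hbonds(fx_b, angle_cutoff = 29.999), 0L)
  ## distance decoy at 3.6 A is not counted
  donors2 <- data.frame(nx = 0, ny = 0, nz = 0, hx = 1, hy = 0, hz = 0)
  acceptors2 <- data.frame(ox = 3.6, oy = 0, oz = 0, cx = 5, cy = 0, cz = 0)
  fx_d <- structure(list(donors = donors2, acceptors = acceptors2,
                         meta = list()), class = "AtomisticFixture")
  expect_equal(count_hbonds(fx_d), 0L)
  ## missing hydrogen is an error
  fx_bad <- fx_d; fx_bad$donors$hx <- NULL
  expect_error(count_hbonds(fx_bad), "hydrogen")
})

test_that("count_hbonds matches brute force across many seeded fixtures", {
  for (seed in 1:25) {
    fx <- gen_belt_fixture(belt = c("top", "middle", "bottom")[seed %% 3 + 1],
                           n_planted = seed %% 11,
                           separation = 2.4 + 0.12 * (seed %% 8),
                           seed = seed)
    expect_equal(count_hbonds(fx), brute_force_hbonds(fx))
  }
})

test_that("dissociation profile finds a constructed outward bend", {
  fx <- channel_fixture()
  model <- fx$model
  sol <- zero_solution(model)
  d0 <- dissociation_profile(model, sol)
  expect_true(all(d0$radial_displacement == 0))
  expect_null(d0$segment)

  ## plant an outward bend only above the 40% arc position of each C-term rod
  rods <- model$meta$rods
  for (k in which(rods$role == "C-term")) {
    ids <- model$meta$rod_nodes[[k]]
    tt <- seq(0, 1, length.out = length(ids))
    p <- model$nodes[ids[1], 1:2]
    rad <- c(p / sqrt(sum(p^2)), 0)
    for (i in seq_along(ids)) {
      amp <- max(0, (0.4 - tt[i]) / 0.4) * 6     # 6 A at the top, 0 below 40%
      sol$displacements[ids[i], ] <- amp * rad
    }
  }
  d <- dissociation_profile(model, sol)
  ## 40% of the arc is residue 110 + 0.4*26 = 120.4; upper bound within +-1
  expect_false(is.null(d$segment))
  expect_equal(d$segment[1], 110L)
  expect_lte(abs(d$segment[2] - 120), 1)
  expect_error(dissociation_profile(model, sol, residues = integer(0)),
               "empty")
})
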