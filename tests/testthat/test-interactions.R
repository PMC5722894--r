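test_that("debye_kappa matches the closed-form Debye expression", {
  expect_equal(debye_kappa(environment_preset("water")), 0)
  expect_equal(debye_kappa(environment_preset("vacuum")), 0)
  env <- environment_preset("salt-water")
  ## independent evaluation with locally spelled-out constants
  I <- 0.3 * 1000; T <- 298; eps_r <- 78.5
  kap <- sqrt(2 * 6.02214076e23 * 1.602176634e-19^2 * I /
                (8.8541878128e-12 * eps_r * 1.380649e-23 * T)) * 1e-9
  expect_equal(debye_kappa(env), kap, tolerance = 1e-10)
  expect_equal(kap, 1.80, tolerance = 0.01)
  ## rule-of-thumb cross-check: lambda_D ~ 0.304/sqrt(I) nm
  expect_equal(1 / kap, 0.304 / sqrt(0.3), tolerance = 0.01)
  ## quadrupling I doubles kappa
  env4 <- environment_preset("salt-water", ionic_strength = 1.2)
  expect_equal(debye_kappa(env4) / debye_kappa(env), 2, tolerance = 1e-12)
})

test_that("screened Coulomb energy follows the closed form", {
  vac <- environment_preset("vacuum")
  expect_equal(screened_coulomb_energy(1, 1, 332.06, vac), 1.0,
               tolerance = 1e-12)
  sw <- environment_preset("salt-water")
  ## independent spreadsheet-style evaluation at q1=+1, q2=-1, r=7
  kapA <- debye_kappa(sw) / 10
  ref <- 332.06 * (1) * (-1) / (78.5 * 7) * exp(-kapA * 7)
  expect_equal(screened_coulomb_energy(1, -1, 7, sw), ref, tolerance = 1e-10)
  ## monotone decay to zero
  r <- seq(3, 60, by = 0.5)
  u <- screened_coulomb_energy(1, 1, r, sw)
  expect_true(all(diff(u) < 0))
  expect_lt(u[length(u)], 1e-4)
  expect_error(screened_coulomb_energy(1, 1, 0, sw), "> 0")
})

test_that("DSSP hydrogen-bond energy matches direct arithmetic", {
  ## symmetric square geometry: r_ON = r_CH, r_OH = r_CN -> 0... use a true
  ## cancellation case: all four distances equal
  n <- c(0, 0, 0); h <- c(1, 0, 0); o <- c(0.5, sqrt(3) / 2, 0)
  cc <- c(0.5, -sqrt(3) / 2, 0)
  ## r_ON = r_OH = r_CN = r_CH = 1 -> E = 0
  expect_equal(dssp_hbond_energy(n, h, cc, o), 0, tolerance = 1e-12)
  ## canonical linear bond: direct arithmetic oracle
  E <- 0.084 * 332 * (1 / 2.9 + 1 / 3.14 - 1 / 1.9 - 1 / 4.14)
  expect_equal(canonical_hbond_energy(), E, tolerance = 1e-12)
  expect_lt(canonical_hbond_energy(), -0.5)
  ## stretching weakens the bond below the -0.5 threshold
  stretch <- function(rON) {
    dssp_hbond_energy(c(0, 0, 0), c(1, 0, 0), c(rON + 1.24, 0, 0),
                      c(rON, 0, 0))
  }
  expect_lt(abs(stretch(5.5)), abs(stretch(2.9)))
  expect_gt(stretch(5.5), -0.5)
  expect_error(dssp_hbond_energy(n, n, cc, o), "coincident")
})

test_that("connector tables equal -dU/dr and decay on the grid", {
  g <- gen_ideal_pentamer(pentamer_spec())
  belts <- belt_spec()
  for (envname in c("vacuum", "water", "salt-water")) {
    env <- environment_preset(envname)
    for (b in c("top", "middle", "bottom")) {
      tb <- build_connector_table(b, belts, g$belt_sites, env)
      ## central-difference oracle at every grid point
      h <- 1e-5
      fd <- -(tb$energy(tb$grid + h) - tb$energy(tb$grid - h)) / (2 * h)
      scale <- max(abs(fd), 1e-12)
      expect_lt(max(abs(fd - tb$force)) / scale, 1e-6)
      ## decay at grid max (screened / short-range well models only: the
      ## bare Coulomb middle belt in vacuum or pure water is long-range)
      screened <- b != "middle" || env$ionic_strength > 0
      if (screened && max(abs(tb$force)) > 0)
        expect_lt(abs(tb$force[length(tb$force)]), 0.01 * max(abs(tb$force)))
      ## energy/force consistency: integrate the force back from grid max
      r <- tb$grid
      Uint <- rev(cumsum(rev((tb$force[-1] + tb$force[-length(r)]) / 2 *
                               diff(r))))
      Umodel <- tb$energy(r[-length(r)]) - tb$energy(r[length(r)])
      expect_lt(max(abs(Uint - Umodel)) /
                  max(max(abs(Umodel)), 1e-9), 0.005)
    }
  }
})

test_that("the middle belt is attractive at the crystallographic separation", {
  g <- gen_ideal_pentamer(pentamer_spec())
  env <- environment_preset("salt-water")
  tb <- build_connector_table("middle", belt_spec(), g$belt_sites, env)
  expect_lt(table_force(tb, tb$r0), 0)
  expect_lt(tb$energy(tb$r0), 0)
  expect_error(build_connector_table("side", belt_spec(), g$belt_sites, env),
               "unknown belt")
  expect_error(build_connector_table("middle", belt_spec(), g$belt_sites, env,
                                     grid = c(3, 2, 1)), "increasing")
})

test_that("environment ordering: |energy| salt-water <= water <= vacuum", {
  r <- seq(4, 20, by = 0.5)
  qs <- list(c(1, -1), c(1, 1))
  for (q in qs) {
    uv <- abs(screened_coulomb_energy(q[1], q[2], r, environment_preset("vacuum")))
    uw <- abs(screened_coulomb_energy(q[1], q[2], r, environment_preset("water")))
    us <- abs(screened_coulomb_energy(q[1], q[2], r, environment_preset("salt-water")))
    expect_true(all(us <= uw + 1e-15))
    expect_true(all(uw <= uv + 1e-15))
  }
})

test_that("table interpolation is piecewise linear with zero extrapolation", {
  g <- gen_ideal_pentamer(pentamer_spec())
  env <- environment_preset("salt-water")
  tb <- build_connector_table("bottom", belt_spec(), g$belt_sites, env)
  i <- 10
  rmid <- (tb$grid[i] + tb$grid[i + 1]) / 2
  expect_equal(table_force(tb, rmid),
               (tb$force[i] + tb$force[i + 1]) / 2, tolerance = 1e-12)
  expect_equal(table_force(tb, max(tb$grid) + 5), 0)
  ## environment presets enforce their invariants
  expect_error(environment_preset("vacuum", ionic_strength = 0.1), "vacuum")
  expect_error(environment_preset("water", relative_permittivity = 0.5),
               "permittivity")
})
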