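## Shared fixtures and independent oracles for the test suite.

## independent O(n^2) hydrogen-bond oracle (kept deliberately separate from
## count_hbonds): plain loops, explicit trigonometry
brute_force_hbonds <- function(fx, dist_cutoff = 3.5, angle_cutoff = 30) {
  n <- 0L
  for (i in seq_len(nrow(fx$donors))) {
    D <- as.numeric(fx$donors[i, c("nx", "ny", "nz")])
    H <- as.numeric(fx$donors[i, c("hx", "hy", "hz")])
    for (j in seq_len(nrow(fx$acceptors))) {
      A <- as.numeric(fx$acceptors[j, c("ox", "oy", "oz")])
      if (sqrt(sum((D - A)^2)) > dist_cutoff) next
      v1 <- H - D; v2 <- A - H
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang <= angle_cutoff) n <- n + 1L
    }
  }
  n
}

## synthetic 5-chain C-alpha PDB text (chains A..E, residues 1..n_res)
synthetic_pdb_text <- function(n_res = 136, chains = LETTERS[1:5]) {
  lines <- character(0)
  serial <- 0L
  for (ci in seq_along(chains)) {
    th0 <- 2 * pi * (ci - 1) / length(chains)
    for (r in seq_len(n_res)) {
      serial <- serial + 1L
      x <- 8 * cos(th0) + 2.3 * cos(r * 100 * pi / 180)
      y <- 8 * sin(th0) + 2.3 * sin(r * 100 * pi / 180)
      z <- 1.5 * r
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chains[ci], r, x, y, z))
    }
  }
  c(lines, "END")
}

## build a tiny stand-alone "model" wrapper so metric functions can be
## exercised on hand-made rod configurations without a full assembly
fake_rod_model <- function(rods, n_per_rod = 5L, plate_thickness = 35) {
  node_list <- list(); rod_nodes <- list(); nid <- 0L
  for (k in seq_len(nrow(rods))) {
    s <- as.numeric(rods[k, c("sx", "sy", "sz")])
    e <- as.numeric(rods[k, c("ex", "ey", "ez")])
    tt <- seq(0, 1, length.out = n_per_rod)
    pts <- outer(1 - tt, s) + outer(tt, e)
    rod_nodes[[k]] <- nid + seq_len(nrow(pts)); nid <- nid + nrow(pts)
    node_list[[k]] <- pts
  }
  nodes <- do.call(rbind, node_list)
  list(nodes = nodes,
       meta = list(rods = rods, rod_nodes = rod_nodes,
                   geometry = list(plate = list(thickness = plate_thickness)),
                   n_subunits = length(unique(rods$subunit))))
}

zero_solution <- function(model) {
  structure(list(u = numeric(6 * nrow(model$nodes)),
                 displacements = matrix(0, nrow(model$nodes), 3),
                 rotations = matrix(0, nrow(model$nodes), 3),
                 increments = list(), residual = 0, converged = TRUE),
            class = "MechSolution")
}

## cached full salt-water channel assembly (analytic wall; used by the fast
## mechanics/metrics unit tests -- the acceptance suite does its own
## calibrated run)
channel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geom <- gen_ideal_pentamer(pentamer_spec())
      env <- environment_preset("salt-water")
      belts <- belt_spec()
      tabs <- lapply(c(top = "top", middle = "middle", bottom = "bottom"),
                     function(b) build_connector_table(b, belts,
                                                       geom$belt_sites, env))
      model <- assemble(geom, material_set(), tabs, env)
      cache <<- list(geom = geom, env = env, belts = belts, tabs = tabs,
                     model = model)
    }
    cache
  }
})
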