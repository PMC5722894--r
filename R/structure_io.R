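#' Belt interaction specification
#'
#' Names the residues forming the three inter-subunit interaction rings of
#' the C-terminal bundle, with their formal charges at physiological pH and
#' the distance from the C-alpha to the side-chain charge centre (used by the
#' middle-belt electrostatic energy model; see the methods vignette).
#' Defaults: top belt E118 (water-mediated hydrogen bonding), middle belt
#' E124/R126/D127 (salt-bridge ring), bottom belt R135/S136 (direct hydrogen
#' bond between adjacent subunits).
#'
#' @param top named integer vector of top-belt residues
#' @param middle named integer vector of middle-belt residues
#' @param bottom named integer vector of bottom-belt residues
#' @param charges named integer vector of per-residue-type formal charges
#'   (values in -1, 0, +1)
#' @param charge_offsets named numeric vector: C-alpha to side-chain charge
#'   centre distance, Angstrom
#' @return a `BeltSpec`
#' @export
belt_spec <- function(top = c(E118 = 118L),
                      middle = c(E124 = 124L, R126 = 126L, D127 = 127L),
                      bottom = c(R135 = 135L, S136 = 136L),
                      charges = c(E = -1L, D = -1L, R = 1L, K = 1L, S = 0L),
                      charge_offsets = c(E = 4.0, D = 2.5, R = 5.5, S = 2.5,
                                         K = 4.6)) {
  if (length(top) < 1 || length(middle) < 1 || length(bottom) < 1)
    stop("belts must be non-empty", call. = FALSE)
  if (!all(charges %in% c(-1L, 0L, 1L)))
    stop("formal charges must be in {-1, 0, +1}", call. = FALSE)
  structure(list(residues = list(top = top, middle = middle, bottom = bottom),
                 charges = charges, charge_offsets = charge_offsets),
            class = "BeltSpec")
}

#' Construct a coarse rod/plate geometry
#'
#' The container shared by the synthetic generator and the PDB route: a rod
#' table (role, subunit, axis endpoints, radius), a bilayer plate definition,
#' per-belt interaction sites and tie loci.
#'
#' @param rods data.frame with columns role, subunit, sx,sy,sz, ex,ey,ez,
#'   radius (and optionally rod_id)
#' @param plate list(thickness, extent, z, inner_radius, footprint_radius)
#' @param belt_sites named list (top/middle/bottom) of data.frames with
#'   columns subunit, residue, label, x, y, z
#' @param tie_pairs data.frame(role, locus) naming which rods are tied to the
#'   plate and where ("all", "span", "head")
#' @param metadata free-form list
#' @return a `CoarseGeometry`
#' @export
coarse_geometry <- function(rods, plate, belt_sites, tie_pairs,
                            metadata = list()) {
  if (is.null(rods$rod_id)) rods$rod_id <- seq_len(nrow(rods))
  geom <- structure(list(rods = rods, plate = plate, belt_sites = belt_sites,
                         tie_pairs = tie_pairs, metadata = metadata),
                    class = "CoarseGeometry")
  validate_coarse_geometry(geom)
  geom
}

validate_coarse_geometry <- function(geom) {
  need <- c("role", "subunit", "sx", "sy", "sz", "ex", "ey", "ez", "radius")
  if (!all(need %in% names(geom$rods)))
    stop("rods table missing columns: ",
         paste(setdiff(need, names(geom$rods)), collapse = ", "), call. = FALSE)
  ct <- geom$rods[geom$rods$role == "C-term", ]
  if (nrow(ct) > 0 && anyDuplicated(ct$subunit))
    stop("exactly one C-term rod per subunit required", call. = FALSE)
  ## belt sites must lie within 1.5 x radius of their subunit's C-term axis
  for (b in names(geom$belt_sites)) {
    bs <- geom$belt_sites[[b]]
    if (is.null(bs) || nrow(bs) == 0) next
    for (i in seq_len(nrow(bs))) {
      rod <- ct[ct$subunit == bs$subunit[i], ]
      if (nrow(rod) != 1) next
      d <- point_line_distance(c(bs$x[i], bs$y[i], bs$z[i]),
                               as.numeric(rod[c("sx", "sy", "sz")]),
                               as.numeric(rod[c("ex", "ey", "ez")]))
      if (d > 1.5 * rod$radius + 1e-9)
        stop(sprintf("belt site (%s, subunit %d, residue %d) lies %.2f A from its rod axis (> 1.5 x radius)",
                     b, bs$subunit[i], bs$residue[i], d), call. = FALSE)
    }
  }
  if (!all(geom$tie_pairs$role %in% geom$rods$role))
    stop("tie_pairs reference unknown rod roles", call. = FALSE)
  invisible(geom)
}

point_line_distance <- function(p, a, b) {
  u <- b - a; t <- sum((p - a) * u) / sum(u * u)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * u))^2))
}

#' Parse a C-alpha trace from PDB-format text
#'
#' Reads fixed-column ATOM/HETATM records, keeping one point per CA atom.
#' Alternate locations other than 'A' or blank are dropped; insertion codes
#' are rejected.  Residue numbering is taken 1-based from the file and
#' `residue_range` is inclusive on both ends.
#'
#' @param pdb_text character vector of PDB lines, or a single string with
#'   embedded newlines, or a file path to an existing file
#' @param chain_filter optional chain identifier(s) to keep
#' @param residue_range optional inclusive c(lo, hi) residue interval
#' @return a `CalphaTrace`: data.frame(chain, residue, resname, x, y, z) with
#'   attribute `source`
#' @export
parse_calpha <- function(pdb_text, chain_filter = NULL, residue_range = NULL) {
  src <- "text"
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    src <- pdb_text
    pdb_text <- readLines(pdb_text, warn = FALSE)
  } else if (length(pdb_text) == 1L) {
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  }
  rec <- substr(pdb_text, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- pdb_text[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    stop("no ATOM records found", call. = FALSE)
  name <- trimws(substr(lines, 13, 16))
  ca <- name == "CA"
  lines <- lines[ca]; lineno <- lineno[ca]
  altloc <- substr(lines, 17, 17)
  ok_alt <- altloc %in% c(" ", "A", "")
  lines <- lines[ok_alt]; lineno <- lineno[ok_alt]
  icode <- substr(lines, 27, 27)
  if (any(!icode %in% c(" ", "")))
    stop("insertion codes are not supported (line ",
         lineno[which(!icode %in% c(" ", ""))[1]], ")", call. = FALSE)
  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", what, " field at line ", lineno[bad[1]], call. = FALSE)
    v
  }
  out <- data.frame(
    chain = substr(lines, 22, 22),
    residue = as.integer(num(lines, 23, 26, "residue number")),
    resname = trimws(substr(lines, 18, 20)),
    x = num(lines, 31, 38, "x coordinate"),
    y = num(lines, 39, 46, "y coordinate"),
    z = num(lines, 47, 54, "z coordinate"),
    stringsAsFactors = FALSE)
  if (!is.null(chain_filter)) out <- out[out$chain %in% chain_filter, ]
  if (!is.null(residue_range))
    out <- out[out$residue >= residue_range[1] & out$residue <= residue_range[2], ]
  if (nrow(out) == 0)
    stop("empty trace: no CA atoms left after filtering", call. = FALSE)
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in trace", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "source") <- src
  class(out) <- c("CalphaTrace", "data.frame")
  out
}

#' Fit rods to C-alpha segments of a trace
#'
#' Each named segment of each chain is reduced to an elastic rod whose axis
#' is the total-least-squares line through its C-alpha points (first
#' principal axis), truncated to the extremal projections of the points.
#'
#' @param trace a [parse_calpha()] trace
#' @param segment_defs named list: role -> c(lo, hi) inclusive residue
#'   interval (applied per chain; chains map to subunits in file order)
#' @param rod_radius rod radius, Angstrom (default 2.5)
#' @param plate list passed through to the geometry (optional)
#' @return a `CoarseGeometry` without belt sites (add via
#'   [locate_belt_sites()])
#' @export
trace_to_rods <- function(trace, segment_defs, rod_radius = 2.5,
                          plate = list(thickness = 35, extent = 120, z = 0,
                                       inner_radius = NA, footprint_radius = NA)) {
  chains <- unique(trace$chain)
  rows <- list(); k <- 0L
  for (ci in seq_along(chains)) {
    ch <- trace[trace$chain == chains[ci], ]
    for (role in names(segment_defs)) {
      seg <- segment_defs[[role]]
      pts <- ch[ch$residue >= seg[1] & ch$residue <= seg[2],
                c("x", "y", "z"), drop = FALSE]
      if (nrow(pts) < 3)
        stop("segment '", role, "' has fewer than 3 residues in chain ",
             chains[ci], call. = FALSE)
      ax <- fit_axis(as.matrix(pts))
      k <- k + 1L
      rows[[k]] <- data.frame(role = role, subunit = ci,
                              sx = ax$start[1], sy = ax$start[2], sz = ax$start[3],
                              ex = ax$end[1], ey = ax$end[2], ez = ax$end[3],
                              radius = rod_radius, stringsAsFactors = FALSE)
    }
  }
  rods <- do.call(rbind, rows)
  coarse_geometry(rods = rods, plate = plate,
                  belt_sites = list(top = NULL, middle = NULL, bottom = NULL),
                  tie_pairs = data.frame(role = intersect(
                    c("TM2", "N-term", "TM1"), rods$role),
                    locus = c(span = "span", `N-term` = "all", head = "head")[
                      seq_len(length(intersect(c("TM2", "N-term", "TM1"),
                                               rods$role)))],
                  stringsAsFactors = FALSE),
                  metadata = list(source = attr(trace, "source"),
                                  site_atom = "CA"))
}

## axis through a point cloud: total-least-squares line (first principal
## axis), refined -- for helical clouds -- by minimising the variance of the
## point-to-axis distance (cylinder fit; removes the PCA tilt bias that the
## helical correlation between azimuth and rise induces over few turns).
## Truncated to the extremal projections, oriented along point order.
fit_axis <- function(P) {
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  if (max(abs(X)) < 1e-9)
    stop("degenerate segment: all points coincident", call. = FALSE)
  sv <- svd(X)
  d <- sv$v[, 1]
  resid <- sqrt(mean((X - (X %*% d) %*% t(d))^2))
  if (resid > 1e-8 && nrow(P) >= 6) {
    ## refine: axis = (ctr + a e1 + b e2) + t * dir(theta, phi in e1/e2)
    e1 <- sv$v[, 2]; e2 <- sv$v[, 3]
    obj <- function(par) {
      dd <- d + par[3] * e1 + par[4] * e2
      dd <- dd / sqrt(sum(dd * dd))
      p0 <- par[1] * e1 + par[2] * e2
      Y <- sweep(X, 2, p0)
      tproj <- Y %*% dd
      radial2 <- rowSums(Y^2) - tproj^2
      stats::var(sqrt(pmax(radial2, 0)))
    }
    op <- stats::optim(c(0, 0, 0, 0), obj, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
    d <- d + op$par[3] * e1 + op$par[4] * e2
    d <- d / sqrt(sum(d * d))
    ctr <- ctr + op$par[1] * e1 + op$par[2] * e2
    X <- sweep(P, 2, ctr)
  }
  t <- X %*% d
  if (t[1] > t[length(t)]) { d <- -d; t <- -t }
  list(start = ctr + min(t) * d, end = ctr + max(t) * d, dir = d,
       rms = sqrt(mean((X - (X %*% d) %*% t(d))^2)))
}

#' Locate belt interaction sites on a trace
#'
#' One site per (subunit, belt residue) at the C-alpha position.
#'
#' @param trace a [parse_calpha()] trace (chains = subunits)
#' @param belts a [belt_spec()]
#' @return named list of data.frames (top/middle/bottom) with columns
#'   subunit, residue, label, x, y, z
#' @export
locate_belt_sites <- function(trace, belts = belt_spec()) {
  chains <- unique(trace$chain)
  lapply(belts$residues, function(rr) {
    out <- list(); k <- 0L
    for (ci in seq_along(chains)) {
      ch <- trace[trace$chain == chains[ci], ]
      for (lab in names(rr)) {
        hit <- ch[ch$residue == rr[[lab]], ]
        if (nrow(hit) == 0)
          stop("belt residue ", lab, " missing from chain ", chains[ci],
               call. = FALSE)
        k <- k + 1L
        out[[k]] <- data.frame(subunit = ci, residue = rr[[lab]], label = lab,
                               x = hit$x[1], y = hit$y[1], z = hit$z[1],
                               stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Write a C-alpha pseudo-atom trace as PDB text
#'
#' @param trace a `CalphaTrace`
#' @param path output file, or NULL to return the lines
#' @return invisibly, the character vector of PDB lines
#' @export
write_calpha_pdb <- function(trace, path = NULL) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)),
    ifelse(nchar(trace$resname) > 0, trace$resname, "GLY"),
    trace$chain, trace$residue, trace$x, trace$y, trace$z)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Serialize / restore a coarse geometry as JSON
#'
#' @param geom a `CoarseGeometry`
#' @param path output (input) file path
#' @return `write_geometry_json` returns the path invisibly;
#'   `read_geometry_json` returns the `CoarseGeometry`
#' @export
write_geometry_json <- function(geom, path) {
  payload <- list(rods = geom$rods, plate = geom$plate,
                  belt_sites = geom$belt_sites, tie_pairs = geom$tie_pairs,
                  metadata = geom$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coarse_geometry(rods = as.data.frame(x$rods),
                  plate = as.list(x$plate),
                  belt_sites = lapply(x$belt_sites, function(b)
                    if (is.null(b) || length(b) == 0) NULL else as.data.frame(b)),
                  tie_pairs = as.data.frame(x$tie_pairs),
                  metadata = as.list(x$metadata))
}
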