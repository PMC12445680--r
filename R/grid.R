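#' Define a finite-difference grid
#'
#' @param origin numeric(3), position of node (1,1,1) in Angstrom
#' @param spacing node spacing in Angstrom (uniform, > 0)
#' @param dim integer(3), node counts per axis (>= 8)
#' @return object of class \code{grid_spec}
#' @export
grid_spec <- function(origin, spacing, dim) {
  dim <- as.integer(dim)
  if (spacing <= 0) stop("spacing must be > 0")
  if (length(dim) != 3 || any(dim < 8)) stop("need >= 8 nodes per axis")
  structure(list(origin = as.numeric(origin), spacing = spacing, dim = dim),
            class = "grid_spec")
}

#' Smallest grid covering a bounding box
#' @param lo,hi numeric(3) corners of the box to cover
#' @param spacing node spacing, Angstrom
#' @param margin extra clearance added on every side, Angstrom
#' @return a \code{grid_spec}
#' @export
grid_covering <- function(lo, hi, spacing, margin = 0) {
  lo <- lo - margin; hi <- hi + margin
  dim <- pmax(ceiling((hi - lo) / spacing) + 1L, 8L)
  # centre the grid on the box
  extent <- (dim - 1L) * spacing
  origin <- (lo + hi) / 2 - extent / 2
  grid_spec(origin, spacing, dim)
}

#' Grid node coordinates along each axis
#' @param grid a \code{grid_spec}
#' @return list(x, y, z) of axis node positions
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing,
       y = grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing,
       z = grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing)
}

#' Upper corner of a grid
#' @param grid a \code{grid_spec}
#' @export
grid_hi <- function(grid) grid$origin + (grid$dim - 1L) * grid$spacing

grid_n <- function(grid) prod(grid$dim)

# TRUE if all points lie inside the grid with the given clearance (Angstrom)
grid_contains <- function(grid, points, clearance = 0) {
  hi <- grid_hi(grid)
  all(points[, 1] >= grid$origin[1] + clearance, points[, 1] <= hi[1] - clearance,
      points[, 2] >= grid$origin[2] + clearance, points[, 2] <= hi[2] - clearance,
      points[, 3] >= grid$origin[3] + clearance, points[, 3] <= hi[3] - clearance)
}

# Fractional grid coordinates (1-based) of cartesian points
grid_frac <- function(grid, points) {
  sweep(sweep(points, 2, grid$origin, "-"), 2, rep(grid$spacing, 3), "/") + 1
}

#' Spread point charges onto grid nodes (trilinear)
#'
#' @param grid a \code{grid_spec}
#' @param points m x 3 matrix of charge positions
#' @param q charges (e)
#' @return flattened node-charge vector (column-major x-fastest layout);
#'   total is conserved exactly
#' @export
trilinear_spread <- function(grid, points, q) {
  points <- matrix(points, ncol = 3)
  if (!grid_contains(grid, points, clearance = grid$spacing))
    stop("charges lie outside the grid (or within one spacing of its faces)")
  f <- grid_frac(grid, points)
  i0 <- floor(f); w1 <- f - i0; w0 <- 1 - w1
  nx <- grid$dim[1]; ny <- grid$dim[2]
  rho <- numeric(grid_n(grid))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    idx <- (i0[, 1] + dx) + nx * (i0[, 2] + dy - 1) + nx * ny * (i0[, 3] + dz - 1)
    w <- (if (dx) w1[, 1] else w0[, 1]) *
         (if (dy) w1[, 2] else w0[, 2]) *
         (if (dz) w1[, 3] else w0[, 3])
    add <- tapply(q * w, idx, sum)
    ii <- as.integer(names(add))
    rho[ii] <- rho[ii] + as.numeric(add)
  }
  rho
}

#' Trilinear interpolation of a node field at arbitrary points
#' @param grid a \code{grid_spec}
#' @param field flattened node values
#' @param points m x 3 matrix
#' @return numeric(m)
#' @export
trilinear_interp <- function(grid, field, points) {
  points <- matrix(points, ncol = 3)
  if (!grid_contains(grid, points))
    stop("interpolation points outside the grid")
  f <- grid_frac(grid, points)
  i0 <- pmin(pmax(floor(f), 1), matrix(rep(grid$dim - 1L, each = nrow(f)), ncol = 3))
  w1 <- f - i0; w0 <- 1 - w1
  nx <- grid$dim[1]; ny <- grid$dim[2]
  out <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    idx <- (i0[, 1] + dx) + nx * (i0[, 2] + dy - 1) + nx * ny * (i0[, 3] + dz - 1)
    w <- (if (dx) w1[, 1] else w0[, 1]) *
         (if (dy) w1[, 2] else w0[, 2]) *
         (if (dz) w1[, 3] else w0[, 3])
    out <- out + w * field[idx]
  }
  out
}

#' Signed distance from grid nodes to the van der Waals union of atoms
#'
#' Negative inside any atom sphere, positive outside; the exact signed
#' distance to the nearest sphere surface.  Used to place the dielectric
#' boundary with sub-grid resolution.
#'
#' @param grid a \code{grid_spec}
#' @param structure a \code{pb_structure} (or NULL: all nodes "outside",
#'   +Inf)
#' @param reach only atoms whose surface comes within \code{reach} of a node
#'   influence it; distances are clamped at \code{reach} (Angstrom)
#' @return flattened signed-distance vector
#' @export
sdf_grid <- function(grid, structure, reach = 6) {
  n <- grid_n(grid)
  sdf <- rep(reach, n)
  if (is.null(structure)) return(sdf)
  ax <- grid_axes(grid)
  a <- structure$atoms
  h <- grid$spacing
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  for (k in seq_len(nrow(a))) {
    r <- a$radius[k]
    if (r <= 0) next
    cx <- a$x[k]; cy <- a$y[k]; cz <- a$z[k]
    R <- r + reach
    ix <- which(abs(ax$x - cx) <= R); if (length(ix) == 0) next
    iy <- which(abs(ax$y - cy) <= R); if (length(iy) == 0) next
    iz <- which(abs(ax$z - cz) <= R); if (length(iz) == 0) next
    dx2 <- (ax$x[ix] - cx)^2; dy2 <- (ax$y[iy] - cy)^2; dz2 <- (ax$z[iz] - cz)^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    d <- sqrt(d2) - r
    idx <- as.vector(outer(outer(ix, (iy - 1) * nx, "+"), (iz - 1) * nx * ny, "+"))
    dv <- as.vector(d)
    upd <- dv < sdf[idx]
    sdf[idx[upd]] <- dv[upd]
  }
  sdf
}

#' Build face-centred dielectric and screening maps
#'
#' Nodes inside the van der Waals union of the atoms take the protein
#' dielectric; edge (face) dielectrics crossing the boundary are combined by
#' a fraction-weighted harmonic mean, with the crossing located by linear
#' interpolation of the signed distance.  The Debye screening term is zeroed
#' inside the protein and a Stern layer around it.
#'
#' @param structure a \code{pb_structure} (NULL for uniform solvent)
#' @param grid a \code{grid_spec}
#' @param eps_in protein dielectric (default 4)
#' @param eps_out solvent dielectric (default 80)
#' @param ionic_strength mol/L (default 0.1)
#' @param T temperature, K
#' @param stern ion-exclusion (Stern) layer width, Angstrom
#' @param require_cover error unless the grid covers the structure plus a
#'   2 Angstrom margin (disable for focused sub-grids)
#' @return object of class \code{dielectric_map}: edge dielectrics
#'   \code{eps_x,eps_y,eps_z}, node screening \code{kappa2eps}
#'   (eps/lambda_D^2, zero where ion-inaccessible), the grid and parameters
#' @export
build_dielectric_map <- function(structure, grid, eps_in = 4, eps_out = 80,
                                 ionic_strength = 0.1, T = 300, stern = 2,
                                 require_cover = TRUE) {
  if (!is.null(structure) && require_cover) {
    a <- structure$atoms
    lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius))
    hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius))
    if (!grid_contains(grid, rbind(lo, hi), clearance = -1e-9) ||
        !grid_contains(grid, rbind(lo - 2, hi + 2), clearance = -1e-9))
      stop("grid does not cover the structure plus a 2 Angstrom margin")
  }
  sdf <- sdf_grid(grid, structure)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  dim(sdf) <- c(nx, ny, nz)
  edge_eps <- function(s1, s2) {
    e <- ifelse(s1 > 0 & s2 > 0, eps_out,
         ifelse(s1 <= 0 & s2 <= 0, eps_in, NA))
    cross <- is.na(e)
    if (any(cross)) {
      f_in <- pmin(pmax(pmax(-s1[cross], -s2[cross]) /
                        (abs(s1[cross]) + abs(s2[cross])), 0), 1)
      e[cross] <- 1 / (f_in / eps_in + (1 - f_in) / eps_out)
    }
    e
  }
  eps_x <- edge_eps(sdf[-nx, , ], sdf[-1, , ])
  eps_y <- edge_eps(sdf[, -ny, ], sdf[, -1, ])
  eps_z <- edge_eps(sdf[, , -nz], sdf[, , -1])
  lam <- debye_length(ionic_strength, T, eps_out)
  k2e <- if (is.finite(lam)) eps_out / lam^2 else 0
  kappa2eps <- ifelse(as.vector(sdf) > stern, k2e, 0)
  structure(list(eps_x = as.vector(eps_x), eps_y = as.vector(eps_y),
                 eps_z = as.vector(eps_z), kappa2eps = kappa2eps,
                 grid = grid, sdf = as.vector(sdf),
                 eps_in = eps_in, eps_out = eps_out,
                 ionic_strength = ionic_strength, T = T, stern = stern),
            class = "dielectric_map")
}

#' Export a potential grid in OpenDX scalar-field format
#' @param pgrid a \code{pb_potential} (finest level is written) or a list
#'   with \code{phi} and \code{grid}
#' @param path output path
#' @param unit "kcal" (kcal/mol/e, native) or "mV"
#' @export
write_dx <- function(pgrid, path, unit = c("kcal", "mV")) {
  unit <- match.arg(unit)
  lev <- if (inherits(pgrid, "pb_potential")) pgrid$levels[[length(pgrid$levels)]] else pgrid
  g <- lev$grid
  phi <- lev$phi
  if (unit == "mV") phi <- phi * PHYS$mV_per_kcal
  n <- g$dim
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX scalar field (potential, %s)", unit),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0 0", g$spacing),
    sprintf("delta 0 %.6f 0", g$spacing),
    sprintf("delta 0 0 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  # OpenDX expects z-fastest ordering
  arr <- array(phi, n)
  vals <- as.vector(aperm(arr, c(3, 2, 1)))
  pad <- c(vals, rep(NA, (3 - length(vals) %% 3) %% 3))
  m <- matrix(pad, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(v)
    paste(sprintf("%.6e", v[!is.na(v)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
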