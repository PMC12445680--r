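#' Fixed box for transmembrane field mapping
#'
#' A cubic box (default 120 Angstrom edge, 76^3 ~ 4.4e5 nodes) centred on the
#' origin with Dirichlet 0 V on its faces, used to solve the plain Poisson
#' equation (no ionic screening) for the potential generated by the protein
#' charges.
#'
#' @param edge box edge, Angstrom
#' @param n nodes per axis (76 gives ~450,000 grid points)
#' @return a \code{grid_spec}
#' @export
field_box <- function(edge = 120, n = 76) {
  grid_spec(rep(-edge / 2, 3), edge / (n - 1), rep(n, 3))
}

#' Gaussian-smeared charge density on a field box
#'
#' Each atomic partial charge becomes a Gaussian of standard deviation
#' \code{sigma} (default 1 Angstrom), sampled on the grid and renormalized
#' per atom so total charge is conserved exactly.
#'
#' @param structure a \code{pb_structure}
#' @param box a \code{grid_spec} from \code{\link{field_box}}
#' @param sigma Gaussian width, Angstrom
#' @param cutoff truncation radius in sigmas
#' @return flattened node-charge vector (e)
#' @export
smear_charges <- function(structure, box, sigma = 1, cutoff = 4) {
  a <- structure$atoms
  hi <- grid_hi(box)
  margin <- 3 * sigma
  bad <- a$x < box$origin[1] + margin | a$x > hi[1] - margin |
         a$y < box$origin[2] + margin | a$y > hi[2] - margin |
         a$z < box$origin[3] + margin | a$z > hi[3] - margin
  if (any(bad & a$charge != 0))
    stop("charged atoms outside the box minus 3 sigma margin: ",
         paste(a$atom_id[bad & a$charge != 0], collapse = ", "))
  ax <- grid_axes(box)
  nx <- box$dim[1]; ny <- box$dim[2]
  rho <- numeric(grid_n(box))
  R <- cutoff * sigma
  for (k in which(a$charge != 0)) {
    ix <- which(abs(ax$x - a$x[k]) <= R)
    iy <- which(abs(ax$y - a$y[k]) <= R)
    iz <- which(abs(ax$z - a$z[k]) <= R)
    wx <- exp(-(ax$x[ix] - a$x[k])^2 / (2 * sigma^2))
    wy <- exp(-(ax$y[iy] - a$y[k])^2 / (2 * sigma^2))
    wz <- exp(-(ax$z[iz] - a$z[k])^2 / (2 * sigma^2))
    w <- outer(outer(wx, wy), wz)
    w <- w / sum(w) * a$charge[k]
    idx <- as.vector(outer(outer(ix, (iy - 1) * nx, "+"), (iz - 1) * nx * ny, "+"))
    rho[idx] <- rho[idx] + as.vector(w)
  }
  rho
}

#' Solve the Poisson equation on a field box
#'
#' Dielectric 4 inside the protein van der Waals union and inside an
#' optional membrane slab, 80 in bulk water; no ionic screening; 0 V
#' Dirichlet on all six faces (the z = +-60 Angstrom planes per the
#' transmembrane convention, with symmetric lateral closure).  The field
#' E = -grad(phi) is taken by central differences.
#'
#' @param rho flattened node charges from \code{\link{smear_charges}}
#' @param box the \code{grid_spec}
#' @param structure structure defining the protein dielectric region (NULL
#'   for uniform \code{eps_out})
#' @param membrane_z optional numeric(2): z range treated as membrane
#'   (eps_in) regardless of atoms
#' @param eps_in,eps_out dielectrics (4 / 80)
#' @param tol,maxit solver controls
#' @return list: \code{potential} (solution with \code{phi}, \code{grid}),
#'   \code{Ex,Ey,Ez} (flattened, kcal/mol/e/Angstrom)
#' @export
solve_field <- function(rho, box, structure = NULL, membrane_z = NULL,
                        eps_in = 4, eps_out = 80, tol = 1e-6, maxit = 10000) {
  dmap <- build_dielectric_map(structure, box, eps_in = eps_in,
                               eps_out = eps_out, ionic_strength = 0,
                               require_cover = FALSE)
  if (!is.null(membrane_z)) {
    ax <- grid_axes(box)
    nx <- box$dim[1]; ny <- box$dim[2]; nz <- box$dim[3]
    in_slab <- function(z) z >= membrane_z[1] & z <= membrane_z[2]
    node_z <- rep(ax$z, each = nx * ny)
    zmask <- in_slab(node_z)
    dim(zmask) <- c(nx, ny, nz)
    mx <- zmask[-nx, , ] & zmask[-1, , ]
    my <- zmask[, -ny, ] & zmask[, -1, ]
    mz <- zmask[, , -nz] & zmask[, , -1]
    dmap$eps_x[as.vector(mx)] <- eps_in
    dmap$eps_y[as.vector(my)] <- eps_in
    dmap$eps_z[as.vector(mz)] <- eps_in
  }
  sol <- solve_lpb(dmap, bc = "zero", rho = rho, tol = tol, maxit = maxit)
  h <- box$spacing
  phi <- array(sol$phi, box$dim)
  grad <- function(arr, d) {
    n <- dim(arr)[d]
    idx1 <- 1:n; lo <- pmax(idx1 - 1, 1); hi <- pmin(idx1 + 1, n)
    sl <- function(i) switch(d, arr[i, , , drop = FALSE],
                             arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
    (sl(hi) - sl(lo)) / ((hi - lo) * h)
  }
  list(potential = sol,
       Ex = -as.vector(grad(phi, 1)),
       Ey = -as.vector(grad(phi, 2)),
       Ez = -as.vector(grad(phi, 3)))
}

#' Export an axis-aligned slice of a field solution
#'
#' @param field result of \code{\link{solve_field}}
#' @param axis "x", "y" or "z": the axis normal to the slice
#' @param value coordinate of the slice plane, Angstrom
#' @param unit "mV" or "kcal" for the potential column
#' @return data.frame with the two in-plane coordinates, phi, and the field
#'   components
#' @export
field_slice <- function(field, axis = "x", value = 0, unit = c("mV", "kcal")) {
  unit <- match.arg(unit)
  g <- field$potential$grid
  ax <- grid_axes(g)
  d <- match(axis, c("x", "y", "z"))
  i0 <- which.min(abs(ax[[d]] - value))
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  pick <- function(v) {
    arr <- array(v, g$dim)
    switch(d, arr[i0, , ], arr[, i0, ], arr[, , i0])
  }
  others <- setdiff(1:3, d)
  u <- rep(ax[[others[1]]], times = g$dim[others[2]])
  v <- rep(ax[[others[2]]], each = g$dim[others[1]])
  conv <- if (unit == "mV") PHYS$mV_per_kcal else 1
  out <- data.frame(u = u, v = v,
                    phi = as.vector(pick(field$potential$phi)) * conv,
                    Ex = as.vector(pick(field$Ex)),
                    Ey = as.vector(pick(field$Ey)),
                    Ez = as.vector(pick(field$Ez)))
  names(out)[1:2] <- c("x", "y", "z")[others]
  out
}
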