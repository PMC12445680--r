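#' Debye screening length
#'
#' lambda_D = sqrt(eps eps0 kB T / (2 NA e^2 I)); about 9.7 Angstrom for
#' 100 mM 1:1 salt in water at 298 K.
#'
#' @param I ionic strength, mol/L (>= 0; 0 gives Inf, i.e. no screening)
#' @param T temperature, K
#' @param eps relative dielectric of the solvent
#' @return Debye length in Angstrom
#' @export
debye_length <- function(I, T = 300, eps = 80) {
  if (I < 0) stop("ionic strength must be >= 0")
  if (I == 0) return(Inf)
  lam2 <- eps * PHYS$eps0_SI * PHYS$kB_SI * T /
    (2 * PHYS$NA_SI * PHYS$e_SI^2 * I * 1000)
  sqrt(lam2) * 1e10
}

#' Solve the linearized Poisson-Boltzmann equation on one grid
#'
#' Seven-point finite-difference discretization of
#' div(eps grad phi) - eps kappa^2 phi = -4 pi C rho with face-centred
#' dielectrics, solved by Jacobi-preconditioned conjugate gradients to a
#' relative residual of \code{tol}.  Potential is in kcal/mol/e.
#'
#' @param dmap a \code{dielectric_map}
#' @param charges data.frame/list with x, y, z (Angstrom) and q (e); may be
#'   NULL (no sources)
#' @param bc boundary rule: "zero", "dh" (sum of per-atom Debye-Hueckel
#'   monopoles in the solvent dielectric), or "dirichlet" (values supplied in
#'   \code{phi_bc})
#' @param phi_bc flattened node vector; only boundary values are used
#' @param tol relative residual tolerance
#' @param maxit iteration cap; non-convergence is an error carrying the
#'   residual history
#' @param rho optional pre-computed flattened node charges (e), bypassing
#'   the trilinear spreading of \code{charges} (used for smeared densities)
#' @return list with \code{phi} (flattened node potentials, boundary values
#'   included), \code{grid}, \code{iterations}, \code{residual}
#' @export
solve_lpb <- function(dmap, charges = NULL, bc = c("zero", "dh", "dirichlet"),
                      phi_bc = NULL, tol = 1e-6, maxit = 10000, rho = NULL) {
  bc <- match.arg(bc)
  g <- dmap$grid
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  N <- grid_n(g); h <- g$spacing

  if (is.null(rho))
    rho <- if (is.null(charges) || length(charges$q) == 0) numeric(N) else
      trilinear_spread(g, cbind(charges$x, charges$y, charges$z), charges$q)

  if (bc == "zero") {
    phi_b <- numeric(N)
  } else if (bc == "dirichlet") {
    if (is.null(phi_bc)) stop("bc='dirichlet' needs phi_bc")
    phi_b <- phi_bc
  } else {
    if (is.null(charges)) stop("bc='dh' needs source charges")
    phi_b <- dh_boundary(g, charges, dmap$eps_out,
                         debye_length(dmap$ionic_strength, dmap$T, dmap$eps_out))
  }

  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  boundary <- ix == 1 | ix == nx | iy == 1 | iy == ny | iz == 1 | iz == nz
  interior <- which(!boundary)
  n_int <- length(interior)
  gi <- integer(N); gi[interior] <- seq_len(n_int)

  d <- numeric(N)                    # diagonal accumulation (all nodes)
  b <- 4 * pi * PHYS$coulomb * rho   # RHS before bc lifting
  ti <- tj <- tx <- vector("list", 3)
  edge_dirs <- list(
    list(w = dmap$eps_x * h, stride = 1L,
         i1 = which(ix <= nx - 1L)),
    list(w = dmap$eps_y * h, stride = nx,
         i1 = which(iy <= ny - 1L)),
    list(w = dmap$eps_z * h, stride = nx * ny,
         i1 = which(iz <= nz - 1L)))
  for (k in 1:3) {
    e <- edge_dirs[[k]]
    i1 <- e$i1; i2 <- i1 + e$stride; w <- e$w
    d[i1] <- d[i1] + w
    d[i2] <- d[i2] + w
    both <- !boundary[i1] & !boundary[i2]
    ti[[k]] <- c(gi[i1[both]], gi[i2[both]])
    tj[[k]] <- c(gi[i2[both]], gi[i1[both]])
    tx[[k]] <- c(-w[both], -w[both])
    b1 <- !boundary[i1] & boundary[i2]
    b[i1[b1]] <- b[i1[b1]] + w[b1] * phi_b[i2[b1]]
    b2 <- boundary[i1] & !boundary[i2]
    b[i2[b2]] <- b[i2[b2]] + w[b2] * phi_b[i1[b2]]
  }
  d <- d + h^3 * dmap$kappa2eps
  A <- Matrix::sparseMatrix(
    i = c(unlist(ti), seq_len(n_int)),
    j = c(unlist(tj), seq_len(n_int)),
    x = c(unlist(tx), d[interior]),
    dims = c(n_int, n_int))
  rhs <- b[interior]

  sol <- cg_solve(A, rhs, Minv = 1 / d[interior], tol = tol, maxit = maxit)
  phi <- phi_b
  phi[interior] <- sol$x
  list(phi = phi, grid = g, iterations = sol$iterations,
       residual = sol$residual)
}

# Debye-Hueckel monopole boundary values on the grid faces (zero elsewhere)
dh_boundary <- function(g, charges, eps_out, lambda) {
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  N <- grid_n(g)
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  bidx <- which(ix == 1 | ix == nx | iy == 1 | iy == ny | iz == 1 | iz == nz)
  px <- g$origin[1] + (ix[bidx] - 1) * g$spacing
  py <- g$origin[2] + (iy[bidx] - 1) * g$spacing
  pz <- g$origin[3] + (iz[bidx] - 1) * g$spacing
  phi <- numeric(length(bidx))
  qs <- charges$q
  for (k in seq_along(qs)) {
    if (qs[k] == 0) next
    r <- sqrt((px - charges$x[k])^2 + (py - charges$y[k])^2 +
              (pz - charges$z[k])^2)
    r <- pmax(r, 1e-6)
    scr <- if (is.finite(lambda)) exp(-r / lambda) else 1
    phi <- phi + PHYS$coulomb * qs[k] * scr / (eps_out * r)
  }
  out <- numeric(N)
  out[bidx] <- phi
  out
}

# Jacobi-preconditioned conjugate gradients for SPD sparse systems
cg_solve <- function(A, b, Minv, tol = 1e-6, maxit = 10000) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), iterations = 0L, residual = 0))
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    hist <- c(hist, res)
    if (res <= tol)
      return(list(x = x, iterations = it, residual = res))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  err <- simpleError(sprintf(
    "PB solver did not converge in %d iterations (residual %.3e)", maxit,
    hist[length(hist)]))
  err$residual_history <- hist
  stop(err)
}

#' Focused multi-level solution of the LPB equation
#'
#' Classic grid focusing: the coarsest level covers the whole structure and
#' uses Debye-Hueckel monopole boundary values; each finer level is centred
#' on the region of interest and takes Dirichlet boundary values interpolated
#' from its parent.  Only charges lying inside a level (with one-spacing
#' clearance) are spread on that level; contributions of the rest enter
#' through the boundary condition.
#'
#' @param structure a \code{pb_structure} defining the dielectric boundary
#'   (NULL for uniform solvent)
#' @param charges data.frame with x, y, z, q
#' @param center numeric(3), centre of the region of interest
#' @param radius half-width of the region of interest (Angstrom); it must fit
#'   inside every level
#' @param levels grid spacings from coarse to fine, Angstrom
#'   (default c(2.5, 1.0, 0.3), the three-step focusing protocol)
#' @param eps_in,eps_out,ionic_strength,T,stern dielectric/screening
#'   parameters, see \code{\link{build_dielectric_map}}
#' @param coarse_margin clearance around the structure on the coarsest level
#' @param fine_margin clearance added to \code{radius} on focused levels
#' @param tol,maxit solver controls
#' @return object of class \code{pb_potential}: \code{levels} is a list of
#'   per-level solutions (finest last)
#' @export
focus_solve <- function(structure, charges, center, radius,
                        levels = c(2.5, 1.0, 0.3),
                        eps_in = 4, eps_out = 80, ionic_strength = 0.1,
                        T = 300, stern = 2, coarse_margin = 10,
                        fine_margin = 3, tol = 1e-6, maxit = 10000) {
  stopifnot(length(levels) >= 1)
  if (!is.null(structure)) {
    a <- structure$atoms
    lo <- c(min(a$x), min(a$y), min(a$z)); hi <- c(max(a$x), max(a$y), max(a$z))
  } else {
    lo <- center - radius; hi <- center + radius
  }
  lo <- pmin(lo, center - radius); hi <- pmax(hi, center + radius)
  sols <- vector("list", length(levels))
  parent <- NULL
  for (l in seq_along(levels)) {
    h <- levels[l]
    if (l == 1) {
      g <- grid_covering(lo, hi, h, margin = coarse_margin)
    } else {
      # nest strictly: deeper levels get smaller margins so rounding of the
      # grid extent can never push a child outside its parent
      g <- grid_covering(center - radius, center + radius, h,
                         margin = fine_margin * (length(levels) - l + 1) + h)
      if (!grid_contains(parent$grid,
                         rbind(g$origin, grid_hi(g)), clearance = 0))
        stop("focus level ", l, " is not contained in its parent grid")
    }
    if (!grid_contains(g, rbind(center - radius, center + radius)))
      stop("region of interest clipped by focus level ", l)
    dmap <- build_dielectric_map(structure, g, eps_in = eps_in,
                                 eps_out = eps_out,
                                 ionic_strength = ionic_strength, T = T,
                                 stern = stern, require_cover = FALSE)
    ch_l <- charges_within(charges, g)
    if (l == 1) {
      sol <- solve_lpb(dmap, charges, bc = if (is.null(charges)) "zero" else "dh",
                       tol = tol, maxit = maxit)
    } else {
      phi_bc <- boundary_from_parent(g, parent)
      sol <- solve_lpb(dmap, ch_l, bc = "dirichlet", phi_bc = phi_bc,
                       tol = tol, maxit = maxit)
    }
    sols[[l]] <- sol
    parent <- sol
  }
  structure(list(levels = sols, center = center, radius = radius),
            class = "pb_potential")
}

charges_within <- function(charges, g) {
  if (is.null(charges)) return(NULL)
  pts <- cbind(charges$x, charges$y, charges$z)
  hi <- grid_hi(g)
  keep <- pts[, 1] > g$origin[1] + g$spacing & pts[, 1] < hi[1] - g$spacing &
          pts[, 2] > g$origin[2] + g$spacing & pts[, 2] < hi[2] - g$spacing &
          pts[, 3] > g$origin[3] + g$spacing & pts[, 3] < hi[3] - g$spacing
  list(x = charges$x[keep], y = charges$y[keep], z = charges$z[keep],
       q = charges$q[keep])
}

boundary_from_parent <- function(g, parent) {
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  bidx <- which(ix == 1 | ix == nx | iy == 1 | iy == ny | iz == 1 | iz == nz)
  pts <- cbind(g$origin[1] + (ix[bidx] - 1) * g$spacing,
               g$origin[2] + (iy[bidx] - 1) * g$spacing,
               g$origin[3] + (iz[bidx] - 1) * g$spacing)
  phi <- numeric(grid_n(g))
  phi[bidx] <- trilinear_interp(parent$grid, parent$phi, pts)
  phi
}

#' Evaluate a (possibly multi-level) potential at points
#'
#' Uses the finest level whose grid contains each point.
#'
#' @param pot a \code{pb_potential} from \code{\link{focus_solve}}, or a
#'   single-level solution from \code{\link{solve_lpb}}
#' @param points m x 3 matrix
#' @param unit "kcal" (kcal/mol/e) or "mV"
#' @return numeric(m)
#' @export
potential_at <- function(pot, points, unit = c("kcal", "mV")) {
  unit <- match.arg(unit)
  points <- matrix(points, ncol = 3)
  levs <- if (inherits(pot, "pb_potential")) pot$levels else list(pot)
  out <- rep(NA_real_, nrow(points))
  for (l in seq_along(levs)) {   # coarse to fine; finest wins
    g <- levs[[l]]$grid
    hi <- grid_hi(g)
    inside <- points[, 1] >= g$origin[1] & points[, 1] <= hi[1] &
              points[, 2] >= g$origin[2] & points[, 2] <= hi[2] &
              points[, 3] >= g$origin[3] & points[, 3] <= hi[3]
    if (any(inside))
      out[inside] <- trilinear_interp(g, levs[[l]]$phi,
                                      points[inside, , drop = FALSE])
  }
  if (anyNA(out)) stop("some points outside all potential grids")
  if (unit == "mV") out <- out * PHYS$mV_per_kcal
  out
}

#' Reaction-field potential of a charge set
#'
#' phi_RF = phi(inhomogeneous dielectric) - phi(uniform eps_in reference),
#' both on the same finest grid so the grid self-energy of the spread
#' charges cancels exactly.  The homogeneous reference is solved with
#' analytic Coulomb Dirichlet boundary values.
#'
#' @inheritParams focus_solve
#' @param eval_points m x 3 matrix where the reaction field is needed
#' @return numeric(m), kcal/mol/e
#' @export
reaction_field_at <- function(structure, charges, center, radius, eval_points,
                              levels = c(2.5, 1.0, 0.3), eps_in = 4,
                              eps_out = 80, ionic_strength = 0.1, T = 300,
                              stern = 2, tol = 1e-6, maxit = 10000) {
  pot <- focus_solve(structure, charges, center, radius, levels = levels,
                     eps_in = eps_in, eps_out = eps_out,
                     ionic_strength = ionic_strength, T = T, stern = stern,
                     tol = tol, maxit = maxit)
  fin <- pot$levels[[length(pot$levels)]]
  g <- fin$grid
  hom <- homogeneous_reference(g, charges, eps_in, tol = tol, maxit = maxit)
  phi_rf <- fin$phi - hom$phi
  trilinear_interp(g, phi_rf, matrix(eval_points, ncol = 3))
}

# Discrete Coulomb reference: uniform eps_ref, no screening, analytic
# Coulomb boundary values; same grid and charge spreading as the focused
# finest level, so self-energy artifacts cancel in differences.
homogeneous_reference <- function(g, charges, eps_ref, tol = 1e-6,
                                  maxit = 10000) {
  dmap <- uniform_dielectric_map(g, eps_ref)
  ch <- charges_within(charges, g)
  phi_bc <- dh_boundary(g, charges, eps_ref, Inf)
  solve_lpb(dmap, ch, bc = "dirichlet", phi_bc = phi_bc, tol = tol,
            maxit = maxit)
}

uniform_dielectric_map <- function(g, eps) {
  nx <- g$dim[1]; ny <- g$dim[2]; nz <- g$dim[3]
  structure(list(eps_x = rep(eps, (nx - 1) * ny * nz),
                 eps_y = rep(eps, nx * (ny - 1) * nz),
                 eps_z = rep(eps, nx * ny * (nz - 1)),
                 kappa2eps = numeric(nx * ny * nz),
                 grid = g, sdf = NULL, eps_in = eps, eps_out = eps,
                 ionic_strength = 0, T = 300, stern = 0),
            class = "dielectric_map")
}

#' Electrostatic charging energy of a site state change
#'
#' For the transition between two charge states of a titratable site, returns
#' the reaction-field (solvation) term and the background-interaction term
#' (with all non-titrating charges), the two legs of the thermodynamic cycle.
#' \code{environment="model"} strips the structure down to the site's own
#' atoms in water (the model compound).
#'
#' @param structure a \code{pb_structure}
#' @param site a \code{titratable_site}
#' @param states integer(2) or labels: the state pair (default reference and
#'   state 2)
#' @param environment "protein" or "model"
#' @param background data.frame x,y,z,q of non-titrating charges interacting
#'   with the site ("protein" environment only); NULL derives it from all
#'   structure atoms outside the site
#' @param levels,eps_in,eps_out,ionic_strength,T,stern,tol,maxit solver
#'   controls, see \code{\link{focus_solve}}
#' @param radius region-of-interest half-width around the site (default: site
#'   extent + 4 Angstrom)
#' @return list: \code{rf} and \code{back} (kcal/mol), their sum \code{total},
#'   and \code{phi_delta} (the multi-level potential of the state-difference
#'   charges, reusable for per-residue contributions)
#' @export
charging_energy <- function(structure, site, states = c(1, 2),
                            environment = c("protein", "model"),
                            background = NULL, levels = c(2.5, 1.0, 0.3),
                            eps_in = 4, eps_out = 80, ionic_strength = 0.1,
                            T = 300, stern = 2, radius = NULL,
                            tol = 1e-6, maxit = 10000) {
  environment <- match.arg(environment)
  if (is.character(states))
    states <- match(states, rownames(site$state_charges))
  a <- structure$atoms
  midx <- site$member_atoms
  pos <- cbind(a$x[midx], a$y[midx], a$z[midx])
  q1 <- site$state_charges[states[1], ]
  q2 <- site$state_charges[states[2], ]
  dq <- q2 - q1
  center <- colMeans(pos)
  if (is.null(radius))
    radius <- max(sqrt(rowSums(sweep(pos, 2, center)^2))) + 4

  env_structure <- if (environment == "protein") structure else
    pb_structure(a[midx, , drop = FALSE])
  if (environment == "protein") {
    if (is.null(background)) {
      rest <- setdiff(seq_len(nrow(a)), midx)
      background <- data.frame(x = a$x[rest], y = a$y[rest], z = a$z[rest],
                               q = a$charge[rest])
      background <- background[background$q != 0, , drop = FALSE]
    }
  } else background <- NULL

  opts <- list(levels = levels, eps_in = eps_in, eps_out = eps_out,
               ionic_strength = ionic_strength, T = T, stern = stern,
               tol = tol, maxit = maxit)

  # phi of the state-difference charges (inhomogeneous + homogeneous ref)
  ch_d <- list(x = pos[, 1], y = pos[, 2], z = pos[, 3], q = dq)
  pot_d <- do.call(focus_solve, c(list(env_structure, ch_d, center, radius), opts))
  fin <- pot_d$levels[[length(pot_d$levels)]]
  hom_d <- homogeneous_reference(fin$grid, ch_d, eps_in, tol = tol,
                                 maxit = maxit)

  if (all(abs(q1) < 1e-12)) {      # reference state uncharged: reuse phi_delta
    phi_rf_site <- trilinear_interp(fin$grid, fin$phi - hom_d$phi, pos)
    rf <- 0.5 * sum(dq * phi_rf_site)
  } else {
    ch_s <- list(x = pos[, 1], y = pos[, 2], z = pos[, 3], q = q1 + q2)
    pot_s <- do.call(focus_solve, c(list(env_structure, ch_s, center, radius), opts))
    fin_s <- pot_s$levels[[length(pot_s$levels)]]
    hom_s <- homogeneous_reference(fin_s$grid, ch_s, eps_in, tol = tol,
                                   maxit = maxit)
    phi_rf_site <- trilinear_interp(fin_s$grid, fin_s$phi - hom_s$phi, pos)
    rf <- 0.5 * sum(dq * phi_rf_site)
  }

  back <- 0
  if (!is.null(background) && nrow(background) > 0) {
    phi_at_back <- potential_at(pot_d, cbind(background$x, background$y,
                                             background$z))
    back <- sum(background$q * phi_at_back)
  }
  list(rf = rf, back = back, total = rf + back, phi_delta = pot_d,
       background = background)
}

#' Pairwise interaction energy of two titratable sites
#'
#' W_AB: interaction of A's state-difference charges with B's, from the PB
#' potential of A evaluated at B (averaged over the two orderings unless
#' \code{symmetrize=FALSE}).
#'
#' @param structure a \code{pb_structure}
#' @param siteA,siteB \code{titratable_site}s (must not share atoms)
#' @param statesA,statesB state pair per site (default reference, 2)
#' @param symmetrize average W(A->B) and W(B->A)
#' @param ... solver options passed to \code{\link{focus_solve}}
#' @param levels,eps_in,eps_out,ionic_strength,T,stern,tol,maxit see
#'   \code{\link{focus_solve}}
#' @return W in kcal/mol
#' @export
interaction_energy <- function(structure, siteA, siteB,
                               statesA = c(1, 2), statesB = c(1, 2),
                               symmetrize = TRUE, levels = c(2.5, 1.0, 0.3),
                               eps_in = 4, eps_out = 80, ionic_strength = 0.1,
                               T = 300, stern = 2, tol = 1e-6, maxit = 10000) {
  if (length(intersect(siteA$member_atoms, siteB$member_atoms)) > 0)
    stop("sites share atoms")
  a <- structure$atoms
  one_way <- function(sA, stA, sB, stB) {
    pA <- cbind(a$x[sA$member_atoms], a$y[sA$member_atoms], a$z[sA$member_atoms])
    pB <- cbind(a$x[sB$member_atoms], a$y[sB$member_atoms], a$z[sB$member_atoms])
    dqA <- site_delta_charges(sA, stA[2]) - site_delta_charges(sA, stA[1])
    dqB <- site_delta_charges(sB, stB[2]) - site_delta_charges(sB, stB[1])
    center <- colMeans(pA)
    radius <- max(sqrt(rowSums(sweep(pA, 2, center)^2))) + 4
    pot <- focus_solve(structure, list(x = pA[, 1], y = pA[, 2], z = pA[, 3],
                                       q = dqA),
                       center, radius, levels = levels, eps_in = eps_in,
                       eps_out = eps_out, ionic_strength = ionic_strength,
                       T = T, stern = stern, tol = tol, maxit = maxit)
    sum(dqB * potential_at(pot, pB))
  }
  w <- one_way(siteA, statesA, siteB, statesB)
  if (symmetrize)
    w <- (w + one_way(siteB, statesB, siteA, statesA)) / 2
  w
}

#' Screened Coulomb interaction in a uniform medium
#'
#' The closed form the PB solver must reproduce in uniform dielectric:
#' W = C q1 q2 exp(-r/lambda) / (eps r), kcal/mol.
#'
#' @param r separation, Angstrom
#' @param q1,q2 charges, e
#' @param eps dielectric
#' @param lambda Debye length, Angstrom (Inf for no screening)
#' @export
coulomb_energy <- function(r, q1 = 1, q2 = 1, eps = 80, lambda = Inf) {
  scr <- if (is.finite(lambda)) exp(-r / lambda) else 1
  PHYS$coulomb * q1 * q2 * scr / (eps * r)
}

#' Analytic Born reaction-field energy
#'
#' W = -(C/2) q^2 / a (1/eps_in - 1/eps_out); -81.96 kcal/mol for a unit
#' charge in a 2 Angstrom cavity transferred from eps 1 to 80.
#'
#' @param q charge, e
#' @param a cavity radius, Angstrom
#' @param eps_in,eps_out dielectrics
#' @export
born_energy <- function(q, a, eps_in = 1, eps_out = 80) {
  -(PHYS$coulomb / 2) * q^2 / a * (1 / eps_in - 1 / eps_out)
}
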