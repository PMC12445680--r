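#' Titration conditions
#'
#' @param pH solution pH (default 7.0)
#' @param E_mV solution redox potential / bias potential vs NHE, mV
#' @param T temperature, K (default 300)
#' @param ionic_strength mol/L (default 0.1)
#' @return object of class \code{titration_conditions}
#' @export
titration_conditions <- function(pH = 7.0, E_mV = 0, T = 300,
                                 ionic_strength = 0.1) {
  if (T <= 0) stop("temperature must be > 0")
  structure(list(pH = pH, E_mV = E_mV, T = T,
                 ionic_strength = ionic_strength),
            class = "titration_conditions")
}

#' Assemble site energetics
#'
#' Container for intrinsic values plus the site-site interaction matrix W,
#' indexed by contiguous global state indices (one block per site, the
#' site's reference state first).
#'
#' @param sites list of \code{titratable_site}
#' @param intrinsic list, one element per site: scalar intrinsic pKa
#'   (acid/base), numeric(2) \code{c(Nd=, Ne=)} intrinsic tautomer pKa (His,
#'   for protonation at N-delta and deprotonation at N-epsilon), or scalar
#'   intrinsic Em in mV (redox)
#' @param W symmetric interaction matrix over global states, kcal/mol;
#'   rows/columns belonging to reference states must be zero
#' @return object of class \code{site_energetics}
#' @export
site_energetics <- function(sites, intrinsic, W) {
  n_states <- vapply(sites, function(s) nrow(s$state_charges), integer(1))
  offsets <- cumsum(c(0L, n_states[-length(n_states)]))
  S <- sum(n_states)
  if (is.null(W)) W <- matrix(0, S, S)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-8)))
    stop("W must be symmetric")
  if (any(abs(diag(W)) > 1e-12)) stop("W must have zero diagonal blocks")
  structure(list(sites = sites, intrinsic = intrinsic, W = W,
                 n_states = n_states, offsets = offsets,
                 site_ids = vapply(sites, `[[`, "", "site_id")),
            class = "site_energetics")
}

# Per-state free energies g (kcal/mol, relative to each site's reference
# state) at the given conditions.  Conventions: acid/base reference =
# deprotonated, g(prot) = RT ln10 (pH - pKa_intr); His reference = HIE,
# g(HIP) = RT ln10 (pH - pKa_Nd), g(HID) = g(HIP) + RT ln10 (pKa_Ne - pH);
# redox reference = reduced, g(ox) = (Em_intr - E) * 0.0230605 kcal/mol/mV.
state_energies <- function(en, cond) {
  rt <- RTln10(cond$T)
  g <- numeric(sum(en$n_states))
  for (i in seq_along(en$sites)) {
    s <- en$sites[[i]]
    o <- en$offsets[i]
    v <- en$intrinsic[[i]]
    if (s$kind %in% c("acid", "base")) {
      g[o + 2] <- rt * (cond$pH - v)
    } else if (s$kind == "his_tautomer") {
      g[o + 2] <- rt * (cond$pH - v[["Nd"]])
      g[o + 3] <- g[o + 2] + rt * (v[["Ne"]] - cond$pH)
    } else {
      g[o + 2] <- (v - cond$E_mV) * PHYS$kcal_per_mV
    }
  }
  g
}

# state bookkeeping: fixed-state index per site (NA if free)
fixed_index <- function(en) {
  vapply(en$sites, function(s) {
    if (is.null(s$fixed_state)) NA_integer_
    else match(s$fixed_state, rownames(s$state_charges))
  }, integer(1))
}

#' Exact Boltzmann enumeration of titration microstates
#'
#' Full partition-function sum over all microstates of the free sites
#' (fixed sites are clamped but still interact).  Serves as the oracle the
#' Monte Carlo sampler is validated against.
#'
#' @param en a \code{site_energetics}
#' @param cond a \code{titration_conditions}
#' @return object of class \code{titration_populations}: per-site state
#'   occupancies (named list of named numeric vectors), zero MC error,
#'   metadata
#' @export
enumerate_exact <- function(en, cond) {
  g <- state_energies(en, cond)
  if (any(!is.finite(g)) || any(!is.finite(en$W)))
    stop("non-finite site energetics")
  fx <- fixed_index(en)
  free <- which(is.na(fx))
  n_micro <- prod(en$n_states[free])
  if (n_micro > 2^20)
    stop("state space exceeds 2^20 microstates; use mc_titrate()")
  kT <- kT_kcal(cond$T)
  # global state index per site for every microstate
  grids <- lapply(seq_along(en$sites), function(i) {
    if (is.na(fx[i])) en$offsets[i] + seq_len(en$n_states[i])
    else en$offsets[i] + fx[i]
  })
  micro <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  G <- rowSums(matrix(g[micro], nrow = nrow(micro)))
  n <- length(en$sites)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      G <- G + en$W[cbind(micro[, i], micro[, j])]
    }
  }
  w <- exp(-(G - min(G)) / kT)
  w <- w / sum(w)
  occ <- lapply(seq_len(n), function(i) {
    o <- en$offsets[i]
    v <- vapply(seq_len(en$n_states[i]), function(s)
      sum(w[micro[, i] == o + s]), numeric(1))
    names(v) <- rownames(en$sites[[i]]$state_charges)
    v
  })
  names(occ) <- en$site_ids
  structure(list(occupancy = occ,
                 se = lapply(occ, function(v) v * 0),
                 meta = list(backend = "exact", conditions = cond,
                             n_microstates = n_micro)),
            class = "titration_populations")
}

#' Metropolis Monte Carlo titration
#'
#' Samples the same microstate energy as \code{\link{enumerate_exact}} with
#' single-site moves plus joint moves for strongly coupled pairs
#' (default |W| > 2.5 kcal/mol), 1000 burn-in sweeps and 1e5 production
#' sweeps by default.  Reproducible for a given seed.
#'
#' @param en a \code{site_energetics}
#' @param cond a \code{titration_conditions}
#' @param sweeps production sweeps
#' @param burn burn-in sweeps
#' @param seed RNG seed (mandatory)
#' @param pair_threshold |W| above which a site pair gets joint moves,
#'   kcal/mol
#' @param n_blocks blocks for the occupancy standard error
#' @return a \code{titration_populations} with per-state MC standard errors
#' @export
mc_titrate <- function(en, cond, sweeps = 1e5, burn = 1e3, seed,
                       pair_threshold = 2.5, n_blocks = 50) {
  if (missing(seed) || is.null(seed)) stop("mc_titrate() requires a seed")
  g <- state_energies(en, cond)
  if (any(!is.finite(g)) || any(!is.finite(en$W)))
    stop("non-finite site energetics")
  fx <- fixed_index(en)
  n <- length(en$sites)
  init <- integer(n)
  for (i in seq_len(n))
    init[i] <- en$offsets[i] + (if (is.na(fx[i])) 1L else fx[i]) - 1L
  pairs <- matrix(0L, 2, 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      bi <- en$offsets[i] + seq_len(en$n_states[i])
      bj <- en$offsets[j] + seq_len(en$n_states[j])
      if (max(abs(en$W[bi, bj])) > pair_threshold &&
          is.na(fx[i]) && is.na(fx[j]))
        pairs <- cbind(pairs, c(i - 1L, j - 1L))
    }
  }
  set.seed(seed)
  blocks <- mc_sample_cpp(en$n_states, en$offsets, g, en$W, init,
                          is_free = is.na(fx), sweeps = as.integer(sweeps),
                          burn = as.integer(burn), pairs = pairs,
                          kT = kT_kcal(cond$T), n_blocks = as.integer(n_blocks))
  means <- colMeans(blocks)
  ses <- apply(blocks, 2, stats::sd) / sqrt(nrow(blocks))
  occ <- se <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- en$offsets[i] + seq_len(en$n_states[i])
    occ[[i]] <- setNames(means[idx], rownames(en$sites[[i]]$state_charges))
    se[[i]] <- setNames(ses[idx], rownames(en$sites[[i]]$state_charges))
  }
  names(occ) <- names(se) <- en$site_ids
  structure(list(occupancy = occ, se = se,
                 meta = list(backend = "mc", conditions = cond,
                             sweeps = sweeps, burn = burn, seed = seed,
                             n_pair_moves = ncol(pairs))),
            class = "titration_populations")
}

#' Occupancy of one site state
#' @param pop a \code{titration_populations}
#' @param site_id site identifier
#' @param state state label or index
#' @export
occupancy <- function(pop, site_id, state) {
  v <- pop$occupancy[[site_id]]
  if (is.null(v)) stop("no site ", site_id)
  unname(if (is.character(state)) v[state] else v[[state]])
}

# protonated-state label per site kind (the state tracked by pKa curves)
protonated_state <- function(site) {
  switch(site$kind,
         acid = , base = "prot",
         his_tautomer = "HIP",
         stop("site ", site$site_id, " is not a protonatable site"))
}

#' Titration curve and pKa by Henderson-Hasselbalch crossing
#'
#' Computes the protonated fraction over a pH grid (exact enumeration or MC
#' backend), locates the half-protonation point by root finding (exact) or
#' monotone interpolation (MC), and reports the Hill slope at the midpoint.
#'
#' @param en a \code{site_energetics}
#' @param site_id which site
#' @param pH_grid pH values bracketing the transition
#' @param cond base conditions (pH is swept)
#' @param backend "exact" or "mc"
#' @param ... passed to \code{\link{mc_titrate}} when backend = "mc"
#' @return list: \code{pKa}, \code{hill}, \code{curve} (data.frame pH,
#'   protonated)
#' @export
pka_curve <- function(en, site_id, pH_grid = seq(0, 14, 0.25),
                      cond = titration_conditions(), backend = "exact", ...) {
  i <- match(site_id, en$site_ids)
  if (is.na(i)) stop("no site ", site_id)
  pstate <- protonated_state(en$sites[[i]])
  theta_at <- function(pH) {
    c2 <- cond; c2$pH <- pH
    pop <- if (backend == "exact") enumerate_exact(en, c2)
           else mc_titrate(en, c2, ...)
    occupancy(pop, site_id, pstate)
  }
  th <- vapply(pH_grid, theta_at, numeric(1))
  cross <- which(diff(sign(th - 0.5)) != 0)
  if (length(cross) == 0)
    stop("no half-protonation crossing in the pH grid; widen the range")
  k <- cross[1]
  if (backend == "exact") {
    pKa <- uniroot(function(p) theta_at(p) - 0.5,
                   c(pH_grid[k], pH_grid[k + 1]), tol = 1e-8)$root
  } else {
    pKa <- approx(th[c(k, k + 1)], pH_grid[c(k, k + 1)], xout = 0.5)$y
  }
  dp <- 0.05
  t1 <- theta_at(pKa - dp); t2 <- theta_at(pKa + dp)
  hill <- -(log10(t2 / (1 - t2)) - log10(t1 / (1 - t1))) / (2 * dp)
  list(pKa = pKa, hill = hill,
       curve = data.frame(pH = pH_grid, protonated = th))
}

#' Redox midpoint potential by bias-potential bisection
#'
#' Scans the solution potential E until the site's oxidized and reduced
#' populations are equal, all other titratable sites re-equilibrating at
#' every bias; the crossing bias is the Em (Nernst midpoint).
#'
#' @param en a \code{site_energetics}
#' @param site_id a redox site
#' @param bounds numeric(2) search window for E, mV; must bracket the
#'   midpoint
#' @param cond conditions (E_mV is swept)
#' @param backend "exact" (bisection to |occ-0.5| <= occ_tol) or "mc"
#' @param occ_tol occupancy tolerance at the returned bias
#' @param ... passed to \code{\link{mc_titrate}} when backend = "mc"
#' @return Em in mV
#' @export
em_midpoint <- function(en, site_id, bounds = c(0, 3000),
                        cond = titration_conditions(), backend = "exact",
                        occ_tol = 0.005, ...) {
  i <- match(site_id, en$site_ids)
  if (is.na(i)) stop("no site ", site_id)
  if (en$sites[[i]]$kind != "redox") stop(site_id, " is not a redox site")
  ox_at <- function(E) {
    c2 <- cond; c2$E_mV <- E
    pop <- if (backend == "exact") enumerate_exact(en, c2)
           else mc_titrate(en, c2, ...)
    occupancy(pop, site_id, "ox")
  }
  flo <- ox_at(bounds[1]) - 0.5; fhi <- ox_at(bounds[2]) - 0.5
  if (flo * fhi > 0)
    stop("search bounds [", bounds[1], ", ", bounds[2],
         "] mV do not bracket the midpoint")
  lo <- bounds[1]; hi <- bounds[2]
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    f <- ox_at(mid) - 0.5
    if (abs(f) <= occ_tol && (hi - lo) < 0.02) return(mid)
    if (f * flo <= 0) hi <- mid else { lo <- mid; flo <- f }
    if ((hi - lo) < 1e-6) return((lo + hi) / 2)
  }
  (lo + hi) / 2
}
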