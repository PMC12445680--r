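#' Intrinsic pKa/Em values and interaction matrix from PB calculations
#'
#' For every titratable site, runs the thermodynamic cycle between the
#' protein and the model compound (the site's own atoms in water): the shift
#' in charging free energy — reaction-field (solvation) term plus
#' background-charge term — is added to the reference pKa/Em.  Background
#' charges are all non-titrating atom charges plus the other sites clamped in
#' their reference states; pairwise couplings W between non-reference states
#' are read off the already-solved state-difference potentials (symmetrized
#' over the two orderings).
#'
#' @param structure a \code{pb_structure}
#' @param sites list of \code{titratable_site}
#' @param levels focusing spacings, coarse to fine (default c(2.5, 1.0, 0.3))
#' @param eps_in,eps_out,ionic_strength,T,stern,tol,maxit solver parameters,
#'   see \code{\link{focus_solve}}
#' @param compute_W compute the pairwise interaction matrix (skip for single
#'   sites)
#' @param verbose print per-site progress
#' @return a \code{site_energetics}; \code{$detail} holds per-site cycle
#'   terms (rf_prot, rf_model, back_prot, per-state, kcal/mol) and the
#'   state-difference potentials reused by the Em-shift decomposition
#' @export
intrinsic_values <- function(structure, sites, levels = c(2.5, 1.0, 0.3),
                             eps_in = 4, eps_out = 80, ionic_strength = 0.1,
                             T = 300, stern = 2, tol = 1e-6, maxit = 10000,
                             compute_W = TRUE, verbose = FALSE) {
  a <- structure$atoms
  n <- length(sites)
  # background charge vector: structure charges with every site's member
  # atoms replaced by that site's reference-state charges
  q_bg <- a$charge
  for (s in sites) q_bg[s$member_atoms] <- s$state_charges[1, ]
  opts <- list(levels = levels, eps_in = eps_in, eps_out = eps_out,
               ionic_strength = ionic_strength, T = T, stern = stern,
               tol = tol, maxit = maxit)

  detail <- vector("list", n)
  intr <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sites[[i]]
    if (verbose) message("site ", s$site_id)
    rest <- setdiff(seq_len(nrow(a)), s$member_atoms)
    bg <- if (length(rest) == 0) {
      data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                 q = numeric(0), residue = character(0))
    } else {
      data.frame(x = a$x[rest], y = a$y[rest], z = a$z[rest],
                 q = q_bg[rest],
                 residue = paste0(a$residue_name[rest], "-",
                                  a$chain_id[rest], ":",
                                  a$residue_number[rest]))
    }
    bg <- bg[bg$q != 0, , drop = FALSE]
    ns <- nrow(s$state_charges)
    dd <- rf_p <- rf_m <- bk_p <- numeric(ns)   # index = state, 1 is ref
    phi_d <- vector("list", ns)
    for (st in 2:ns) {
      ce_p <- do.call(charging_energy,
                      c(list(structure, s, states = c(1, st),
                             environment = "protein", background = bg), opts))
      ce_m <- do.call(charging_energy,
                      c(list(structure, s, states = c(1, st),
                             environment = "model"), opts))
      rf_p[st] <- ce_p$rf; rf_m[st] <- ce_m$rf; bk_p[st] <- ce_p$back
      dd[st] <- ce_p$total - ce_m$total
      phi_d[[st]] <- ce_p$phi_delta
    }
    rt <- RTln10(T)
    intr[[i]] <- switch(s$kind,
      acid = ,
      base = s$reference - dd[2] / rt,              # state 2 = protonation
      his_tautomer = c(Nd = unname(s$reference["Nd"]) - dd[2] / rt,
                       Ne = unname(s$reference["Ne"]) +
                            (dd[3] - dd[2]) / rt),  # HIP -> HID deprotonation
      redox = s$reference + dd[2] * PHYS$mV_per_kcal)
    detail[[i]] <- list(rf_prot = rf_p, rf_model = rf_m, back_prot = bk_p,
                        ddG = dd, phi_delta = phi_d, background = bg)
  }

  n_states <- vapply(sites, function(s) nrow(s$state_charges), integer(1))
  offsets <- cumsum(c(0L, n_states[-n]))
  S <- sum(n_states)
  W <- matrix(0, S, S)
  if (compute_W && n > 1) {
    pos_of <- function(s) cbind(a$x[s$member_atoms], a$y[s$member_atoms],
                                a$z[s$member_atoms])
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      si <- sites[[i]]; sj <- sites[[j]]
      for (ai in 2:n_states[i]) for (bj in 2:n_states[j]) {
        wij <- sum(site_delta_charges(sj, bj) *
                   potential_at(detail[[i]]$phi_delta[[ai]], pos_of(sj)))
        wji <- sum(site_delta_charges(si, ai) *
                   potential_at(detail[[j]]$phi_delta[[bj]], pos_of(si)))
        w <- (wij + wji) / 2
        W[offsets[i] + ai, offsets[j] + bj] <- w
        W[offsets[j] + bj, offsets[i] + ai] <- w
      }
    }
  }
  en <- site_energetics(sites, intr, W)
  en$detail <- detail
  en$pb_options <- opts
  en
}

#' Site energetics of a cluster in uniform solvent (closed form)
#'
#' For fixtures whose sites sit in pure water the PB problem has the exact
#' screened-Coulomb solution: intrinsic values equal the references and
#' W_ij = C dq_i dq_j exp(-r/lambda)/(eps r).  Used to build large
#' Monte-Carlo-vs-enumeration fixtures without grid solves; the PB route is
#' cross-checked against this closed form in the test-suite.
#'
#' @param structure a \code{pb_structure} (atom positions locate the sites)
#' @param sites list of \code{titratable_site}
#' @param eps solvent dielectric
#' @param ionic_strength mol/L
#' @param T temperature, K
#' @return a \code{site_energetics}
#' @export
uniform_medium_energetics <- function(structure, sites, eps = 80,
                                      ionic_strength = 0.1, T = 300) {
  a <- structure$atoms
  n <- length(sites)
  intr <- lapply(sites, `[[`, "reference")
  n_states <- vapply(sites, function(s) nrow(s$state_charges), integer(1))
  offsets <- cumsum(c(0L, n_states[-n]))
  W <- matrix(0, sum(n_states), sum(n_states))
  lam <- debye_length(ionic_strength, T, eps)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      si <- sites[[i]]; sj <- sites[[j]]
      pi_ <- cbind(a$x[si$member_atoms], a$y[si$member_atoms], a$z[si$member_atoms])
      pj_ <- cbind(a$x[sj$member_atoms], a$y[sj$member_atoms], a$z[sj$member_atoms])
      for (ai in 2:n_states[i]) for (bj in 2:n_states[j]) {
        dqi <- site_delta_charges(si, ai); dqj <- site_delta_charges(sj, bj)
        w <- 0
        for (u in seq_along(dqi)) for (v in seq_along(dqj)) {
          r <- sqrt(sum((pi_[u, ] - pj_[v, ])^2))
          w <- w + coulomb_energy(r, dqi[u], dqj[v], eps, lam)
        }
        W[offsets[i] + ai, offsets[j] + bj] <- w
        W[offsets[j] + bj, offsets[i] + ai] <- w
      }
    }
  }
  site_energetics(sites, intr, W)
}
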