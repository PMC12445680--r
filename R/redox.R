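#' Em profile of redox sites along the membrane normal
#'
#' For every redox site: the midpoint potential by bias-potential bisection
#' (all protonatable sites re-equilibrating; the \emph{other} redox sites are
#' clamped in their reduced states — one hole at a time, the standard
#' single-oxidation convention), the z coordinate of the site's
#' state-difference charge centroid, and the decomposition of the Em shift
#' into solvation-loss and protein-charge terms.  A site whose midpoint
#' search fails is returned flagged (NA Em) and the profile continues.
#'
#' @param structure a \code{pb_structure}
#' @param en a \code{site_energetics} from \code{\link{intrinsic_values}}
#' @param cond a \code{titration_conditions} (pH 7, 300 K, 100 mM defaults)
#' @param search half-width of the Em search window around the intrinsic
#'   value, mV
#' @return data.frame sorted by z: site_id, z, Em_mV, solvation_shift_mV,
#'   charge_shift_mV, residual_mV, ok
#' @export
em_profile <- function(structure, en, cond = titration_conditions(),
                       search = 4000) {
  idx <- which(vapply(en$sites, function(s) s$kind == "redox", logical(1)))
  rows <- lapply(idx, function(i) {
    s <- en$sites[[i]]
    z <- site_z(structure, s)
    en_i <- en
    for (j in setdiff(idx, i))     # single-hole convention
      en_i$sites[[j]]$fixed_state <- rownames(en$sites[[j]]$state_charges)[1]
    em <- tryCatch(
      em_midpoint(en_i, s$site_id,
                  bounds = en$intrinsic[[i]] + c(-search, search),
                  cond = cond),
      error = function(e) NA_real_)
    dec <- if (is.na(em)) list(solvation_shift_mV = NA_real_,
                               charge_shift_mV = NA_real_,
                               residual_mV = NA_real_)
           else decompose_shift(en_i, s$site_id, em, cond)
    data.frame(site_id = s$site_id, z = z, Em_mV = em,
               solvation_shift_mV = dec$solvation_shift_mV,
               charge_shift_mV = dec$charge_shift_mV,
               residual_mV = dec$residual_mV, ok = !is.na(em))
  })
  out <- do.call(rbind, rows)
  out[order(out$z), , drop = FALSE]
}

# z of the |dq|-weighted centroid of a site's state-difference charges
site_z <- function(structure, site, state = 2) {
  dq <- abs(site_delta_charges(site, state))
  w <- if (sum(dq) > 0) dq / sum(dq) else rep(1 / length(dq), length(dq))
  sum(structure$atoms$z[site$member_atoms] * w)
}

#' Decompose an Em shift into solvation and protein-charge terms
#'
#' Em - Em_ref = solvation_shift + charge_shift + residual, exact by
#' construction of the residual.  The solvation ("solvation loss") term is
#' the reaction-field shift with all protein charges zeroed; the charge term
#' is the interaction of the site's ox-minus-red charges with the background
#' charges plus the equilibrium-average charges of the other titratable
#' sites (the relaxed variant; \code{relaxed = FALSE} freezes the other
#' sites in their reference states); the residual reports the nonlinearity
#' of coupled titration left over.
#'
#' @param en a \code{site_energetics} with PB detail
#' @param site_id a redox site
#' @param Em_mV the computed midpoint (from \code{\link{em_midpoint}})
#' @param cond conditions at which the other sites are equilibrated
#' @param relaxed use equilibrium-average charges of the other titratable
#'   sites (TRUE) or their reference states (FALSE)
#' @return list: solvation_shift_mV, charge_shift_mV, residual_mV
#' @export
decompose_shift <- function(en, site_id, Em_mV, cond = titration_conditions(),
                            relaxed = TRUE) {
  i <- match(site_id, en$site_ids)
  if (is.na(i)) stop("no site ", site_id)
  if (is.null(en$detail)) stop("energetics lack PB detail (closed-form set?)")
  d <- en$detail[[i]]
  solv <- (d$rf_prot[2] - d$rf_model[2]) * PHYS$mV_per_kcal
  chg_kcal <- d$back_prot[2]
  if (relaxed && length(en$sites) > 1) {
    c2 <- cond; c2$E_mV <- Em_mV
    pop <- enumerate_exact(en, c2)
    for (j in seq_along(en$sites)) {
      if (j == i) next
      occ <- pop$occupancy[[j]]
      for (s in 2:en$n_states[j])
        chg_kcal <- chg_kcal +
          occ[[s]] * en$W[en$offsets[i] + 2, en$offsets[j] + s]
    }
  }
  chg <- chg_kcal * PHYS$mV_per_kcal
  ref <- en$sites[[i]]$reference
  list(solvation_shift_mV = solv, charge_shift_mV = chg,
       residual_mV = Em_mV - ref - solv - chg)
}

#' Per-residue contributions to a site's Em charge shift
#'
#' Splits the protein-charge term by residue: each background residue's
#' charges dotted with the site's ox-minus-red PB potential (plus, for the
#' other titratable sites, their equilibrium-occupancy-weighted couplings).
#' The table sums to the charge shift of \code{\link{decompose_shift}}.
#'
#' @inheritParams decompose_shift
#' @return data.frame: residue, contribution_mV, sorted by |contribution|
#' @export
per_residue_contributions <- function(en, site_id, Em_mV = NULL,
                                      cond = titration_conditions(),
                                      relaxed = TRUE) {
  i <- match(site_id, en$site_ids)
  if (is.na(i)) stop("no site ", site_id)
  d <- en$detail[[i]]
  bg <- d$background
  out <- data.frame(residue = character(0), contribution_mV = numeric(0))
  if (nrow(bg) > 0) {
    phi <- potential_at(d$phi_delta[[2]], cbind(bg$x, bg$y, bg$z))
    contr <- tapply(bg$q * phi, bg$residue, sum) * PHYS$mV_per_kcal
    out <- data.frame(residue = names(contr),
                      contribution_mV = as.numeric(contr))
  }
  if (relaxed && length(en$sites) > 1) {
    if (is.null(Em_mV)) Em_mV <- en$intrinsic[[i]]
    c2 <- cond; c2$E_mV <- Em_mV
    pop <- enumerate_exact(en, c2)
    for (j in seq_along(en$sites)) {
      if (j == i) next
      occ <- pop$occupancy[[j]]
      w <- sum(vapply(2:en$n_states[j], function(s)
        occ[[s]] * en$W[en$offsets[i] + 2, en$offsets[j] + s], numeric(1)))
      out <- rbind(out, data.frame(residue = en$site_ids[j],
                                   contribution_mV = w * PHYS$mV_per_kcal))
    }
  }
  out[order(-abs(out$contribution_mV)), , drop = FALSE]
}

#' Em spread over a conformer ensemble
#'
#' Recomputes intrinsic energetics and midpoints for every conformer and
#' reports, per site, the ensemble mean and the maximum absolute deviation
#' from it (the "mean +- dev" reporting convention for MD-snapshot Em
#' calculations).
#'
#' @param structure a \code{pb_structure} carrying conformers (see
#'   \code{\link{make_conformer_ensemble}}); the base coordinates are not
#'   used
#' @param sites list of \code{titratable_site}
#' @param cond a \code{titration_conditions}
#' @param ... PB options forwarded to \code{\link{intrinsic_values}}
#' @return data.frame: site_id, Em_mean_mV, Em_dev_mV, n_conformers
#' @export
ensemble_em <- function(structure, sites, cond = titration_conditions(), ...) {
  if (is.null(structure$conformers) || length(structure$conformers) == 0)
    stop("structure has no conformers")
  n <- length(structure$conformers)
  redox_ids <- vapply(Filter(function(s) s$kind == "redox", sites),
                      `[[`, "", "site_id")
  ems <- matrix(NA_real_, n, length(redox_ids),
                dimnames = list(NULL, redox_ids))
  for (k in seq_len(n)) {
    stk <- use_conformer(structure, k)
    enk <- intrinsic_values(stk, sites, ...)
    for (id in redox_ids) {
      i <- match(id, enk$site_ids)
      ems[k, id] <- em_midpoint(enk, id,
                                bounds = enk$intrinsic[[i]] + c(-4000, 4000),
                                cond = cond)
    }
  }
  data.frame(site_id = redox_ids,
             Em_mean_mV = colMeans(ems),
             Em_dev_mV = apply(ems, 2, function(v) max(abs(v - mean(v)))),
             n_conformers = n)
}
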