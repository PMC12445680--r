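#' Moser-Dutton electron-transfer rate
#'
#' The empirical ruler log10 k = 15 - 0.6 R - 3.1 (dG + lambda)^2 / lambda,
#' with R the edge-to-edge distance in Angstrom and dG, lambda in eV; the
#' rate is maximal (activationless) at dG = -lambda, and every 1.667
#' Angstrom of distance costs one decade.
#'
#' @param R edge-to-edge distance, Angstrom (>= 0)
#' @param dG reaction free energy, eV
#' @param lambda reorganization energy, eV (> 0)
#' @param coef ruler coefficients c(intercept, per-Angstrom slope,
#'   Franck-Condon prefactor)
#' @return rate in s^-1
#' @export
moser_dutton_rate <- function(R, dG, lambda, coef = c(15, 0.6, 3.1)) {
  if (lambda <= 0) stop("reorganization energy must be > 0")
  if (any(R < 0)) stop("distance must be >= 0")
  10^(coef[1] - coef[2] * R - coef[3] * (dG + lambda)^2 / lambda)
}

#' Build a hole-hopping chain
#'
#' An ordered chain of redox centres: a hole injected at the first member
#' hops along the chain and is absorbed at the last (the terminal sink).
#' Step free energy for hole transfer is
#' dG = (Em_acceptor - Em_donor) / 1000 eV, so the hole runs downhill toward
#' lower Em; the forward rate follows the Moser-Dutton ruler and the
#' backward rate is set by exact detailed balance,
#' k_b = k_f exp(+dG / kT).  (Evaluating the ruler with the sign of dG
#' flipped would imply an effective temperature of 1/(4 x 3.1 ln10) = 0.035
#' eV rather than kT at 300 K and distort equilibrium populations.)
#'
#' @param ids member names, in hopping order (length m >= 1)
#' @param Em_mV midpoint potentials of the members, mV
#' @param R_edge edge-to-edge distances of consecutive pairs, Angstrom
#'   (length m - 1)
#' @param lambda reorganization energy, eV
#' @param T temperature, K
#' @param coef ruler coefficients, see \code{\link{moser_dutton_rate}}
#' @return object of class \code{hop_chain}: data.frame of steps (donor,
#'   acceptor, R, dG_eV, k_f, k_b) plus members
#' @export
hop_chain <- function(ids, Em_mV, R_edge, lambda = 0.7, T = 300,
                      coef = c(15, 0.6, 3.1)) {
  m <- length(ids)
  if (length(Em_mV) != m) stop("Em_mV must match ids")
  if (m >= 2 && length(R_edge) != m - 1)
    stop("need one edge-to-edge distance per consecutive pair")
  if (m >= 2 && any(!is.finite(R_edge)))
    stop("disconnected chain: non-finite edge-to-edge distance")
  steps <- if (m >= 2) {
    dG <- (Em_mV[-1] - Em_mV[-m]) / 1000
    kT <- PHYS$kB_SI * T / PHYS$e_SI
    kf <- moser_dutton_rate(R_edge, dG, lambda, coef)
    data.frame(donor = ids[-m], acceptor = ids[-1], R = R_edge, dG_eV = dG,
               k_f = kf, k_b = kf * exp(dG / kT))
  } else data.frame(donor = character(0), acceptor = character(0),
                    R = numeric(0), dG_eV = numeric(0), k_f = numeric(0),
                    k_b = numeric(0))
  structure(list(members = ids, Em_mV = Em_mV, steps = steps,
                 lambda = lambda, T = T, coef = coef),
            class = "hop_chain")
}

#' Mean first-passage time through a hopping chain
#'
#' The expected time for a hole starting at the chain head to be absorbed at
#' the terminal sink, from the exact solution of the first-passage linear
#' system of the birth-death master equation (the terminal member is
#' absorbing: no outflow).
#'
#' @param chain a \code{hop_chain}
#' @return MFPT in ns (0 for a single-member chain)
#' @export
chain_mfpt <- function(chain) {
  st <- chain$steps
  m <- length(chain$members)
  if (m <= 1) return(0)
  if (any(!is.finite(st$k_f)) || any(!is.finite(st$k_b)))
    stop("non-finite rates in chain")
  n <- m - 1                       # transient states
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    out <- st$k_f[i] + if (i > 1) st$k_b[i - 1] else 0
    Q[i, i] <- -out
    if (i < n) Q[i, i + 1] <- st$k_f[i]
    if (i > 1) Q[i, i - 1] <- st$k_b[i - 1]
  }
  tvec <- solve(Q, rep(-1, n))
  tvec[1] * 1e9
}

#' Chain kinetics over a reorganization-energy sweep
#'
#' @param ids,Em_mV,R_edge,T,coef as in \code{\link{hop_chain}}
#' @param lambda_range numeric(2), eV (default c(0.6, 0.8), the canonical
#'   outer-sphere window for reaction-centre electron transfer)
#' @param n_lambda grid points
#' @return list: \code{sweep} (data.frame lambda, mfpt_ns), \code{mfpt_min_ns},
#'   \code{mfpt_max_ns}, and the chain at the central lambda
#' @export
lambda_sweep <- function(ids, Em_mV, R_edge, lambda_range = c(0.6, 0.8),
                         n_lambda = 9, T = 300, coef = c(15, 0.6, 3.1)) {
  lam <- seq(lambda_range[1], lambda_range[2], length.out = n_lambda)
  mf <- vapply(lam, function(l)
    chain_mfpt(hop_chain(ids, Em_mV, R_edge, lambda = l, T = T, coef = coef)),
    numeric(1))
  list(sweep = data.frame(lambda = lam, mfpt_ns = mf),
       mfpt_min_ns = min(mf), mfpt_max_ns = max(mf),
       chain = hop_chain(ids, Em_mV, R_edge, lambda = mean(lambda_range),
                         T = T, coef = coef))
}
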