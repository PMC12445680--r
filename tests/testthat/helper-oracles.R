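# Independent oracles and small fixture builders shared across the suite.

# Kirkwood series: reaction-field energy of a point charge q at distance d
# from the centre of a sphere of radius a (eps_in inside, eps_out outside).
kirkwood_rf_energy <- function(q, a, d, eps_in, eps_out, nmax = 120) {
  n <- 0:nmax
  coef <- (n + 1) * (eps_in - eps_out) /
    (eps_in * ((n + 1) * eps_out + n * eps_in))
  (332.0637 * q^2 / (2 * a)) * sum(coef * (d / a)^(2 * n))
}

# Master-equation MFPT oracle: survival-function integration with the matrix
# exponential over the transient generator.
mfpt_expm_oracle <- function(chain) {
  st <- chain$steps
  n <- length(chain$members) - 1
  if (n < 1) return(0)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Q[i, i] <- -(st$k_f[i] + if (i > 1) st$k_b[i - 1] else 0)
    if (i < n) Q[i, i + 1] <- st$k_f[i]
    if (i > 1) Q[i, i - 1] <- st$k_b[i - 1]
  }
  p0 <- c(1, rep(0, n - 1))
  surv <- function(t) {
    vapply(t, function(tt)
      sum(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * tt)))), numeric(1))
  }
  # integrate S(t) out to where S < 1e-13, in units of the fastest decay
  t_scale <- 1 / max(abs(diag(Q)))
  t_hi <- t_scale
  while (surv(t_hi) > 1e-13 && t_hi < 1e6 * t_scale) t_hi <- t_hi * 2
  stats::integrate(function(u) surv(u * t_hi), 0, 1, rel.tol = 1e-10,
                   subdivisions = 2000L)$value * t_hi * 1e9
}

# Brute-force z-binning of unit-charge groups for the region tally oracle.
brute_tally <- function(z, sign, bounds) {
  t(vapply(seq_len(nrow(bounds)), function(r) {
    inb <- z >= bounds[r, 1] & z < bounds[r, 2]
    c(n_pos = sum(sign[inb] > 0), n_neg = sum(sign[inb] < 0))
  }, c(n_pos = 0, n_neg = 0)))
}

# Minimal PDB writer for parser tests (standard fixed columns).
write_toy_pdb <- function(path, atoms) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
    seq_len(nrow(atoms)), atoms$name, atoms$res, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, 1.0, 0.0, substr(atoms$name, 1, 1))
  writeLines(c(lines, "END"), path)
  path
}

# An Asp "tripeptide" (GLY-ASP-GLY backbone stubs) with optional waters and
# an unknown ligand, for read_pdb tests.
toy_asp_pdb <- function(path, waters = 0, ligand = FALSE) {
  res_atoms <- function(res, resno, x0) {
    nm <- switch(res, GLY = c("N", "CA", "C", "O"),
                 ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"))
    data.frame(name = nm, res = res, chain = "A", resno = resno,
               x = x0 + seq_along(nm) * 1.3, y = 0, z = 0)
  }
  a <- rbind(res_atoms("GLY", 1, 0), res_atoms("ASP", 2, 6),
             res_atoms("GLY", 3, 18))
  if (waters > 0)
    a <- rbind(a, data.frame(name = "O", res = "HOH", chain = "A",
                             resno = 100 + seq_len(waters),
                             x = 30 + 3 * seq_len(waters), y = 0, z = 0))
  if (ligand)
    a <- rbind(a, data.frame(name = "C1", res = "LIG", chain = "A",
                             resno = 200, x = 40, y = 5, z = 0))
  write_toy_pdb(path, a)
}

# Single pseudo-indole redox probe floating in water (cycle-closure fixture).
isolated_probe_fixture <- function() {
  p <- redoxpb:::pseudo_indole_atoms(c(0, 0, 0))
  atoms <- data.frame(atom_id = 1:9, atom_name = p$atom_name,
                      residue_name = "IND", chain_id = "A",
                      residue_number = 1L, x = p$x, y = p$y, z = p$z,
                      charge = 0, radius = p$radius)
  st <- pb_structure(atoms)
  list(structure = st, sites = list(redoxpb:::probe_site("probe", 1:9)))
}

# Capacitor fixture: two full-width charged sheets in a wide shallow box of
# uniform dielectric, with the grounded-plane 1D closed form as oracle.
capacitor_fixture <- function() {
  box <- grid_spec(c(-60, -60, -30), 2.0, c(61, 61, 31))
  w <- 55
  pts <- expand.grid(x = seq(-w, w, 2.5), y = seq(-w, w, 2.5))
  n <- nrow(pts)
  atoms <- data.frame(
    atom_id = seq_len(2 * n), atom_name = "Q", residue_name = "SHT",
    chain_id = "A", residue_number = seq_len(2 * n),
    x = rep(pts$x, 2), y = rep(pts$y, 2), z = rep(c(-10, 10), each = n),
    charge = rep(c(-1, 1), each = n), radius = 0.5)
  sigma <- n / (2 * w)^2
  H <- 30; d <- 10
  list(box = box, structure = pb_structure(atoms),
       Ez_analytic = -4 * pi * 332.0637 * sigma / 80 * (H - d) / H)
}
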