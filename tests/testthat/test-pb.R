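test_that("Debye length follows the closed form and its scaling law", {
  expect_equal(debye_length(0), Inf)
  # 0.304/sqrt(I) nm at 298 K in water
  expect_equal(debye_length(0.1, T = 298, eps = 80), 9.61, tolerance = 0.02)
  expect_equal(debye_length(0.4, T = 298) * 2, debye_length(0.1, T = 298))
  expect_error(debye_length(-0.1), ">= 0")
})

test_that("trilinear spreading conserves charge and interpolation is exact on linear fields", {
  g <- grid_spec(c(-5, -5, -5), 1, c(11, 11, 11))
  set.seed(2)
  pts <- matrix(runif(15, -3, 3), 5)
  q <- runif(5, -2, 2)
  rho <- trilinear_spread(g, pts, q)
  expect_equal(sum(rho), sum(q), tolerance = 1e-12)
  ax <- grid_axes(g)
  lin <- outer(outer(2 * ax$x, 3 * ax$y, "+"), 5 * ax$z, "+")
  vals <- trilinear_interp(g, as.vector(lin), pts)
  expect_equal(vals, 2 * pts[, 1] + 3 * pts[, 2] + 5 * pts[, 3],
               tolerance = 1e-10)
  expect_error(trilinear_spread(g, matrix(c(20, 0, 0), 1), 1), "outside")
})

test_that("dielectric map places protein and solvent nodes correctly", {
  st <- make_born_ion(1, 10)
  g <- grid_covering(c(-15, -15, -15), c(15, 15, 15), 1)
  dm <- build_dielectric_map(st, g, require_cover = FALSE)
  probe <- function(p) {
    i <- round((p - g$origin) / g$spacing) + 1
    i[1] + g$dim[1] * (i[2] - 1) + g$dim[1] * g$dim[2] * (i[3] - 1)
  }
  centre <- probe(c(0, 0, 0))
  expect_equal(dm$kappa2eps[centre], 0)
  expect_true(dm$sdf[centre] < 0)
  far <- probe(c(14, 14, 14))          # ~14.2 A outside the surface
  expect_true(dm$sdf[far] > 2)
  expect_true(dm$kappa2eps[far] > 0)
  # edge dielectric away from the boundary is pure
  expect_true(all(abs(dm$eps_x[dm$eps_x < 79] - 4) < 1e-9 |
                  dm$eps_x[dm$eps_x < 79] < 80))
  expect_error(build_dielectric_map(st, grid_spec(c(-5, -5, -5), 1, c(9, 9, 9))),
               "margin")
})

test_that("protein-node volume of a Born sphere matches the analytic volume", {
  st <- make_born_ion(1, 2)
  g <- grid_covering(c(-4, -4, -4), c(4, 4, 4), 0.3)
  dm <- build_dielectric_map(st, g, require_cover = FALSE)
  vol <- sum(dm$sdf <= 0) * g$spacing^3
  expect_equal(vol, 4 / 3 * pi * 2^3, tolerance = 0.05)
})

test_that("uniform-medium potential matches Coulomb and is linear in the charges", {
  g <- grid_covering(c(-15, -15, -15), c(15, 15, 15), 1.0)
  dm <- redoxpb:::uniform_dielectric_map(g, 80)
  s1 <- solve_lpb(dm, list(x = 0, y = 0, z = 0, q = 1), bc = "dh")
  phi10 <- trilinear_interp(g, s1$phi, matrix(c(10, 0, 0), 1))
  expect_equal(phi10, 332.0637 / (80 * 10), tolerance = 0.02)
  s2 <- solve_lpb(dm, list(x = 0, y = 0, z = 0, q = 2), bc = "dh")
  expect_equal(max(abs(s2$phi - 2 * s1$phi)) / max(abs(s2$phi)), 0,
               tolerance = 1e-5)
})

test_that("solver reports residual history when the iteration cap is hit", {
  g <- grid_covering(c(-8, -8, -8), c(8, 8, 8), 1.0)
  dm <- redoxpb:::uniform_dielectric_map(g, 80)
  err <- tryCatch(solve_lpb(dm, list(x = 0, y = 0, z = 0, q = 1),
                            bc = "dh", maxit = 3),
                  error = identity)
  expect_s3_class(err, "error")
  expect_length(err$residual_history, 3)
})

test_that("Born reaction-field energy is reproduced at moderate focusing", {
  st <- make_born_ion(1, 2)
  ch <- list(x = 0, y = 0, z = 0, q = 1)
  rf <- reaction_field_at(st, ch, c(0, 0, 0), 6, c(0, 0, 0),
                          levels = c(2.0, 0.5), eps_in = 1, eps_out = 80,
                          ionic_strength = 0)
  expect_equal(0.5 * rf, born_energy(1, 2, 1, 80), tolerance = 0.02)
  # charge-sign symmetry: energy depends on q^2
  rf_neg <- reaction_field_at(st, list(x = 0, y = 0, z = 0, q = -1),
                              c(0, 0, 0), 6, c(0, 0, 0),
                              levels = c(2.0, 0.5), eps_in = 1, eps_out = 80,
                              ionic_strength = 0)
  expect_equal(0.5 * (-1) * rf_neg, 0.5 * rf, tolerance = 1e-6)
})

test_that("focusing agrees with a single fine grid in uniform dielectric", {
  ch <- list(x = 0.6, y = 0, z = 0, q = 1)
  pot_f <- focus_solve(NULL, ch, c(0, 0, 0), 5, levels = c(2.0, 0.5),
                       eps_in = 80, eps_out = 80, ionic_strength = 0)
  fin <- pot_f$levels[[2]]
  g1 <- fin$grid
  dm <- redoxpb:::uniform_dielectric_map(g1, 80)
  phi_bc <- redoxpb:::dh_boundary(g1, ch, 80, Inf)
  direct <- solve_lpb(dm, ch, bc = "dirichlet", phi_bc = phi_bc)
  p <- matrix(c(2, 1, 0), 1)
  expect_equal(trilinear_interp(g1, fin$phi, p),
               trilinear_interp(g1, direct$phi, p), tolerance = 0.01)
})

test_that("grid placement: half-voxel translation moves the Born energy by < 1%", {
  W <- vapply(c(0, 1.0), function(shift) {
    st <- make_born_ion(1, 2)
    st$atoms$x <- st$atoms$x + shift
    ch <- list(x = shift, y = 0, z = 0, q = 1)
    0.5 * reaction_field_at(st, ch, c(shift, 0, 0), 6, c(shift, 0, 0),
                            levels = c(2.0, 0.5), eps_in = 1, eps_out = 80,
                            ionic_strength = 0)
  }, numeric(1))
  expect_equal(W[1], W[2], tolerance = 0.01)
})

test_that("spacing refinement changes the Born energy by well under 1 kcal/mol", {
  st <- make_born_ion(1, 2)
  ch <- list(x = 0, y = 0, z = 0, q = 1)
  W <- vapply(c(0.5, 0.4), function(h) {
    0.5 * reaction_field_at(st, ch, c(0, 0, 0), 5, c(0, 0, 0),
                            levels = c(2.0, h), eps_in = 1, eps_out = 80,
                            ionic_strength = 0)
  }, numeric(1))
  expect_lt(abs(W[1] - W[2]), 1)
})

test_that("charging a site in an uncharged cavity shows the solvation-loss sign", {
  # reaction field of charge creation: strictly more negative in water than
  # inside a low-dielectric cavity
  st <- make_born_ion(0, 2)                       # bare 2 A sphere, no charge
  ch <- list(x = 0, y = 0, z = 0, q = 1)
  rf_water <- 0.5 * reaction_field_at(st, ch, c(0, 0, 0), 5, c(0, 0, 0),
                                      levels = c(2.0, 0.5), eps_in = 4,
                                      eps_out = 80, ionic_strength = 0)
  cav <- make_born_ion(0, 8)                      # buried in an 8 A cavity
  rf_cav <- 0.5 * reaction_field_at(cav, ch, c(0, 0, 0), 5, c(0, 0, 0),
                                    levels = c(2.0, 0.5), eps_in = 4,
                                    eps_out = 80, ionic_strength = 0)
  expect_lt(rf_water, rf_cav)
  expect_gt(rf_cav - rf_water, 0)                 # solvation loss positive
})

test_that("charging_energy closes the cycle for a site alone in water", {
  fx <- isolated_probe_fixture()
  opts <- list(levels = c(2.0, 0.8), ionic_strength = 0)
  ce_p <- do.call(charging_energy,
                  c(list(fx$structure, fx$sites[[1]], environment = "protein"),
                    opts))
  ce_m <- do.call(charging_energy,
                  c(list(fx$structure, fx$sites[[1]], environment = "model"),
                    opts))
  expect_equal(ce_p$rf, ce_m$rf, tolerance = 1e-9)
  expect_equal(ce_p$back, 0)
  expect_equal(ce_p$total - ce_m$total, 0, tolerance = 1e-9)
})

test_that("background term reproduces Coulomb for a unit charge at 10 A", {
  fx <- isolated_probe_fixture()
  a <- fx$structure$atoms
  a <- rbind(a, data.frame(atom_id = 10, atom_name = "Q",
                           residue_name = "CHG", chain_id = "A",
                           residue_number = 2, x = 10, y = 0, z = 0,
                           charge = 1, radius = 0.0))
  st <- pb_structure(a)
  ce <- charging_energy(st, fx$sites[[1]], environment = "protein",
                        levels = c(2.0, 0.8), eps_in = 80, eps_out = 80,
                        ionic_strength = 0)
  # ox-minus-red charges sum to +1 centred ~10 A from the background charge
  dq <- site_delta_charges(fx$sites[[1]], 2)
  oracle <- sum(vapply(seq_len(9), function(k) {
    r <- sqrt((a$x[k] - 10)^2 + a$y[k]^2 + a$z[k]^2)
    coulomb_energy(r, dq[k], 1, 80, Inf)
  }, numeric(1)))
  expect_equal(ce$back, oracle, tolerance = 0.02)
  expect_equal(oracle, 332.0637 / 800, tolerance = 0.05)
})

test_that("interaction energy matches screened Coulomb, reciprocity and decay", {
  mk2 <- function(d) {
    atoms <- data.frame(
      atom_id = 1:2, atom_name = "Q", residue_name = "PS", chain_id = "A",
      residue_number = 1:2, x = c(0, d), y = 0, z = 0, charge = 0, radius = 2)
    st <- pb_structure(atoms)
    s1 <- titratable_site("s1", "base", 1, rbind(deprot = 0, prot = 1), 10)
    s2 <- titratable_site("s2", "base", 2, rbind(deprot = 0, prot = 1), 10)
    list(st = st, s1 = s1, s2 = s2)
  }
  f <- mk2(5)
  w12 <- interaction_energy(f$st, f$s1, f$s2, symmetrize = FALSE,
                            levels = c(2.0, 0.8), eps_in = 80, eps_out = 80,
                            ionic_strength = 0)
  w21 <- interaction_energy(f$st, f$s2, f$s1, symmetrize = FALSE,
                            levels = c(2.0, 0.8), eps_in = 80, eps_out = 80,
                            ionic_strength = 0)
  expect_equal(w12, 332.0637 / (80 * 5), tolerance = 0.02)
  expect_lt(abs(w12 - w21) / abs(w12), 0.05)
  # screened decay at 100 mM: negligible at 60 A
  f2 <- mk2(60)
  w60 <- interaction_energy(f2$st, f2$s1, f2$s2, symmetrize = TRUE,
                            levels = c(2.5), eps_in = 80, eps_out = 80,
                            ionic_strength = 0.1)
  expect_lt(abs(w60), 0.01)
  expect_error(interaction_energy(f$st, f$s1, f$s1), "share")
})
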