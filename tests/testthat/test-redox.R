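pb_fast <- list(levels = c(2.0, 0.8), ionic_strength = 0)

test_that("a probe alone in water decomposes to zero shifts", {
  fx <- isolated_probe_fixture()
  en <- do.call(intrinsic_values, c(list(fx$structure, fx$sites), pb_fast))
  expect_equal(en$intrinsic[[1]], 1070, tolerance = 1e-6)
  em <- em_midpoint(en, "probe", c(0, 3000))
  dec <- decompose_shift(en, "probe", em)
  expect_lt(abs(dec$solvation_shift_mV), 1e-6)
  expect_equal(dec$charge_shift_mV, 0)
  expect_lt(abs(dec$residual_mV), 1)
})

test_that("an uncharged cavity produces pure positive solvation loss", {
  fx <- isolated_probe_fixture()
  a <- fx$structure$atoms
  # surround the probe with a neutral low-dielectric shell
  body <- redoxpb:::fcc_points(rep(-9, 3), rep(9, 3), 3.5)
  body <- body[sqrt(rowSums(body^2)) <= 9, , drop = FALSE]
  d2 <- rep(Inf, nrow(body))
  for (k in 1:9)
    d2 <- pmin(d2, (body[, 1] - a$x[k])^2 + (body[, 2] - a$y[k])^2 +
                   (body[, 3] - a$z[k])^2)
  body <- body[d2 > 2.8^2, , drop = FALSE]
  atoms <- rbind(
    data.frame(atom_id = 0, atom_name = "PSA", residue_name = "BOD",
               chain_id = "A", residue_number = seq_len(nrow(body)) + 10,
               x = body[, 1], y = body[, 2], z = body[, 3], charge = 0,
               radius = 2),
    a)
  atoms$atom_id <- seq_len(nrow(atoms))
  st <- pb_structure(atoms)
  site <- redoxpb:::probe_site("probe", nrow(body) + 1:9)
  en <- do.call(intrinsic_values, c(list(st, list(site)), pb_fast))
  em <- em_midpoint(en, "probe", c(0, 4000))
  dec <- decompose_shift(en, "probe", em)
  expect_gt(dec$solvation_shift_mV, 50)    # buried: solvation loss
  expect_equal(dec$charge_shift_mV, 0)     # nothing charged around
  expect_lt(abs(dec$residual_mV), 1)
  # buried probe sits strictly above the exposed reference
  expect_gt(em, 1070)
})

test_that("a single charged residue owns the whole charge shift", {
  fx <- isolated_probe_fixture()
  a <- rbind(fx$structure$atoms,
             data.frame(atom_id = 10, atom_name = "Q", residue_name = "CHG",
                        chain_id = "A", residue_number = 5, x = 10, y = 0,
                        z = 0, charge = 1, radius = 0))
  st <- pb_structure(a)
  site <- redoxpb:::probe_site("probe", 1:9)
  en <- do.call(intrinsic_values,
                c(list(st, list(site)), list(levels = c(2.0, 0.8),
                                             ionic_strength = 0,
                                             eps_in = 80, eps_out = 80)))
  em <- em_midpoint(en, "probe", c(0, 3000))
  dec <- decompose_shift(en, "probe", em)
  tab <- per_residue_contributions(en, "probe", em)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$contribution_mV, dec$charge_shift_mV, tolerance = 1e-9)
  # +1 e at ~10 A from a +1 state-difference in water: +18 mV
  expect_equal(dec$charge_shift_mV, 332.0637 / 800 * PHYS$mV_per_kcal,
               tolerance = 0.05)
  expect_gt(dec$charge_shift_mV, 0)
})

test_that("per-residue contributions sum to the charge shift on the coupled fixture", {
  fx <- make_coupled_redox_proton(seed = 1)
  en <- intrinsic_values(fx$structure, fx$sites, levels = c(2.5, 1.0))
  cond <- titration_conditions(pH = 7)
  em <- em_midpoint(en, "probe", en$intrinsic[[1]] + c(-4000, 4000),
                    cond = cond)
  dec <- decompose_shift(en, "probe", em, cond)
  tab <- per_residue_contributions(en, "probe", em, cond)
  expect_equal(sum(tab$contribution_mV), dec$charge_shift_mV,
               tolerance = 1e-6)
  # additivity identity holds by construction
  expect_equal(1070 + dec$solvation_shift_mV + dec$charge_shift_mV +
                 dec$residual_mV, em, tolerance = 1e-9)
})

test_that("ensemble Em averages single-conformer values and flags topology mismatch", {
  fx <- isolated_probe_fixture()
  a <- rbind(fx$structure$atoms,
             data.frame(atom_id = 10, atom_name = "Q", residue_name = "CHG",
                        chain_id = "A", residue_number = 5, x = 10, y = 0,
                        z = 0, charge = 1, radius = 0))
  st <- pb_structure(a)
  site <- redoxpb:::probe_site("probe", 1:9)
  base <- atom_coords(st)
  conf2 <- base; conf2[10, 1] <- 20            # charge moved 10 -> 20 A
  st$conformers <- list(base, conf2)
  ens <- ensemble_em(st, list(site), levels = c(2.0, 0.8),
                     ionic_strength = 0, eps_in = 80, eps_out = 80)
  # per-conformer midpoints, computed independently
  single_em <- function(coords) {
    stk <- st; stk$conformers <- list(coords)
    stk <- use_conformer(stk, 1)
    enk <- intrinsic_values(stk, list(site), levels = c(2.0, 0.8),
                            ionic_strength = 0, eps_in = 80, eps_out = 80)
    em_midpoint(enk, "probe", c(0, 3000))
  }
  e1 <- single_em(base); e2 <- single_em(conf2)
  expect_equal(ens$Em_mean_mV, mean(c(e1, e2)), tolerance = 0.01)
  expect_equal(ens$Em_dev_mV, abs(e1 - e2) / 2, tolerance = 0.02)
  expect_gt(ens$Em_dev_mV, 1)     # the two geometries genuinely differ

  # identical conformers: zero deviation
  st$conformers <- list(base, base, base)
  ens0 <- ensemble_em(st, list(site), levels = c(2.0, 0.8),
                      ionic_strength = 0, eps_in = 80, eps_out = 80)
  expect_equal(ens0$Em_dev_mV, 0, tolerance = 1e-9)

  expect_error(pb_structure(st$atoms, conformers = list(base[-1, ])),
               "conformer")
  expect_error(ensemble_em(fx$structure, list(site)), "no conformers")
})
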