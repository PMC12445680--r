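bin_site <- function(id, kind = "acid", ref = 4.0) {
  m <- if (kind == "acid") rbind(deprot = -1, prot = 0)
       else rbind(deprot = 0, prot = 1)
  titratable_site(id, kind, 1, m, ref)
}

redox_site_def <- function(id = "trp", ref = 1070)
  titratable_site(id, "redox", 1, rbind(red = 0, ox = 1), ref)

test_that("exact enumeration reproduces Henderson-Hasselbalch and Nernst limits", {
  en <- site_energetics(list(bin_site("a", ref = 4.0)), list(4.0), NULL)
  pop <- enumerate_exact(en, titration_conditions(pH = 7))
  expect_equal(occupancy(pop, "a", "prot"), 1e-3 / (1 + 1e-3),
               tolerance = 1e-12)
  expect_equal(sum(pop$occupancy$a), 1)

  enr <- site_energetics(list(redox_site_def()), list(1070), NULL)
  pop <- enumerate_exact(enr, titration_conditions(E_mV = 1070))
  expect_equal(occupancy(pop, "trp", "ox"), 0.5, tolerance = 1e-12)
})

test_that("two coupled acids match the hand-summed 4-state partition function", {
  W <- matrix(0, 4, 4)
  w <- RTln10(300)
  W[2, 4] <- W[4, 2] <- w
  en <- site_energetics(list(bin_site("a1"), bin_site("a2")),
                        list(4.0, 4.0), W)
  cond <- titration_conditions(pH = 4.3)
  pop <- enumerate_exact(en, cond)
  kT <- kT_kcal(300)
  g <- RTln10(300) * (4.3 - 4.0)
  states <- expand.grid(x1 = 0:1, x2 = 0:1)           # 1 = protonated
  G <- states$x1 * g + states$x2 * g + states$x1 * states$x2 * w
  z <- exp(-G / kT); z <- z / sum(z)
  expect_equal(occupancy(pop, "a1", "prot"), sum(z[states$x1 == 1]),
               tolerance = 1e-12)
  expect_equal(occupancy(pop, "a2", "deprot"), sum(z[states$x2 == 0]),
               tolerance = 1e-12)
})

test_that("MC titration matches the closed form within 3 standard errors", {
  en <- site_energetics(list(bin_site("a", ref = 4.0)), list(4.0), NULL)
  pop <- mc_titrate(en, titration_conditions(pH = 4.5), sweeps = 2e4,
                    seed = 31)
  hh <- 1 / (1 + 10^(4.5 - 4.0))
  se <- max(pop$se$a[["prot"]], 1e-4)
  expect_lt(abs(occupancy(pop, "a", "prot") - hh), 3 * se)
})

test_that("MC matches exact enumeration on an interacting 12-site cluster", {
  cl <- make_site_cluster(12, coupling = 1.4, seed = 7)
  cond <- titration_conditions(pH = 7)
  mc <- mc_titrate(cl$energetics, cond, sweeps = 1e5, seed = 42)
  ex <- enumerate_exact(cl$energetics, cond)
  expect_lt(max(abs(unlist(mc$occupancy) - unlist(ex$occupancy))), 0.01)
})

test_that("MC runs are reproducible per seed and validate inputs", {
  cl <- make_site_cluster(6, coupling = 2, seed = 3)
  cond <- titration_conditions()
  m1 <- mc_titrate(cl$energetics, cond, sweeps = 5e3, seed = 11)
  m2 <- mc_titrate(cl$energetics, cond, sweeps = 5e3, seed = 11)
  expect_identical(m1$occupancy, m2$occupancy)
  expect_error(mc_titrate(cl$energetics, cond, sweeps = 5e3), "seed")
  bad <- cl$energetics; bad$intrinsic[[1]] <- NaN
  expect_error(mc_titrate(bad, cond, seed = 1, sweeps = 100), "non-finite")
})

test_that("pKa curve recovers the intrinsic value and unit Hill slope when isolated", {
  en <- site_energetics(list(bin_site("glu", ref = 4.4)), list(4.4), NULL)
  res <- pka_curve(en, "glu", pH_grid = seq(2, 7, 0.5))
  expect_equal(res$pKa, 4.4, tolerance = 1e-6)
  expect_equal(res$hill, 1.0, tolerance = 0.02)
  expect_error(pka_curve(en, "glu", pH_grid = seq(10, 12, 0.5)), "widen")
})

test_that("strong anti-cooperativity splits apparent pKa values symmetrically", {
  w <- 4 * RTln10(300)       # 4 pH units of splitting
  W <- matrix(0, 4, 4); W[2, 4] <- W[4, 2] <- w
  en <- site_energetics(list(bin_site("a1"), bin_site("a2")),
                        list(7.0, 7.0), W)
  # proton-hole symmetry puts the titration centre at
  # pKa_intr - W / (2 RT ln10); the two macroscopic crossings sit
  # symmetrically around it
  ctr <- 7 - w / (2 * RTln10(300))
  theta_tot <- function(pH) {
    pop <- enumerate_exact(en, titration_conditions(pH = pH))
    occupancy(pop, "a1", "prot") + occupancy(pop, "a2", "prot")
  }
  lo <- uniroot(function(p) theta_tot(p) - 1.5, c(-5, ctr), tol = 1e-9)$root
  hi <- uniroot(function(p) theta_tot(p) - 0.5, c(ctr, 14), tol = 1e-9)$root
  expect_equal(hi - ctr, ctr - lo, tolerance = 1e-6)  # symmetric split
  expect_gt(hi - lo, 3)                               # split of order W
  # the per-site apparent pKa (identical sites) sits at the centre
  res <- pka_curve(en, "a1", pH_grid = seq(0, 12, 0.5))
  expect_equal(res$pKa, ctr, tolerance = 1e-6)
})

test_that("em_midpoint returns the reference for an isolated site and shifts by W for a fixed neighbour", {
  en <- site_energetics(list(redox_site_def()), list(1070), NULL)
  expect_lt(abs(em_midpoint(en, "trp", c(0, 3000)) - 1070), 1)
  expect_error(em_midpoint(en, "trp", c(2000, 3000)), "bracket")

  # fixed -1 charge nearby, modelled as a clamped site: Em drops by exactly W
  neg <- titratable_site("fixq", "acid", 1,
                         rbind(off = 0, on = -1), 0, fixed_state = "on")
  w <- -3.2     # kcal/mol, attractive to the radical cation
  W <- matrix(0, 4, 4); W[2, 4] <- W[4, 2] <- w
  en2 <- site_energetics(list(redox_site_def(), neg), list(1070, 0), W)
  em <- em_midpoint(en2, "trp", c(-3000, 3000))
  expect_equal(em, 1070 + w * PHYS$mV_per_kcal, tolerance = 0.01)
})

test_that("redox occupancy is monotone non-decreasing in the bias potential", {
  cl <- make_site_cluster(5, coupling = 2, seed = 13)
  sites <- c(cl$sites, list(redox_site_def("probe")))
  en0 <- cl$energetics
  n <- length(sites)
  W <- matrix(0, 2 * n, 2 * n)
  W[seq_len(2 * (n - 1)), seq_len(2 * (n - 1))] <- en0$W
  W[2 * n, 2] <- W[2, 2 * n] <- -1.5      # couple the probe to site 1
  en <- site_energetics(sites, c(en0$intrinsic, list(1100)), W)
  occ <- vapply(seq(600, 1600, 100), function(E)
    occupancy(enumerate_exact(en, titration_conditions(E_mV = E)),
              "probe", "ox"), numeric(1))
  expect_true(all(diff(occ) >= -1e-12))
})

test_that("His tautomer site titrates between three states with the bundled references", {
  his <- titratable_site("his", "his_tautomer", 1:2,
                         rbind(HIE = c(-0.2, 0.2), HIP = c(0.5, 0.5),
                               HID = c(0.2, -0.2)),
                         c(Ne = 7.0, Nd = 6.6))
  en <- site_energetics(list(his), list(c(Ne = 7.0, Nd = 6.6)), NULL)
  acidic <- enumerate_exact(en, titration_conditions(pH = 3))
  expect_gt(occupancy(acidic, "his", "HIP"), 0.99)
  basic <- enumerate_exact(en, titration_conditions(pH = 11))
  expect_lt(occupancy(basic, "his", "HIP"), 0.01)
  # neutral tautomer preference set by the pKa difference (Ne held tighter)
  expect_gt(occupancy(basic, "his", "HIE"), occupancy(basic, "his", "HID"))
  rat <- occupancy(basic, "his", "HIE") / occupancy(basic, "his", "HID")
  expect_equal(log10(rat), 7.0 - 6.6, tolerance = 1e-6)
  # apparent pKa of the protonated state crossing
  res <- pka_curve(en, "his", pH_grid = seq(3, 11, 0.5))
  expect_equal(res$pKa, 6.45, tolerance = 0.05)   # 6.6 and 7.0 in parallel
})

test_that("fixed sites are excluded from sampling but shape the equilibrium", {
  neg <- titratable_site("clamp", "acid", 1, rbind(off = 0, on = -1), 0,
                         fixed_state = "on")
  base <- bin_site("lys", "base", 10.4)
  W <- matrix(0, 4, 4); W[4, 2] <- W[2, 4] <- -2
  en <- site_energetics(list(base, neg), list(10.4, 0), W)
  pop <- enumerate_exact(en, titration_conditions(pH = 10.4))
  expect_equal(occupancy(pop, "clamp", "on"), 1)
  # attraction to the clamped -1 stabilizes the protonated (+1) state
  expect_gt(occupancy(pop, "lys", "prot"), 0.9)
  mc <- mc_titrate(en, titration_conditions(pH = 10.4), sweeps = 5e3,
                   seed = 2)
  expect_equal(occupancy(mc, "clamp", "on"), 1)
})

test_that("coupled redox-proton energetics give the Nernstian Em-vs-pH slope", {
  # closed-form two-site model: strong repulsion between radical cation and
  # protonated (+1) site
  prs <- bin_site("prs", "base", 11.5)
  W <- matrix(0, 4, 4); W[2, 4] <- W[4, 2] <- 12
  en <- site_energetics(list(redox_site_def("probe", 1070), prs),
                        list(1070, 11.5), W)
  ems <- vapply(6:9, function(p)
    em_midpoint(en, "probe", c(-2000, 4000),
                cond = titration_conditions(pH = p)), numeric(1))
  slope <- coef(lm(ems ~ c(6:9)))[[2]]
  expect_equal(slope, -nernst_slope_mV(300), tolerance = 0.02)
  # decoupled limit: slope vanishes
  en0 <- site_energetics(list(redox_site_def("probe", 1070), prs),
                         list(1070, 11.5), NULL)
  ems0 <- vapply(c(6, 9), function(p)
    em_midpoint(en0, "probe", c(-2000, 4000),
                cond = titration_conditions(pH = p)), numeric(1))
  expect_lt(abs(diff(ems0)), 1)
})
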