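test_that("PQR writing and re-reading preserves the atom table", {
  cl <- make_site_cluster(6, coupling = 1.2, seed = 11)
  f <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(cl$structure, f)
  st2 <- read_pqr(f)
  a1 <- cl$structure$atoms; a2 <- st2$atoms
  expect_equal(a2$charge, a1$charge, tolerance = 1e-8)
  expect_equal(a2$radius, a1$radius, tolerance = 1e-8)
  expect_equal(a2$x, round(a1$x, 3))
  expect_equal(a2$residue_number, a1$residue_number)
  expect_equal(a2$atom_name, a1$atom_name)
  # second round trip is exact (printed precision is a fixed point)
  f2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(st2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed PQR numeric fields are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 X ION A 1 0.0 0.0 0.0 1.0 2.0",
               "ATOM 2 Y ION A 2 1.0 0.0 0.0 1.0 oops"), f)
  expect_error(read_pqr(f), "line 2")
  writeLines("REMARK nothing", f)
  expect_error(read_pqr(f), "no ATOM")
})

test_that("read_pdb assigns library charges, drops waters, honours retain list", {
  f <- withr::local_tempfile(fileext = ".pdb")
  toy_asp_pdb(f, waters = 2)
  st <- read_pdb(f)
  a <- st$atoms
  expect_false(any(a$residue_name == "HOH"))
  od <- a$charge[a$atom_name %in% c("OD1", "OD2")]
  expect_equal(od, c(-0.5, -0.5))
  expect_equal(sum(a$charge), -1)
  # retained ligand water
  st2 <- read_pdb(f, keep_waters = "A:101")
  expect_equal(sum(st2$atoms$residue_name == "HOH"), 1)
  expect_equal(st2$atoms$residue_number[st2$atoms$residue_name == "HOH"], 101)
})

test_that("unknown residues error unless the zero-charge fallback is enabled", {
  f <- withr::local_tempfile(fileext = ".pdb")
  toy_asp_pdb(f, ligand = TRUE)
  expect_error(read_pdb(f), "LIG")
  st <- read_pdb(f, zero_charge_fallback = TRUE)
  expect_equal(st$atoms$charge[st$atoms$residue_name == "LIG"], 0)
})

test_that("define_sites instantiates reference values and fixed states", {
  f <- withr::local_tempfile(fileext = ".pdb")
  toy_asp_pdb(f)
  st <- read_pdb(f)
  sites <- define_sites(st)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$kind, "acid")
  expect_equal(sites[[1]]$reference, 4.0)

  # His: three tautomer states with the two reference pKa values
  his <- data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2",
                             "CE1", "NE2"),
                    res = "HIS", chain = "A", resno = 5,
                    x = seq_len(10) * 1.3, y = 1, z = 0)
  write_toy_pdb(f, his)
  sth <- read_pdb(f)
  sh <- define_sites(sth)
  expect_equal(sh[[1]]$kind, "his_tautomer")
  expect_equal(nrow(sh[[1]]$state_charges), 3)
  expect_equal(unname(sh[[1]]$reference["Ne"]), 7.0)
  expect_equal(unname(sh[[1]]$reference["Nd"]), 6.6)
  sh2 <- define_sites(sth, fixed_states = c("A:5" = "HIE"))
  expect_equal(sh2[[1]]$fixed_state, "HIE")

  # Trp is a redox site only when flagged
  trp <- data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2",
                             "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
                    res = "TRP", chain = "A", resno = 7,
                    x = seq_len(14) * 1.3, y = 2, z = 0)
  write_toy_pdb(f, trp)
  stw <- read_pdb(f)
  expect_length(define_sites(stw), 0)
  sw <- define_sites(stw, redox_trp = "A:7")
  expect_equal(sw[[1]]$kind, "redox")
  expect_equal(sw[[1]]$reference, 1070)
})

test_that("titratable_site enforces the one-proton/one-electron state ladder", {
  expect_error(titratable_site("x", "acid", 1, rbind(a = -1), 4.0), ">= 2")
  expect_error(titratable_site("x", "acid", 1:2,
                               rbind(a = c(-1, 0), b = c(1, 0)), 4.0),
               "\\+-1")
  s <- titratable_site("x", "acid", 1:2, rbind(a = c(-0.5, -0.5),
                                               b = c(0, 0)), 4.0)
  expect_equal(site_delta_charges(s, 2), c(0.5, 0.5))
})

test_that("region tally reproduces the constructed layer pattern", {
  # 3 cations and 4 anions in the first 5 A layer from the lower surface
  z_cat <- c(-19, -17, -16); z_an <- c(-18.5, -17.5, -16.5, -15.5)
  atoms <- data.frame(
    atom_id = 1:9, atom_name = "Q", residue_name = "CHG", chain_id = "A",
    residue_number = 1:9, x = seq(0, 8) * 3, y = 0,
    z = c(z_cat, z_an, 0, 15),
    charge = c(1, 1, 1, -1, -1, -1, -1, 0, 0), radius = 2)
  st <- pb_structure(atoms)
  tal <- region_charge_tally(st, interfaces = c(-20, 20))
  expect_equal(tal$n_pos[1], 3)
  expect_equal(tal$n_neg[1], 4)
  expect_equal(tal$net[1], -1)
  expect_equal(tal$net[-1], rep(0, 4))
})

test_that("region tally is all zero without ionized groups and errors on bad interfaces", {
  st <- make_born_ion(0, 2)
  tal <- region_charge_tally(st, interfaces = c(-5, 5), layer_thickness = 2)
  expect_true(all(tal$n_pos == 0) && all(tal$n_neg == 0))
  expect_error(region_charge_tally(st, interfaces = c(100, 140)),
               "outside")
})

test_that("region tally matches a brute-force z-binning oracle on random groups", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    z <- runif(n, -24, 24)
    q <- sample(c(-1, 1), n, replace = TRUE)
    atoms <- data.frame(
      atom_id = 1:n, atom_name = "Q", residue_name = "CHG", chain_id = "A",
      residue_number = 1:n, x = runif(n, -5, 5), y = runif(n, -5, 5), z = z,
      charge = q, radius = 2)
    st <- pb_structure(atoms)
    tal <- region_charge_tally(st, interfaces = c(-25, 25))
    oracle <- brute_tally(z, q, cbind(tal$z_lo, tal$z_hi))
    expect_equal(tal$n_pos, unname(oracle[, "n_pos"]))
    expect_equal(tal$n_neg, unname(oracle[, "n_neg"]))
  }
  # total over covered range equals the overall group count
  expect_equal(sum(abs(brute_tally(runif(5), rep(1, 5),
                                   rbind(c(0, 1))))), 5)
})

test_that("edge-to-edge distance is the side-chain minimum and symmetric", {
  atoms <- data.frame(
    atom_id = 1:4, atom_name = c("N", "CB", "N", "CB"),
    residue_name = "XXX", chain_id = "A", residue_number = c(1, 1, 2, 2),
    x = c(0, 0, 9, 5), y = 0, z = 0, charge = 0, radius = 1.7)
  st <- pb_structure(atoms)
  expect_equal(edge_to_edge_distance(st, "A:1", "A:2"), 5.0)
  expect_equal(edge_to_edge_distance(st, "A:2", "A:1"), 5.0)
  expect_error(edge_to_edge_distance(st, "A:1", "B:9"), "not found")

  # multi-atom residues against an exhaustive pairwise-minimum oracle
  set.seed(5)
  for (rep in 1:4) {
    xa <- matrix(runif(15, 0, 4), 5)
    xb <- matrix(runif(15, 6, 12), 5)
    atoms <- data.frame(
      atom_id = 1:10, atom_name = paste0("C", rep(1:5, 2)),
      residue_name = "XXX", chain_id = "A",
      residue_number = rep(1:2, each = 5),
      x = c(xa[, 1], xb[, 1]), y = c(xa[, 2], xb[, 2]),
      z = c(xa[, 3], xb[, 3]), charge = 0, radius = 1.7)
    st <- pb_structure(atoms)
    oracle <- min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                       2 * xa %*% t(xb)))
    expect_equal(edge_to_edge_distance(st, "A:1", "A:2"), oracle,
                 tolerance = 1e-10)
  }
})

test_that("conformer handling preserves atom ordering and validates shape", {
  st <- make_site_cluster(4, seed = 3)$structure
  ens <- make_conformer_ensemble(st, n = 3, sigma = 0.2, seed = 9)
  st1 <- use_conformer(ens, 2)
  expect_equal(st1$atoms$atom_id, st$atoms$atom_id)
  expect_equal(st1$atoms$charge, st$atoms$charge)
  expect_false(isTRUE(all.equal(st1$atoms$x, st$atoms$x)))
  expect_error(pb_structure(st$atoms, conformers = list(matrix(0, 2, 3))),
               "conformer")
  expect_error(atom_coords(st, conformer = 1), "not present")
})
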