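test_that("a simple protein chain parses into chains and residues", {
  txt <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 2, 3.0, 0, 0),
    pdb_line(4, "CA", "SER", "A", 3, 4.5, 0, 0),
    "END")
  s <- parse_structure(txt)
  expect_equal(length(unique(s$residues$chain)), 1)
  expect_equal(nrow(s$residues), 3)
  expect_equal(s$residues$aa1, c("A", "G", "S"))
  expect_true(all(s$residues$mol == "protein"))
})

test_that("protein and nucleic chains are partitioned by residue name", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_line(3, "P", "DA", "B", 1, 10, 0, 0),
    pdb_line(4, "C1'", "DT", "B", 2, 13, 0, 0),
    pdb_line(5, "P", "DG", "C", 1, 20, 0, 0),
    "END")
  s <- parse_structure(txt)
  prot_chains <- unique(s$residues$chain[s$residues$mol == "protein"])
  na_chains <- unique(s$residues$chain[s$residues$mol == "DNA"])
  expect_equal(prot_chains, "A")
  expect_setequal(na_chains, c("B", "C"))
})

test_that("altlocs resolve to highest occupancy and H/waters are dropped", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    pdb_line(3, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_line(4, "H", "ALA", "A", 1, 2, 2, 2, element = "H"),
    pdb_line(5, "O", "HOH", "A", 90, 8, 8, 8, record = "HETATM"),
    "END")
  s <- parse_structure(txt)
  expect_equal(nrow(s$atoms), 2)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(ca$x, 0)  # occupancy 0.6 conformer wins
  expect_false(any(s$atoms$resid == "HOH"))
  expect_false(any(s$atoms$element == "H"))
})

test_that("selenomethionine is mapped to its parent amino acid", {
  txt <- c(
    pdb_line(1, "CA", "MSE", "A", 1, 0, 0, 0, record = "HETATM"),
    pdb_line(2, "CA", "ALA", "A", 2, 3, 0, 0),
    "END")
  s <- parse_structure(txt)
  expect_equal(s$residues$mol[1], "protein")
  expect_equal(s$residues$aa1[1], "M")
})

test_that("inputs without atom records are rejected", {
  expect_error(parse_structure(c("HEADER    NOTHING", "END")),
               "no ATOM/HETATM")
})

test_that("isolated atoms recover the analytic sphere area", {
  # two single-atom residues far apart: each is a free solvent-expanded
  # sphere, area 4*pi*(r_vdw + probe)^2
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  areas <- shrake_rupley(xyz, c("C", "C"), probe_radius = 1.4,
                         n_points = 960)
  expect_equal(areas, rep(4 * pi * (1.70 + 1.4)^2, 2), tolerance = 1e-6)
})

test_that("an atom enclosed by a tight shell has zero area", {
  cage <- golden_points(64) * 3.0
  xyz <- rbind(c(0, 0, 0), cage)
  areas <- shrake_rupley(xyz, rep("C", nrow(xyz)))
  expect_identical(areas[1], 0)
})

test_that("areas are non-negative, deterministic, and rigid-motion invariant", {
  fx <- sphere_fixture()
  xyz <- as.matrix(fx$structure$atoms[, c("x", "y", "z")])
  el <- fx$structure$atoms$element
  a1 <- shrake_rupley(xyz, el)
  expect_true(all(a1 >= 0))
  expect_identical(a1, shrake_rupley(xyz, el))
  set.seed(42)
  tr <- random_rigid()
  a2 <- shrake_rupley(apply_rigid(xyz, tr), el)
  # tolerance reflects the sampling resolution of the point lattice
  # the point lattice quantises each atom's area in steps of about
  # 4*pi*r^2/240 (~0.5 A^2 for carbon); allow a few steps per atom
  expect_lt(max(abs(a2 - a1)), 6)
  expect_lt(mean(abs(a2 - a1)), 1.5)
})

test_that("per-atom area in a complex never exceeds the area alone", {
  fx <- sphere_fixture()
  at <- fx$structure$atoms
  sub <- at[at$resno <= 20, ]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  alone <- 4 * pi * (1.7 + 1.4)^2  # single-atom upper bound for carbon
  areas <- shrake_rupley(xyz, rep("C", nrow(xyz)))
  expect_true(all(areas <= alone + 1e-9))
})

test_that("residue area is the exact sum of its atom areas", {
  fx <- sphere_fixture()
  acc <- compute_sasa(fx$structure)
  areas <- shrake_rupley(as.matrix(fx$structure$atoms[, c("x", "y", "z")]),
                         fx$structure$atoms$element)
  by_res <- tapply(areas, fx$structure$atoms$reskey, sum)
  expect_equal(acc$area, as.numeric(by_res[acc$reskey]))
})

test_that("surface selection is inclusive at the threshold", {
  acc <- data.frame(reskey = c("A:1", "A:2", "A:3"),
                    rasa = c(4.9, 5.0, 60.0))
  expect_setequal(surface_residues(acc, 5), c("A:2", "A:3"))
  acc0 <- data.frame(reskey = c("A:1", "A:2"), rasa = c(0, 0))
  expect_length(surface_residues(acc0, 5), 0)
})

test_that("a shell with known burial yields exactly the exposed residues", {
  fx <- cached("cage100", {
    f <- make_pseudo_protein(fixture_spec(seed = 9, n_res = 60,
                                          n_buried = 40))
    f$access <- compute_sasa(f$structure)
    f
  })
  expect_equal(nrow(fx$structure$residues), 100)
  sr <- surface_residues(fx$access)
  expect_length(sr, 60)
  expect_length(intersect(sr, fx$truth$buried), 0)
  expect_true(all(fx$access$area[fx$access$reskey %in% fx$truth$buried]
                  == 0))
})
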