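test_that("circular variance matches the analytic cases", {
  expect_equal(circular_variance(c(0, 0, 0), rbind(c(3, 0, 0)), 12), 0,
               tolerance = 1e-12)
  expect_equal(circular_variance(c(0, 0, 0), rbind(c(4, 0, 0), c(-4, 0, 0)),
                                 12), 1, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, 0, 0),
                                 rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)),
                                 12),
               1 - sqrt(3) / 3, tolerance = 1e-12)
})

test_that("circular variance is bounded and rigid-motion invariant", {
  set.seed(7)
  for (rep in 1:20) {
    cloud <- matrix(stats::rnorm(60, sd = 5), ncol = 3)
    ctr <- stats::rnorm(3, sd = 2)
    cv <- circular_variance(ctr, cloud, 12)
    if (!is.na(cv)) {
      expect_gte(cv, 0)
      expect_lte(cv, 1)
      tr <- random_rigid()
      cv2 <- circular_variance(drop(apply_rigid(rbind(ctr), tr)),
                               apply_rigid(cloud, tr), 12)
      expect_equal(cv2, cv, tolerance = 1e-10)
    }
  }
})

test_that("scaling coordinates and the radius together leaves CV unchanged", {
  set.seed(8)
  cloud <- matrix(stats::rnorm(45, sd = 4), ncol = 3)
  cv <- circular_variance(c(0, 0, 0), cloud, 10)
  expect_equal(circular_variance(c(0, 0, 0), cloud * 3.7, 37), cv,
               tolerance = 1e-12)
})

test_that("no neighbour within the radius gives an undefined CV", {
  expect_true(is.na(circular_variance(c(0, 0, 0), rbind(c(50, 0, 0)), 12)))
})

test_that("a global radius beyond the diameter includes every atom", {
  fx <- sphere_fixture()
  prot <- subset_structure(fx$structure, mol = "protein")
  cv_100 <- residue_cv(prot, 100)
  cv_huge <- residue_cv(prot, 1e6)
  expect_equal(cv_100, cv_huge, tolerance = 1e-12)
})

test_that("residue CV is the mean of its atomic CVs", {
  # two single-atom residues plus a far pair: residue CV equals atomic CV
  txt <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_line(3, "CA", "GLY", "A", 3, -3, 0, 0),
    "END")
  s <- parse_structure(txt)
  cv <- residue_cv(s, 12)
  expect_equal(unname(cv["A:1"]), 1, tolerance = 1e-12)  # antipodal pair
  expect_equal(unname(cv["A:2"]),
               circular_variance(c(3, 0, 0), rbind(c(0, 0, 0), c(-3, 0, 0)),
                                 12),
               tolerance = 1e-12)
})

test_that("buried fixture residues are more locally buried than exposed ones", {
  fx <- pocket_fixture()
  d <- fx$descriptors
  pit <- d$cv_local[d$reskey %in% fx$truth$pocket]
  shell <- d$cv_local[d$reskey %in% fx$truth$planted]
  expect_gt(min(pit), max(shell))
  expect_true(all(pit > 0.9))
})

test_that("propensity scaling is linear onto [0, 1]", {
  raw <- c(A = 2.534, R = 0, K = 1.267)
  sc <- scale_propensities(raw)
  expect_equal(unname(sc["A"]), 1)
  expect_equal(unname(sc["R"]), 0)
  expect_equal(unname(sc["K"]), 0.5)
  expect_error(scale_propensities(c(A = 0, C = 0)), "all-zero")
  expect_error(scale_propensities(c(A = -1)), ">= 0")
})

test_that("the shipped propensity table covers the 20 amino acids", {
  p <- read_propensities()
  expect_length(p, 20)
  expect_equal(max(p), 1)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(names(which.max(p)), "R")  # arginine maximal
})

test_that("conservation files clamp, pass through and report bad lines", {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c("A\t1\t0.35", "A\t2\t1.2", "A\t3B\t0.5"), tmp)
  expect_warning(sc <- conservation_from_file(tmp), "clamped")
  expect_equal(unname(sc["A:1"]), 0.35)
  expect_equal(unname(sc["A:2"]), 1.0)
  expect_equal(unname(sc["A:3B"]), 0.5)
  bad <- tempfile()
  on.exit(unlink(bad), add = TRUE)
  writeLines(c("A\t1\t0.2", "A\tx\t0.3"), bad)
  expect_error(conservation_from_file(bad), "line 2")
})

test_that("residues absent from the conservation input default to zero", {
  fx <- sphere_fixture()
  cons <- fx$truth$cons[1:10]  # drop most residues
  expect_warning(d <- compute_descriptors(fx$structure, cons),
                 "without conservation")
  expect_true(all(d$cons[!d$reskey %in% names(cons)] == 0))
})

test_that("descriptor values all live in [0, 1] for surface residues", {
  d <- sphere_fixture()$descriptors
  for (col in c("cons", "prop", "cv_local", "cv_global")) {
    expect_true(all(d[[col]][d$surface] >= 0 & d[[col]][d$surface] <= 1),
                info = col)
  }
})
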