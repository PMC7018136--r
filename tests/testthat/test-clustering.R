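# Synthetic descriptor tables and graphs give exact control over the
# clustering inputs; fixture-based tests cover the geometric path.

syn_d <- function(n, cons = 0.5, prop = 0.5, cvl = 0.5, cvg = 0.5) {
  data.frame(reskey = paste0("A:", seq_len(n)), chain = "A",
             resno = seq_len(n), insert = "", resid = "ALA", aa1 = "A",
             cons = rep_len(cons, n), prop = rep_len(prop, n),
             cv_local = rep_len(cvl, n), cv_global = rep_len(cvg, n),
             rasa = 50, surface = TRUE, stringsAsFactors = FALSE)
}

named_graph <- function(g, keys) {
  igraph::V(g)$name <- keys
  g
}

full_graph <- function(keys) {
  named_graph(igraph::make_full_graph(length(keys)), keys)
}

path_graph <- function(keys) {
  named_graph(igraph::make_ring(length(keys), circular = FALSE), keys)
}

test_that("residue adjacency follows the minimal heavy-atom distance", {
  txt <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ALA", "A", 2, 4, 0, 0),
    pdb_line(3, "CA", "ALA", "A", 3, 10, 0, 0),
    pdb_line(4, "CA", "ALA", "A", 4, 14, 0, 0),
    "END")
  s <- parse_structure(txt)
  g <- adjacency_graph(s, s$residues$reskey, cutoff = 5)
  expect_true(igraph::are_adjacent(g, "A:1", "A:2"))   # 4 A apart
  expect_false(igraph::are_adjacent(g, "A:2", "A:3"))  # 6 A apart
  expect_true(igraph::are_adjacent(g, "A:3", "A:4"))
  # a chain of residues 4 A apart forms one connected component
  txt2 <- c(vapply(1:6, function(i)
    pdb_line(i, "CA", "ALA", "A", i, 4 * i, 0, 0), character(1)), "END")
  s2 <- parse_structure(txt2)
  g2 <- adjacency_graph(s2, s2$residues$reskey, cutoff = 5)
  expect_equal(igraph::components(g2)$no, 1)
})

test_that("seeds are connected components of the top-ranked pool", {
  # two well-separated 4-residue cliques of high scorers among noise
  d <- syn_d(24, cons = 0.2, prop = 0.2)
  d$cons[1:4] <- 0.9; d$cons[5:8] <- 0.85
  g <- igraph::disjoint_union(full_graph(d$reskey[1:4]),
                              full_graph(d$reskey[5:8]))
  g <- igraph::add_vertices(g, 16, name = d$reskey[9:24])
  expected <- list(count = 24, n_surface = 24, fraction = 1)
  seeds <- detect_seeds(d, g, expected)  # pool = top 8
  expect_length(seeds, 2)
  expect_setequal(unlist(lapply(seeds, `[[`, "residues")),
                  d$reskey[1:8])
  expect_true(all(unlist(lapply(seeds, `[[`, "layer")) == "seed"))
})

test_that("1-2 residue components are kept only when nothing larger exists", {
  d <- syn_d(12, cons = 0.2)
  d$cons[c(1, 2, 5)] <- 0.9
  # residues 1-2 adjacent; 5 isolated
  g <- igraph::add_vertices(full_graph(d$reskey[1:2]), 10,
                            name = d$reskey[3:12])
  expected <- list(count = 9, n_surface = 12, fraction = 0.75)
  seeds <- detect_seeds(d, g, expected)  # pool of 3: residues 1, 2, 5
  expect_setequal(lengths(lapply(seeds, `[[`, "residues")), c(2, 1))
  # with a 3-residue component present the small ones are discarded
  d2 <- syn_d(12, cons = 0.2)
  d2$cons[1:3] <- 0.9; d2$cons[5] <- 0.85
  g2 <- igraph::add_vertices(full_graph(d2$reskey[1:3]), 9,
                             name = d2$reskey[4:12])
  expected2 <- list(count = 12, n_surface = 12, fraction = 1)
  seeds2 <- detect_seeds(d2, g2, expected2)  # pool of 4: 1,2,3 and 5
  expect_length(seeds2, 1)
  expect_setequal(seeds2[[1]]$residues, d2$reskey[1:3])
})

test_that("tied ranks resolve deterministically", {
  d <- syn_d(20, cons = 0.5, prop = 0.5)
  g <- full_graph(d$reskey)
  expected <- list(count = 6, n_surface = 20, fraction = 0.3)
  s1 <- detect_seeds(d, g, expected)
  s2 <- detect_seeds(d, g, expected)
  expect_identical(s1, s2)
  # uniform scores: lower residue number wins the tie-break
  expect_setequal(s1[[1]]$residues, paste0("A:", 1:2))
})

test_that("pocket restarts obey the per-scheme buried fractions", {
  d <- syn_d(20)
  d$cv_local <- c(rep(0.95, 1), rep(0.5, 19))  # 25% of a 4-residue seed
  patch <- list(residues = d$reskey[1:4],
                layer = stats::setNames(rep("seed", 4), d$reskey[1:4]),
                score = stats::setNames(rep(1, 4), d$reskey[1:4]))
  r1 <- restart_on_pockets(list(patch), d, pdna_config(), "SC1")
  expect_true(r1$restart)   # 25% > 20%
  expect_setequal(r1$excluded, d$reskey[d$cv_local > 0.9])
  r2 <- restart_on_pockets(list(patch), d, pdna_config(), "SC2")
  expect_false(r2$restart)  # 25% < 30%
  r3 <- restart_on_pockets(list(patch), d, pdna_config(), "SC3")
  expect_false(r3$restart)  # never applies
})

test_that("extension absorbs a high-scoring ring and merges bridged seeds", {
  # path 1-2-3-4-5-6-7: seeds at {1,2,3} and {5,6,7}, bridge residue 4
  # scores just below the seed pool but inside the extension pool
  d <- syn_d(7, cons = 0.8, prop = 0.8)
  d$cons[4] <- 0.7
  g <- path_graph(d$reskey)
  expected <- list(count = 18, n_surface = 7, fraction = 1)
  seeds <- detect_seeds(d, g, expected)
  grown <- extend_clusters(seeds, d, g, expected)
  expect_length(grown, 1)  # merged through the bridge
  expect_setequal(grown[[1]]$residues, d$reskey)
  expect_identical(unname(grown[[1]]$layer["A:4"]), "extension")
  # no admissible neighbour (seed isolated in the graph) leaves patches
  # unchanged
  d2 <- syn_d(10, cons = 0.2)
  d2$cons[1] <- 0.9
  g2 <- named_graph(igraph::make_empty_graph(10, directed = FALSE),
                    d2$reskey)
  expected2 <- list(count = 3, n_surface = 10, fraction = 0.3)
  seeds2 <- detect_seeds(d2, g2, expected2)
  expect_identical(extend_clusters(seeds2, d2, g2, expected2), seeds2)
})

test_that("the outer layer stops at the expected count and only grows", {
  d <- syn_d(20, cons = 0.8, prop = 0.8)
  g <- full_graph(d$reskey)
  expected <- list(count = 6, n_surface = 20, fraction = 0.3)
  seeds <- detect_seeds(d, g, expected)
  grown <- extend_clusters(seeds, d, g, expected)
  done <- add_outer_layer(grown, d, g, expected)
  expect_equal(sum(lengths(lapply(done, `[[`, "residues"))), 6)
  before <- unlist(lapply(grown, `[[`, "residues"))
  after <- unlist(lapply(done, `[[`, "residues"))
  expect_true(all(before %in% after))
  # already at the expected count: nothing is added
  again <- add_outer_layer(done, d, g, expected)
  expect_identical(again, done)
})

test_that("undersized predictions trigger exactly one relaxation retry", {
  # two high scorers isolated in an edgeless remainder: growth is blocked,
  # so the strict pass stays under 70% of the expected size
  d <- syn_d(30, cons = 0.2)
  d$cons[1:2] <- 0.9
  g <- igraph::add_vertices(full_graph(d$reskey[1:2]), 28,
                            name = d$reskey[3:30])
  expected <- expected_interface_size(30)
  pass <- list(patches = detect_seeds(d, g, expected),
               pocket_excluded = character(0), pocket_restarted = FALSE)
  out <- relax_and_retry(pass, d, g, expected)
  expect_true(out$relaxed)
  # a completed pass above the trigger is returned untouched
  d2 <- syn_d(10, cons = 0.8, prop = 0.8)
  g2 <- full_graph(d2$reskey)
  expected2 <- list(count = 3, n_surface = 10, fraction = 0.3)
  big <- add_outer_layer(
    extend_clusters(detect_seeds(d2, g2, expected2), d2, g2, expected2),
    d2, g2, expected2)
  expect_gte(sum(lengths(lapply(big, `[[`, "residues"))),
             0.7 * expected2$count)
  pass2 <- list(patches = big, pocket_excluded = character(0))
  out2 <- relax_and_retry(pass2, d2, g2, expected2)
  expect_false(out2$relaxed)
  expect_identical(out2$patches, big)
})

test_that("patch filtering removes 1-2 residue patches unconditionally", {
  g <- full_graph(paste0("A:", 1:30))
  mk <- function(keys) list(residues = keys,
                            layer = stats::setNames(rep("seed",
                                                        length(keys)), keys),
                            score = stats::setNames(rep(1, length(keys)),
                                                    keys))
  patches <- list(mk(paste0("A:", 1:2)), mk(paste0("A:", 3:8)))
  expected <- list(count = 20, n_surface = 30, fraction = 0.66)
  out <- filter_patches(patches, g, expected, seed = 1)
  expect_length(out, 1)
  expect_length(out[[1]]$residues, 6)
})

test_that("size filtering only engages above 70% of the expected size", {
  g <- full_graph(paste0("A:", 1:40))
  mk <- function(keys) list(residues = keys,
                            layer = stats::setNames(rep("seed",
                                                        length(keys)), keys),
                            score = stats::setNames(rep(1, length(keys)),
                                                    keys))
  # single patch at 60% of expected: kept without size testing
  expected <- list(count = 10, n_surface = 40, fraction = 0.25)
  out <- filter_patches(list(mk(paste0("A:", 1:6))), g, expected, seed = 1)
  expect_length(out, 1)
  # oversized prediction: small patches fall below the random percentile
  # (on a complete graph the null patch size equals the seed pool size)
  expected2 <- list(count = 40, n_surface = 40, fraction = 1)
  patches <- list(mk(paste0("A:", 1:3)), mk(paste0("A:", 4:8)),
                  mk(paste0("A:", 9:40)))
  out2 <- filter_patches(patches, g, expected2, seed = 1)
  expect_length(out2, 1)
  expect_length(out2[[1]]$residues, 32)
})

test_that("the full clustering is deterministic for fixed inputs", {
  fx <- sphere_fixture()
  p1 <- run_prediction(fx$structure, fx$descriptors, seed = 4)
  p2 <- run_prediction(fx$structure, fx$descriptors, seed = 4)
  expect_identical(prediction_table(p1), prediction_table(p2))
  expect_identical(lapply(p1$patches, `[[`, "residues"),
                   lapply(p2$patches, `[[`, "residues"))
})

test_that("planted patches are recovered with layered structure", {
  fx <- sphere_fixture()
  pred <- run_prediction(fx$structure, fx$descriptors, seed = 1)
  keys <- predicted_residues(pred)
  expect_true(all(keys %in% fx$truth$planted))
  layers <- unlist(lapply(pred$patches, `[[`, "layer"))
  expect_true(all(c("seed", "extension", "outer") %in% layers))
  # layers partition each patch
  for (p in pred$patches) {
    expect_setequal(names(p$layer), p$residues)
  }
})
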