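# Shared lazily-built fixtures, cached so expensive geometry and SASA work
# is done once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

sphere_fixture <- function() cached("sphere", {
  fx <- make_pseudo_protein(fixture_spec(seed = 1, n_res = 150))
  fx$descriptors <- compute_descriptors(fx$structure, fx$truth$cons)
  fx
})

concave_fixture <- function() cached("concave", {
  fx <- make_pseudo_protein(fixture_spec(seed = 1, n_res = 150,
                                         geometry = "concave-envelope",
                                         planted_aa = "SER"))
  fx$descriptors <- compute_descriptors(fx$structure, fx$truth$cons)
  fx
})

pocket_fixture <- function() cached("pocket", {
  fx <- make_pseudo_protein(fixture_spec(seed = 1, n_res = 150,
                                         pocket = TRUE))
  fx$descriptors <- compute_descriptors(fx$structure, fx$truth$cons)
  fx
})

bound_pair_fixture <- function() cached("bound_pair", {
  make_bound_pair(fixture_spec(seed = 3, n_res = 150))
})

# random rigid-body transform (proper rotation + translation)
random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(xyz, tr) {
  sweep(xyz %*% tr$rot, 2, tr$shift, "+")
}

# minimal hand-written PDB text builder for parser tests
pdb_line <- function(serial, elety, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", record = "ATOM  ", element = NULL) {
  if (is.null(element)) element <- substr(elety, 1, 1)
  name_field <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("%s%5d %4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, alt, resid, chain, resno,
          x, y, z, occ, 0, element)
}

# golden-spiral unit sphere lattice (duplicated here so tests stay on the
# package's public surface)
golden_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
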