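# Seeded synthetic fixtures: pseudo-protein atom clouds with controllable
# geometry, planted high-signal patches, optional buried residues, deep
# conserved pockets, and bound/free pairs with a DNA pseudo-strand.
#
# Pseudo-residues use real amino-acid names so the propensity table
# applies: planted patches are arginine/lysine-rich (DNA interfaces are
# enriched in positively charged and polar residues), backgrounds are
# hydrophobic/acidic. None of this is a physically realistic protein model;
# it provides geometry and signals with known ground truth.

AA_BACKGROUND <- c("LEU", "VAL", "ILE", "PHE", "ALA", "GLU", "ASP", "MET")

#' Specification of a synthetic fixture
#'
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param n_res number of shell residues (>= 20).
#' @param geometry "sphere", "concave-envelope" or "helix-bundle".
#' @param planted_n planted patch size (0 disables the plant).
#' @param planted_cons conservation of planted residues (default 0.8;
#'   background is uniform on [0.1, 0.3], giving the 0.4+ contrast used in
#'   recovery tests).
#' @param planted_aa residue types for the planted patch.
#' @param n_buried number of fully buried single-atom residues (each
#'   enclosed in an atom cage carried by a host surface residue).
#' @param pocket add a deep, conserved, highly buried pocket (local
#'   circular variance above 0.9) on the side opposite the planted patch.
#' @param spacing target shell spacing between residue centres (Angstrom).
#' @return a fixture specification list.
#' @export
fixture_spec <- function(seed, n_res = 150, geometry = "sphere",
                         planted_n = 12, planted_cons = 0.8,
                         planted_aa = "ARG", n_buried = 0,
                         pocket = FALSE, spacing = 6.0) {
  if (n_res < 20) stop("n_res must be >= 20")
  geometry <- match.arg(geometry,
                        c("sphere", "concave-envelope", "helix-bundle"))
  list(seed = seed, n_res = n_res, geometry = geometry,
       planted_n = planted_n, planted_cons = planted_cons,
       planted_aa = planted_aa, n_buried = n_buried, pocket = pocket,
       spacing = spacing)
}

# quasi-uniform directions (Fibonacci lattice)
fib_sphere <- function(n) sphere_points(n)

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal frame with u as third axis
frame_of <- function(u) {
  u <- unit(u)
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- unit(pracma_cross(u, a))
  t2 <- pracma_cross(u, t1)
  list(u = u, t1 = t1, t2 = t2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# small rigid atom cluster for one pseudo-residue; CB points outward
residue_cluster <- function(center, outward, resid) {
  f <- frame_of(outward)
  atoms <- rbind(
    CA = center,
    N = center + 1.46 * f$t1,
    C = center - 1.20 * f$t1 + 0.85 * f$t2,
    O = center - 1.90 * f$t1 - 0.60 * f$t2
  )
  elety <- c("CA", "N", "C", "O")
  if (resid != "GLY") {
    atoms <- rbind(atoms, CB = center + 1.53 * f$u)
    elety <- c(elety, "CB")
  }
  list(xyz = atoms, elety = elety,
       element = substr(elety, 1, 1))
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v / sqrt(1 + phi^2)
}

#' Generate a pseudo-protein structure with known ground truth
#'
#' Realises residues as small rigid atom clusters on the chosen geometry.
#' The sphere geometry is a shell of residues; the concave-envelope
#' geometry punches a cylindrical channel through the shell whose lining
#' residues are globally buried (circular variance at 100 A above 0.6) -
#' the planted patch lines the channel waist. The optional pocket is a
#' deep, narrow, conserved pit whose residues have local circular variance
#' above 0.9 while remaining probe-accessible. Buried residues are single
#' atoms enclosed in a cage of host-residue atoms, so their accessible area
#' is exactly zero.
#'
#' @param spec a specification from \code{\link{fixture_spec}}.
#' @return list with \code{structure} (a \code{pdna_structure}),
#'   \code{pdb} (PDB text), and \code{truth}: planted/buried/pocket residue
#'   keys, per-residue conservation and residue types.
#' @export
make_pseudo_protein <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_res
  R <- sqrt(n * spec$spacing^2 / (4 * pi))
  rows <- list()
  add_res <- function(center, outward, resid, chain = "A") {
    cl <- residue_cluster(center, outward, resid)
    rows[[length(rows) + 1]] <<- data.frame(
      resid = resid, chain = chain, elety = cl$elety,
      element = cl$element, x = cl$xyz[, 1], y = cl$xyz[, 2],
      z = cl$xyz[, 3], stringsAsFactors = FALSE)
  }
  add_atoms <- function(xyz, resid, elety = "CA", chain = "A") {
    xyz <- matrix(xyz, ncol = 3)
    rows[[length(rows) + 1]] <<- data.frame(
      resid = resid, chain = chain,
      elety = rep(elety, length.out = nrow(xyz)),
      element = substr(rep(elety, length.out = nrow(xyz)), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  }

  planted_idx <- integer(0)
  shell_dirs <- fib_sphere(n)
  if (isTRUE(spec$pocket)) {
    # clear a mouth in the shell above the pocket (placed at -z)
    shell_dirs <- shell_dirs[shell_dirs[, 3] > -cos(35 * pi / 180), ,
                             drop = FALSE]
    n <- nrow(shell_dirs)
  }
  if (spec$geometry == "sphere") {
    centers <- shell_dirs * R
    outward <- shell_dirs
    if (spec$planted_n > 0) {
      planted_idx <- order(-shell_dirs[, 3])[seq_len(spec$planted_n)]
    }
  } else if (spec$geometry == "concave-envelope") {
    ch_r <- 6.5           # channel radius
    keep <- abs(shell_dirs[, 3]) < cos(asin(min(0.99, (ch_r + 2) / R)))
    sh <- shell_dirs[keep, , drop = FALSE]
    centers <- sh * R
    outward <- sh
    # channel lining: rings of residues facing the channel axis
    zs <- seq(-R + 6, R - 6, by = 5)
    m <- 6
    for (z in zs) {
      for (k in seq_len(m)) {
        ang <- 2 * pi * (k - 1) / m + z  # twist to avoid stacking
        pos <- c(ch_r * cos(ang), ch_r * sin(ang), z)
        centers <- rbind(centers, pos)
        outward <- rbind(outward, unit(c(-cos(ang), -sin(ang), 0)))
      }
    }
    n_shell <- sum(keep)
    n_chan <- length(zs) * m
    if (spec$planted_n > 0) {
      chan_idx <- n_shell + order(abs(centers[(n_shell + 1):
                                                (n_shell + n_chan), 3]))
      planted_idx <- chan_idx[seq_len(min(spec$planted_n, n_chan))]
    }
  } else { # helix-bundle
    per <- ceiling(n / 4)
    centers <- NULL
    outward <- NULL
    axes <- rbind(c(6, 6, 0), c(-6, 6, 0), c(-6, -6, 0), c(6, -6, 0))
    for (h in 1:4) {
      t <- seq_len(per)
      ang <- 1.75 * t + h * pi / 2
      pos <- cbind(axes[h, 1] + 4.0 * cos(ang),
                   axes[h, 2] + 4.0 * sin(ang),
                   1.55 * t - 1.55 * per / 2)
      centers <- rbind(centers, pos)
      outward <- rbind(outward,
                       t(apply(pos, 1, function(p)
                         unit(c(p[1], p[2], 0.2 * p[3])))))
    }
    centers <- centers[seq_len(n), , drop = FALSE]
    outward <- outward[seq_len(n), , drop = FALSE]
    if (spec$planted_n > 0) {
      planted_idx <- order(-centers[, 3])[seq_len(spec$planted_n)]
    }
  }

  n_main <- nrow(centers)
  aa <- sample(AA_BACKGROUND, n_main, replace = TRUE)
  cons <- stats::runif(n_main, 0.1, 0.3)
  if (length(planted_idx)) {
    aa[planted_idx] <- rep(spec$planted_aa,
                           length.out = length(planted_idx))
    # radial conservation gradient within the site (centres of binding
    # sites are more conserved than their edges); keeps the contrast with
    # the background at >= planted_cons - 0.3
    ctr <- colMeans(centers[planted_idx, , drop = FALSE])
    dd <- sqrt(rowSums((centers[planted_idx, , drop = FALSE] -
                          matrix(ctr, length(planted_idx), 3,
                                 byrow = TRUE))^2))
    rel <- if (max(dd) > 0) dd / max(dd) else dd
    cons[planted_idx] <- spec$planted_cons + 0.049 * (1 - rel)
  }
  for (i in seq_len(n_main)) add_res(centers[i, ], outward[i, ], aa[i])
  labels <- rep("background", n_main)
  labels[planted_idx] <- "planted"

  # buried residues: single atoms in icosahedral cages whose atoms belong
  # to the adjacent host shell residue, so the enclosed atom has zero area
  if (spec$n_buried > 0) {
    hosts <- setdiff(seq_len(n_main), planted_idx)
    if (length(hosts) < spec$n_buried) stop("too few residues to host cages")
    hosts <- hosts[seq_len(spec$n_buried)]
    ico <- icosahedron() * 3.2
    for (h in hosts) {
      cage_center <- centers[h, ] - 5.5 * outward[h, ]
      cage <- sweep(ico, 2, cage_center, "+")
      # cage atoms appended to the host residue
      rows[[h]] <- rbind(rows[[h]], data.frame(
        resid = rows[[h]]$resid[1], chain = "A",
        elety = paste0("C", seq_len(12)), element = "C",
        x = cage[, 1], y = cage[, 2], z = cage[, 3],
        stringsAsFactors = FALSE))
      add_res_single <- cage_center
      add_atoms(add_res_single, "ALA", "CA")
      labels <- c(labels, "buried")
      cons <- c(cons, 0.05)
    }
  }

  # deep conserved pocket opposite the planted patch: a pit of arginines
  # beneath the shell, enclosed by a plug of wall atoms except for a
  # narrow probe-accessible exit
  if (isTRUE(spec$pocket)) {
    axis <- c(0, 0, -1)
    f <- frame_of(axis)
    pit_center <- (R - 4) * axis
    pit_r <- 2.0
    n_pit <- 6
    for (k in seq_len(n_pit)) {
      ang <- 2 * pi * (k - 1) / n_pit
      pos <- pit_center + 1.8 * axis +
        pit_r * (cos(ang) * f$t1 + sin(ang) * f$t2)
      add_res(pos, axis, "ARG")  # side chains point toward the exit
      labels <- c(labels, "pocket")
      cons <- c(cons, 0.95)
    }
    # enclosing wall: two concentric shells of single-atom residues
    # around the pit centre, pierced by a long narrow chimney toward the
    # surface. The tube is wide enough for the solvent probe (radius 4.6
    # A) but, being long, subtends a small solid angle from the pit, so
    # the pit residues are highly buried (local CV > 0.9) yet remain
    # probe-accessible.
    chim_r <- 4.6
    wall_shells <- c(9.5, 11.5)
    wall_ns <- c(340, 480)
    wall <- NULL
    for (ws in seq_along(wall_shells)) {
      wall_dirs <- fib_sphere(wall_ns[ws])
      hole <- wall_dirs[, 3] <
        -cos(asin(min(0.99, (chim_r + 1.2) / wall_shells[ws])))
      wall <- rbind(wall,
                    sweep(wall_dirs[!hole, , drop = FALSE] *
                            wall_shells[ws], 2, pit_center, "+"))
    }
    for (zz in seq(3.5, 13, by = 1.8)) {
      ang <- 2 * pi * seq_len(15) / 15 + zz
      ring <- sweep(outer(cos(ang), chim_r * f$t1) +
                      outer(sin(ang), chim_r * f$t2),
                    2, pit_center + zz * axis, "+")
      wall <- rbind(wall, ring)
    }
    for (w in seq_len(nrow(wall))) {
      add_atoms(wall[w, ], "GLY", "CA")
      labels <- c(labels, "wall")
      cons <- c(cons, 0.05)
    }
  }

  at <- do.call(rbind, rows)
  res_id <- rep(seq_along(rows), vapply(rows, nrow, integer(1)))
  at$resno <- res_id
  struct <- fixture_structure(at)
  keys <- struct$residues$reskey
  truth <- list(
    planted = keys[labels == "planted"],
    buried = keys[labels == "buried"],
    pocket = keys[labels == "pocket"],
    wall = keys[labels == "wall"],
    cons = stats::setNames(cons, keys),
    resid = stats::setNames(struct$residues$resid, keys)
  )
  list(structure = struct, pdb = fixture_pdb_text(struct), truth = truth)
}

# assemble a pdna_structure directly from a fixture atom table
fixture_structure <- function(at) {
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = "",
    resid = at$resid, elety = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z, o = 1,
    stringsAsFactors = FALSE
  )
  atoms$mol <- molecule_class(atoms$resid)
  atoms$reskey <- res_key(atoms$chain, atoms$resno, atoms$insert)
  res_idx <- !duplicated(atoms$reskey)
  residues <- data.frame(
    reskey = atoms$reskey[res_idx], chain = atoms$chain[res_idx],
    resno = atoms$resno[res_idx], insert = "",
    resid = atoms$resid[res_idx], mol = atoms$mol[res_idx],
    stringsAsFactors = FALSE
  )
  residues$aa1 <- aa_one(residues$resid)
  residues$natoms <- as.integer(table(atoms$reskey)[residues$reskey])
  out <- list(id = "fixture", atoms = atoms, residues = residues)
  class(out) <- "pdna_structure"
  out
}

# PDB text for a fixture structure (fixed-format ATOM records)
fixture_pdb_text <- function(struct) {
  a <- struct$atoms
  name_field <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                       a$elety)
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_field, a$resid, a$chain, a$resno,
    a$x, a$y, a$z, a$o, 0, a$element)
  c(lines, "END")
}

#' Generate a bound/free pair with a DNA pseudo-strand over the plant
#'
#' Builds a sphere pseudo-protein with a planted patch, then places a DNA
#' pseudo-strand (nucleotides with standard backbone and base atom names)
#' just outside the planted residues, so that exactly those residues lose
#' accessible area in the bound form. Support/core/rim labels derived at
#' generation time (from the two accessibility contexts) are emitted as
#' truth.
#'
#' @param spec a \code{\link{fixture_spec}} (geometry is forced to sphere).
#' @param strand_gap radial gap (Angstrom) between the protein shell and
#'   the nucleotide centres.
#' @return list with \code{bound}/\code{free} structures, their PDB texts,
#'   and \code{truth} (planted keys, conservation, and the generation-time
#'   SCR labels).
#' @export
make_bound_pair <- function(spec, strand_gap = 3.5) {
  spec$geometry <- "sphere"
  fx <- make_pseudo_protein(spec)
  struct <- fx$structure
  planted <- fx$truth$planted
  pidx <- match(planted, struct$residues$reskey)
  # nucleotide centres above each planted residue
  rows <- list()
  n_at <- 0L
  R <- max(sqrt(rowSums(atom_xyz(struct)^2)))
  for (i in seq_along(pidx)) {
    res_at <- struct$atoms[struct$atoms$reskey == planted[i], , drop = FALSE]
    ca <- as.numeric(res_at[res_at$elety == "CA", c("x", "y", "z")][1, ])
    u <- unit(ca)
    f <- frame_of(u)
    c0 <- ca + (strand_gap + 1.5) * u
    bb <- rbind(
      P = c0 + 1.2 * u,
      `OP1` = c0 + 1.9 * u + 0.9 * f$t1,
      `OP2` = c0 + 1.9 * u - 0.9 * f$t1,
      `O5'` = c0 + 0.6 * u + 1.2 * f$t2,
      `C4'` = c0 + 1.0 * f$t1 + 0.8 * f$t2,
      `C1'` = c0 - 0.5 * u + 0.9 * f$t1
    )
    base <- rbind(
      N1 = c0 - 1.6 * u,
      C2 = c0 - 2.3 * u + 0.8 * f$t1,
      N3 = c0 - 2.3 * u - 0.8 * f$t1
    )
    xyz <- rbind(bb, base)
    rows[[i]] <- data.frame(
      resid = if (i %% 2) "DA" else "DT", chain = "B",
      elety = rownames(xyz),
      element = substr(gsub("[^A-Z].*$", "", rownames(xyz)), 1, 1),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      resno = i, stringsAsFactors = FALSE)
  }
  dna <- do.call(rbind, rows)
  dna$element <- substr(dna$elety, 1, 1)
  prot_at <- struct$atoms[, c("resid", "chain", "elety", "element",
                              "x", "y", "z", "resno")]
  bound <- fixture_structure(rbind(prot_at, dna))
  free <- struct
  iface <- interface_residues(bound)
  truth <- fx$truth
  truth$scr <- stats::setNames(iface$scr, iface$reskey)
  list(bound = bound, free = free,
       bound_pdb = fixture_pdb_text(bound), free_pdb = fx$pdb,
       truth = truth)
}

#' Generate a synthetic alignment with a matching tree
#'
#' Sequences evolve along a random tree: conserved columns are identical in
#' every sequence, the rest mutate per branch with a probability set by
#' \code{noise} and the branch length. The query is \code{seq1}.
#'
#' @param n_seq number of sequences (>= 3).
#' @param length alignment length.
#' @param conserved_columns integer indices of fully conserved columns.
#' @param noise per-branch mutation intensity of the remaining columns
#'   (0-1).
#' @param seed RNG seed.
#' @return list with \code{alignment} (character matrix), \code{fasta}
#'   (text lines), \code{tree} (phylo), \code{newick} (text),
#'   \code{conserved} (logical per column) and \code{query_id}.
#' @export
make_alignment <- function(n_seq = 20, length = 100,
                           conserved_columns = seq_len(20), noise = 0.3,
                           seed = 1) {
  if (n_seq < 3) stop("need at least 3 sequences")
  set.seed(seed)
  aa20 <- sort(unique(unname(AA3[1:20])))
  tree <- ape::rtree(n_seq, tip.label = paste0("seq", seq_len(n_seq)))
  tree$edge.length <- tree$edge.length / mean(tree$edge.length) * 0.3
  root_seq <- sample(aa20, length, replace = TRUE)
  conserved <- seq_len(length) %in% conserved_columns
  n_node <- max(tree$edge)
  seqs <- vector("list", n_node)
  root <- tree$edge[1, 1]
  seqs[[root]] <- root_seq
  edge_order <- tree$edge[order(match(tree$edge[, 1],
                                      c(root, tree$edge[, 2]))), ]
  # preorder traversal: parents are always filled before children
  edges <- tree$edge
  todo <- rep(TRUE, nrow(edges))
  while (any(todo)) {
    for (k in which(todo)) {
      p <- edges[k, 1]
      if (!is.null(seqs[[p]])) {
        s <- seqs[[p]]
        bl <- tree$edge.length[k]
        p_mut <- noise * (1 - exp(-3 * bl))
        mut <- !conserved & stats::runif(length) < p_mut
        if (any(mut)) {
          s[mut] <- vapply(s[mut], function(x)
            sample(setdiff(aa20, x), 1), character(1))
        }
        seqs[[edges[k, 2]]] <- s
        todo[k] <- FALSE
      }
    }
  }
  aln <- do.call(rbind, seqs[seq_len(n_seq)])
  rownames(aln) <- tree$tip.label
  fasta <- as.vector(rbind(paste0(">", rownames(aln)),
                           apply(aln, 1, paste, collapse = "")))
  list(alignment = aln, fasta = fasta, tree = tree,
       newick = ape::write.tree(tree), conserved = conserved,
       query_id = "seq1")
}
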