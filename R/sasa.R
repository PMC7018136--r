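# Solvent-accessible surface area by Shrake-Rupley sphere sampling.

.pdna_cache <- new.env(parent = emptyenv())

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice); the same point set is reused for every atom.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom accessible surface areas (Shrake-Rupley)
#'
#' Samples points on each atom's solvent-expanded sphere (van der Waals
#' radius + probe radius) and counts the fraction not occluded by any other
#' atom's expanded sphere. Deterministic for a fixed point count.
#'
#' @param xyz numeric matrix (n x 3) of atom coordinates in Angstrom.
#' @param elements character vector of element symbols (for radii).
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points sphere sampling points per atom (default 240).
#' @return numeric vector of per-atom accessible areas in A^2.
#' @export
shrake_rupley <- function(xyz, elements, probe_radius = 1.4, n_points = 240) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 2) stop("accessibility requires a structure with at least 2 atoms")
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  radii <- vdw_radius(elements) + probe_radius
  sp <- sphere_points(n_points)
  # neighbour lists: atoms whose expanded spheres can intersect
  cutoff <- 2 * max(radii)
  nb <- neighbour_list(xyz, cutoff)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    ri <- radii[i]
    if (length(js) == 0) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    js <- js[sqrt(rowSums((xyz[js, , drop = FALSE] -
                             matrix(xyz[i, ], length(js), 3,
                                    byrow = TRUE))^2)) < ri + radii[js]]
    if (length(js) == 0) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    pts <- sp * ri
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in js) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= radii[j]^2
      if (!any(free)) break
    }
    areas[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  areas
}

# Coarse neighbour list within a cutoff, computed blockwise so memory stays
# bounded for large structures.
neighbour_list <- function(xyz, cutoff, block = 512L) {
  n <- nrow(xyz)
  out <- vector("list", n)
  c2 <- cutoff^2
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    for (k in seq_along(idx)) {
      i <- idx[k]
      js <- which(d2[k, ] <= c2)
      out[[i]] <- js[js != i]
    }
  }
  out
}

max_asa_table <- function() {
  if (is.null(.pdna_cache$max_asa)) {
    path <- system.file("extdata", "max_asa.tsv", package = "pdnasite")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    .pdna_cache$max_asa <- stats::setNames(tab$max_asa, tab$resid)
  }
  .pdna_cache$max_asa
}

#' Per-residue solvent accessibility
#'
#' Computes per-atom accessible areas in the context of every atom present
#' in \code{struct} and sums them per residue. Relative accessibility
#' (rASA, percent) is the residue area divided by a fixed per-amino-acid
#' reference maximum (theoretical maxima of Tien et al. 2013, shipped as a
#' two-column config file). Residues of unknown type (nucleic, ligands) get
#' \code{NA} rASA and are excluded from surface sets.
#'
#' @param struct a \code{pdna_structure}; all its atoms act as occluders.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points sphere sampling points per atom.
#' @param context free-form tag stored with the record (e.g. "free",
#'   "complex").
#' @return data frame (class \code{pdna_access}): reskey, chain, resno,
#'   insert, resid, area (A^2), rasa (percent), context.
#' @export
#' @examples
#' fx <- make_pseudo_protein(fixture_spec(seed = 1, n_res = 30))
#' acc <- compute_sasa(fx$structure)
#' head(acc$rasa)
compute_sasa <- function(struct, probe_radius = 1.4, n_points = 240,
                         context = "free") {
  stopifnot(inherits(struct, "pdna_structure"))
  areas <- shrake_rupley(atom_xyz(struct), struct$atoms$element,
                         probe_radius, n_points)
  per_res <- tapply(areas, struct$atoms$reskey, sum)
  res <- struct$residues
  out <- data.frame(
    reskey = res$reskey, chain = res$chain, resno = res$resno,
    insert = res$insert, resid = res$resid,
    area = as.numeric(per_res[res$reskey]),
    stringsAsFactors = FALSE
  )
  ref <- max_asa_table()[res$resid]
  out$rasa <- ifelse(is.na(ref), NA_real_, 100 * out$area / ref)
  out$context <- context
  class(out) <- c("pdna_access", "data.frame")
  out
}

#' Surface residues from an accessibility record
#'
#' @param acc a \code{pdna_access} record from \code{\link{compute_sasa}}.
#' @param threshold minimal rASA (percent, inclusive) for a residue to count
#'   as surface; default 5.
#' @return character vector of residue keys with \code{rasa >= threshold}.
#' @export
surface_residues <- function(acc, threshold = 5) {
  acc$reskey[!is.na(acc$rasa) & acc$rasa >= threshold]
}
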