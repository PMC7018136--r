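# Per-residue descriptors: circular variance (local/global), scaled
# DNA-interface propensities, and conservation loaded from file.

#' Circular variance of one atom
#'
#' CV(i) = 1 - (1/n_i) * || sum_j r_ij / ||r_ij|| || over the n_i atoms j
#' within \code{r_c} Angstrom of atom i (inclusive cutoff). Values near 0
#' indicate a protruding position, values near 1 a buried one.
#'
#' @param center numeric length-3 coordinate of the atom.
#' @param coords numeric matrix (m x 3) of the other atoms.
#' @param r_c neighbourhood radius in Angstrom.
#' @return CV in [0, 1], or \code{NA} if no neighbour lies within
#'   \code{r_c}.
#' @export
#' @examples
#' circular_variance(c(0, 0, 0), rbind(c(3, 0, 0), c(-3, 0, 0)), 12) # 1
circular_variance <- function(center, coords, r_c) {
  if (r_c <= 0) stop("r_c must be > 0")
  coords <- matrix(as.numeric(coords), ncol = 3)
  d <- sweep(coords, 2, as.numeric(center))
  dist <- sqrt(rowSums(d^2))
  keep <- dist <= r_c & dist > 0
  if (!any(keep)) return(NA_real_)
  u <- d[keep, , drop = FALSE] / dist[keep]
  1 - sqrt(sum(colSums(u)^2)) / sum(keep)
}

# Vectorised CV for all atoms of a coordinate set, blockwise.
atom_cv <- function(xyz, r_c, block = 256L) {
  n <- nrow(xyz)
  out <- numeric(n)
  sq <- rowSums(xyz^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    d2[d2 < 0] <- 0
    for (k in seq_along(idx)) {
      i <- idx[k]
      dist <- sqrt(d2[k, ])
      keep <- which(dist <= r_c & dist > 1e-9)
      keep <- keep[keep != i]
      if (length(keep) == 0) {
        out[i] <- NA_real_
        next
      }
      dd <- xyz[keep, , drop = FALSE] -
        matrix(xyz[i, ], length(keep), 3, byrow = TRUE)
      u <- dd / dist[keep]
      out[i] <- 1 - sqrt(sum(colSums(u)^2)) / length(keep)
    }
  }
  out
}

#' Per-residue circular variance
#'
#' The CV of a residue is the unweighted mean of the CVs of its atoms.
#' Atoms without any neighbour within \code{r_c} are treated as missing and
#' the mean is taken over the defined atoms only; a residue with no defined
#' atom gets \code{NA}.
#'
#' @param struct a \code{pdna_structure}; the CV neighbourhood is all its
#'   atoms.
#' @param r_c neighbourhood radius in Angstrom.
#' @return named numeric vector of residue CVs, names are residue keys.
#' @export
residue_cv <- function(struct, r_c) {
  cv <- atom_cv(atom_xyz(struct), r_c)
  named <- tapply(cv, struct$atoms$reskey, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  stats::setNames(as.numeric(named[struct$residues$reskey]),
                  struct$residues$reskey)
}

#' Scale a raw propensity table to [0, 1]
#'
#' Divides every raw value by the table maximum, so the most DNA-interface
#' prone amino acid maps to 1 and a zero propensity maps to 0.
#'
#' @param raw named numeric vector (one-letter amino acid -> raw
#'   propensity), all values >= 0.
#' @return named numeric vector of scaled propensities in [0, 1].
#' @export
scale_propensities <- function(raw) {
  if (any(raw < 0)) stop("raw propensities must be >= 0")
  m <- max(raw)
  if (m == 0) stop("all-zero propensity table cannot be scaled")
  raw / m
}

#' Read an amino-acid interface propensity table
#'
#' Two-column TSV (one-letter amino acid, raw value); the 20 standard amino
#' acids must all be present. Values are scaled to [0, 1] with
#' \code{\link{scale_propensities}}.
#'
#' @param path TSV path; default is the propensity table shipped with the
#'   package (a synthetic stand-in for a published protein-DNA interface
#'   propensity scale: range 0-2.534 with arginine maximal, positively
#'   charged and polar residues high, hydrophobics low).
#' @return named numeric vector of 20 scaled propensities.
#' @export
read_propensities <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dna_propensity_synthetic.tsv",
                        package = "pdnasite")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  raw <- stats::setNames(tab$raw, tab$aa)
  std <- sort(unique(unname(AA3[1:20])))
  missing <- setdiff(std, names(raw))
  if (length(missing)) {
    stop("propensity table lacks entries for: ",
         paste(missing, collapse = ", "))
  }
  scale_propensities(raw)
}

#' Read per-residue conservation scores from file
#'
#' TSV with columns chain, resno (author numbering, optionally suffixed
#' with an insertion code) and score. Scores are clamped to [0, 1] with a
#' warning. Residues of the structure absent from the file default to 0
#' (also with a warning) when the scores are later joined by
#' \code{\link{compute_descriptors}}.
#'
#' @param path TSV path.
#' @return named numeric vector, names are residue keys
#'   (\code{chain:resno[insert]}).
#' @export
conservation_from_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  out <- numeric(0)
  keys <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1]]
    if (length(parts) != 3) {
      stop("malformed conservation line ", i, ": expected 3 fields, got ",
           length(parts))
    }
    score <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(score)) stop("malformed conservation line ", i,
                           ": non-numeric score '", parts[3], "'")
    m <- regmatches(parts[2], regexec("^(-?[0-9]+)([A-Za-z]?)$", parts[2]))[[1]]
    if (length(m) == 0) stop("malformed conservation line ", i,
                             ": bad residue number '", parts[2], "'")
    keys <- c(keys, res_key(parts[1], m[2], m[3]))
    out <- c(out, score)
  }
  if (any(out < 0 | out > 1)) {
    warning("conservation scores outside [0, 1] clamped")
    out <- pmin(1, pmax(0, out))
  }
  stats::setNames(out, keys)
}

#' Assemble the per-residue descriptor set
#'
#' Computes, for every surface residue of a protein structure, the four
#' descriptors consumed by the scoring schemes: conservation (cons, [0,1]),
#' scaled DNA-interface propensity (prop, [0,1]), and local/global circular
#' variance (cv_local at \code{r_local} = 12 A, cv_global at
#' \code{r_global} = 100 A).
#'
#' @param struct a \code{pdna_structure}; only its protein component is
#'   used.
#' @param conservation named numeric vector of conservation scores keyed by
#'   residue key (see \code{\link{conservation_from_file}} and
#'   \code{\link{tree_trace_conservation}}). Residues without a score get 0
#'   with a warning.
#' @param propensities named numeric vector of scaled propensities from
#'   \code{\link{read_propensities}}.
#' @param config configuration list from \code{\link{pdna_config}}.
#' @param access optional precomputed \code{pdna_access} record for the
#'   protein-only structure (recomputed if NULL).
#' @return data frame (class \code{pdna_descriptors}): reskey, chain,
#'   resno, insert, resid, aa1, cons, prop, cv_local, cv_global, rasa,
#'   surface.
#' @export
compute_descriptors <- function(struct, conservation,
                                propensities = read_propensities(),
                                config = pdna_config(), access = NULL) {
  prot <- subset_structure(struct, mol = "protein")
  if (is.null(access)) {
    access <- compute_sasa(prot, probe_radius = config$probe_radius,
                           n_points = config$sasa_points, context = "free")
  }
  cvl <- residue_cv(prot, config$r_local)
  cvg <- residue_cv(prot, config$r_global)
  res <- prot$residues
  cons <- conservation[res$reskey]
  if (anyNA(cons)) {
    warning(sum(is.na(cons)),
            " residue(s) without conservation score set to 0")
    cons[is.na(cons)] <- 0
  }
  if (any(cons < 0 | cons > 1)) {
    warning("conservation scores outside [0, 1] clamped")
    cons <- pmin(1, pmax(0, cons))
  }
  out <- data.frame(
    reskey = res$reskey, chain = res$chain, resno = res$resno,
    insert = res$insert, resid = res$resid, aa1 = res$aa1,
    cons = unname(cons),
    prop = unname(propensities[res$aa1]),
    cv_local = unname(cvl[res$reskey]),
    cv_global = unname(cvg[res$reskey]),
    rasa = access$rasa[match(res$reskey, access$reskey)],
    stringsAsFactors = FALSE
  )
  out$surface <- !is.na(out$rasa) & out$rasa >= config$surface_rasa
  class(out) <- c("pdna_descriptors", "data.frame")
  out
}
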