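# Experimental interface extraction and the support-core-rim model.

#' Extract the protein-DNA interface from a bound complex
#'
#' Computes each protein residue's relative accessibility twice: in the
#' full complex context (rasa_dna) and with all nucleic atoms deleted
#' (rasa_free). Interface residues are those more buried in the presence of
#' the nucleic partner (delta = rasa_free - rasa_dna above a small
#' numerical tolerance that suppresses sphere-sampling noise). Each
#' interface residue is classified with \code{\link{classify_scr}}. When
#' the complex contains several protein chains, every chain's interface is
#' computed in the full biological-unit context. RNA chains are treated
#' exactly like DNA.
#'
#' @param bound a \code{pdna_structure} with at least one protein and one
#'   nucleic (DNA or RNA) chain.
#' @param config configuration list (probe radius, sampling points,
#'   delta-rASA tolerance).
#' @return data frame (class \code{pdna_interface}): reskey, chain, resno,
#'   insert, resid, rasa_free, rasa_dna, delta, scr (support/core/rim),
#'   restricted to interface residues. The full per-residue table is
#'   attached as attribute \code{"all"}.
#' @export
interface_residues <- function(bound, config = pdna_config()) {
  mols <- unique(bound$residues$mol)
  if (!"protein" %in% mols) stop("bound structure has no protein chain")
  if (!any(c("DNA", "RNA") %in% mols)) {
    stop("bound structure has no nucleic (DNA/RNA) chain")
  }
  complexed <- subset_structure(bound, mol = c("protein", "DNA", "RNA",
                                               "other"))
  free <- subset_structure(bound, mol = "protein")
  acc_dna <- compute_sasa(complexed, probe_radius = config$probe_radius,
                          n_points = config$sasa_points, context = "complex")
  acc_free <- compute_sasa(free, probe_radius = config$probe_radius,
                           n_points = config$sasa_points, context = "free")
  res <- free$residues
  i_free <- match(res$reskey, acc_free$reskey)
  i_dna <- match(res$reskey, acc_dna$reskey)
  all_tab <- data.frame(
    reskey = res$reskey, chain = res$chain, resno = res$resno,
    insert = res$insert, resid = res$resid,
    rasa_free = acc_free$rasa[i_free],
    rasa_dna = acc_dna$rasa[i_dna],
    stringsAsFactors = FALSE
  )
  all_tab$delta <- all_tab$rasa_free - all_tab$rasa_dna
  iface <- !is.na(all_tab$delta) & all_tab$delta > config$delta_rasa_tol
  out <- all_tab[iface, , drop = FALSE]
  out$scr <- classify_scr(out$rasa_free, out$rasa_dna)
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  class(out) <- c("pdna_interface", "data.frame")
  out
}

#' Support-core-rim classification of an interface residue
#'
#' Thresholds at 25 percent relative accessibility: \emph{support} residues
#' are buried both with (rasa_dna < 25) and without (rasa_free < 25) the
#' DNA; \emph{core} residues are exposed without DNA (rasa_free >= 25) and
#' buried with it (rasa_dna < 25); \emph{rim} residues are exposed in both
#' contexts (>= is inclusive for "exposed"). The fourth quadrant
#' (rasa_free < 25 with rasa_dna >= 25) is impossible for an interface
#' residue (delta > 0) and raises a consistency error.
#'
#' @param rasa_free relative accessibility (percent) without the partner.
#' @param rasa_dna relative accessibility (percent) in the complex.
#' @return character vector: "support", "core" or "rim".
#' @export
#' @examples
#' classify_scr(10, 5)   # support
#' classify_scr(40, 10)  # core
#' classify_scr(40, 30)  # rim
classify_scr <- function(rasa_free, rasa_dna) {
  out <- ifelse(rasa_free < 25 & rasa_dna < 25, "support",
                ifelse(rasa_free >= 25 & rasa_dna < 25, "core",
                       ifelse(rasa_free >= 25 & rasa_dna >= 25, "rim",
                              NA_character_)))
  if (anyNA(out)) {
    stop("inconsistent accessibilities: rasa_free < 25 with rasa_dna >= 25 ",
         "is impossible for an interface residue")
  }
  out
}

#' Atomic contacts between protein and nucleic residues
#'
#' All protein-atom/nucleic-atom pairs at distance strictly below
#' \code{cutoff} (default 5 A). Each nucleic atom is labelled
#' \code{backbone} (phosphate and sugar atoms, C1' included by the standard
#' phosphodiester convention) or \code{base} (all others).
#'
#' @param struct a \code{pdna_structure} containing protein and nucleic
#'   atoms.
#' @param cutoff contact distance in Angstrom (strict \code{<}).
#' @return data frame: reskey, elety (protein side), na_reskey, na_elety,
#'   dist, part ("backbone"/"base").
#' @export
atomic_contacts <- function(struct, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  pa <- struct$atoms[struct$atoms$mol == "protein", , drop = FALSE]
  na_ <- struct$atoms[struct$atoms$mol %in% c("DNA", "RNA"), , drop = FALSE]
  empty <- data.frame(reskey = character(0), elety = character(0),
                      na_reskey = character(0), na_elety = character(0),
                      dist = numeric(0), part = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pa) == 0 || nrow(na_) == 0) return(empty)
  px <- as.matrix(pa[, c("x", "y", "z")])
  nx <- as.matrix(na_[, c("x", "y", "z")])
  out <- vector("list", 0)
  block <- 512L
  for (start in seq(1L, nrow(px), by = block)) {
    idx <- start:min(start + block - 1L, nrow(px))
    d2 <- outer(rowSums(px[idx, , drop = FALSE]^2), rowSums(nx^2), "+") -
      2 * px[idx, , drop = FALSE] %*% t(nx)
    d2[d2 < 0] <- 0
    hits <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hits)) {
      out[[length(out) + 1]] <- data.frame(
        reskey = pa$reskey[idx[hits[, 1]]],
        elety = pa$elety[idx[hits[, 1]]],
        na_reskey = na_$reskey[hits[, 2]],
        na_elety = na_$elety[hits[, 2]],
        dist = sqrt(d2[hits]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$part <- ifelse(res$na_elety %in% NA_BACKBONE_ATOMS, "backbone", "base")
  rownames(res) <- NULL
  res
}

#' Contact profile per support-core-rim class
#'
#' Summarises, for each interface class, the residue count, the total
#' number of atomic contacts, contacts per residue, and the backbone/base
#' split of those contacts.
#'
#' @param interface a \code{pdna_interface} from
#'   \code{\link{interface_residues}}.
#' @param contacts a contact table from \code{\link{atomic_contacts}}.
#' @return data frame with one row per class (support, core, rim):
#'   n_residues, n_contacts, contacts_per_residue, frac_backbone,
#'   frac_base, plus the class share of all base contacts
#'   (base_contact_share).
#' @export
scr_contact_profile <- function(interface, contacts) {
  classes <- c("support", "core", "rim")
  scr_of <- stats::setNames(interface$scr, interface$reskey)
  contacts$scr <- scr_of[contacts$reskey]
  total_base <- sum(contacts$part == "base", na.rm = TRUE)
  rows <- lapply(classes, function(cl) {
    keys <- interface$reskey[interface$scr == cl]
    cc <- contacts[!is.na(contacts$scr) & contacts$scr == cl, , drop = FALSE]
    n_res <- length(keys)
    n_con <- nrow(cc)
    n_bb <- sum(cc$part == "backbone")
    n_base <- n_con - n_bb
    data.frame(
      scr = cl, n_residues = n_res, n_contacts = n_con,
      contacts_per_residue = if (n_res > 0) n_con / n_res else 0,
      frac_backbone = if (n_con > 0) n_bb / n_con else 0,
      frac_base = if (n_con > 0) n_base / n_con else 0,
      base_contact_share = if (total_base > 0) n_base / total_base else 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write per-residue interface and per-contact tables as TSV
#'
#' @param interface a \code{pdna_interface}.
#' @param contacts a contact table from \code{\link{atomic_contacts}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_interface_tsv <- function(interface, contacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "interface_residues.tsv")
  f2 <- file.path(dir, "contacts.tsv")
  utils::write.table(
    interface[, c("chain", "resno", "insert", "rasa_free", "rasa_dna",
                  "delta", "scr")],
    f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(contacts, f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f1, f2))
}
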