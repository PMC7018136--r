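# The three scoring schemes and the expected interface size.

SCHEMES <- c("SC1", "SC2", "SC3")
LAYERS <- c("seed", "extension", "outer")

#' Layer score of residues under a scoring scheme
#'
#' Each scheme sums two descriptors in [0, 1], so scores lie in [0, 2]. The
#' seed and extension layers always share the same combination:
#' \describe{
#'   \item{SC1}{seed/extension: cons + prop; outer: cons + (1 - cv_local).
#'     Generic conserved binding sites.}
#'   \item{SC2}{seed/extension: cons + cv_global; outer: cons + prop.
#'     Enveloping (concave) interfaces such as polymerase sites.}
#'   \item{SC3}{all layers: prop + (1 - cv_local). No-conservation-signal
#'     sites: locally protruding residues with favourable chemistry.}
#' }
#'
#' @param scheme one of "SC1", "SC2", "SC3".
#' @param layer one of "seed", "extension", "outer".
#' @param d a \code{pdna_descriptors} data frame (or any data frame with
#'   columns cons, prop, cv_local, cv_global).
#' @return numeric vector of scores in [0, 2]; \code{NA} where a required
#'   descriptor is missing.
#' @export
#' @examples
#' d <- data.frame(cons = 0.8, prop = 0.6, cv_local = 0.2, cv_global = 0.5)
#' layer_score("SC1", "seed", d)  # 1.4
layer_score <- function(scheme, layer, d) {
  scheme <- match.arg(scheme, SCHEMES)
  layer <- match.arg(layer, LAYERS)
  switch(scheme,
    SC1 = if (layer == "outer") d$cons + (1 - d$cv_local) else d$cons + d$prop,
    SC2 = if (layer == "outer") d$cons + d$prop else d$cons + d$cv_global,
    SC3 = d$prop + (1 - d$cv_local)
  )
}

#' Expected interface size given the number of surface residues
#'
#' The expected fraction of surface residues belonging to a DNA interface
#' is f(x) = 2.66/x + 0.03 for x surface residues (decreasing in x, with
#' asymptote 0.03). The expected residue count is the fraction times x,
#' rounded half-up, with a floor of \code{min_count} so that the 1-2
#' residue patch filter cannot void every prediction on tiny proteins.
#'
#' @param n_surface number of protein surface residues (>= 1).
#' @param min_count minimum expected count (default 3).
#' @return list with \code{n_surface}, \code{fraction} and \code{count}.
#' @export
#' @examples
#' expected_interface_size(100)$fraction  # 0.0566
expected_interface_size <- function(n_surface, min_count = 3) {
  if (n_surface < 1) stop("n_surface must be >= 1")
  f <- 2.66 / n_surface + 0.03
  list(n_surface = n_surface, fraction = f,
       count = max(min_count, round_half_up(f * n_surface)))
}
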