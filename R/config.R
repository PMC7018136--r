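#' Default configuration for prediction and interface extraction
#'
#' Returns the full list of tunable parameters with their defaults. Any
#' subset can be overridden through \code{...} or by a plain-text
#' \code{key = value} file read with \code{\link{read_config}}.
#'
#' Geometry and accessibility: \code{probe_radius} (A) is the solvent probe,
#' \code{sasa_points} the number of sphere-sampling points per atom,
#' \code{surface_rasa} the relative-accessibility threshold (percent)
#' defining surface residues, \code{r_local}/\code{r_global} (A) the
#' circular-variance radii. Clustering: candidate pools for the seed,
#' extension and outer layers hold the top \code{seed_pool_frac},
#' \code{ext_pool_frac} and \code{outer_pool_frac} fractions of the expected
#' interface size; \code{score_clus} is the admission floor relative to the
#' current cluster mean score; \code{relax_factor}/\code{relax_floor_factor}
#' govern the single relaxation retry triggered below \code{relax_trigger}
#' of the expected size. Pocket avoidance: residues with local circular
#' variance above \code{cv_local_high} are highly buried; a seed whose
#' highly-buried fraction exceeds \code{pocket_frac_sc1}
#' (\code{pocket_frac_sc2} for scheme SC2) triggers one restart. Filtering:
#' patches are size-tested against the \code{filter_percentile} quantile of
#' \code{filter_n_random} random connected surface patches whenever the
#' prediction exceeds \code{filter_trigger} of the expected size. Scheme
#' selection: \code{cons_low}, \code{cvg_high} and \code{prop_high} are the
#' decision-tree thresholds on seed means.
#'
#' @param ... named overrides of any default.
#' @return a named list of parameters.
#' @export
#' @examples
#' cfg <- pdna_config(surface_rasa = 10)
#' cfg$surface_rasa
pdna_config <- function(...) {
  cfg <- list(
    probe_radius = 1.4,
    sasa_points = 240,
    surface_rasa = 5,
    r_local = 12,
    r_global = 100,
    contact_cutoff = 5,
    adjacency_cutoff = 5,
    delta_rasa_tol = 1e-3,
    seed_pool_frac = 1 / 3,
    ext_pool_frac = 2 / 3,
    outer_pool_frac = 1,
    score_clus = 0.7,
    relax_factor = 1.5,
    relax_floor_factor = 0.9,
    relax_trigger = 0.70,
    cv_local_high = 0.9,
    pocket_frac_sc1 = 0.20,
    pocket_frac_sc2 = 0.30,
    filter_trigger = 0.70,
    filter_n_random = 1000,
    filter_percentile = 0.95,
    min_expected = 3,
    cons_low = 0.3,
    cvg_high = 0.6,
    prop_high = 0.9
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config parameter(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Read configuration overrides from a key = value text file
#'
#' Lines are \code{key = value}; blank lines and lines starting with
#' \code{#} are ignored. Values are parsed as numerics.
#'
#' @param path file path.
#' @param base configuration to override, default \code{pdna_config()}.
#' @return a configuration list.
#' @export
read_config <- function(path, base = pdna_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("malformed config line ", i, ": '", lines[[i]], "'")
    }
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) stop("non-numeric value on config line ", i)
    if (!key %in% names(base)) stop("unknown config key '", key, "'")
    base[[key]] <- val
  }
  base
}
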