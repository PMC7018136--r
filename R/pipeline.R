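# Automated scheme selection, single/two-round prediction, iterative mode.

#' Choose a scoring scheme from the properties of SC1 seeds
#'
#' Decision tree over the means of the descriptors across the SC1 seed
#' residues: a very low conservation signal (mean cons < 0.3, or no seeds
#' at all) selects SC3; otherwise seeds sitting in a very concave region
#' (mean cv_global > 0.6) without strongly favourable chemistry (mean prop
#' < 0.9) select SC2; otherwise SC1.
#'
#' @param seeds SC1 seed patches from \code{\link{detect_seeds}}.
#' @param d surface-residue descriptor table.
#' @param config configuration list.
#' @return list with \code{scheme} and a \code{trace} recording the three
#'   decision statistics and the reason.
#' @export
select_scheme <- function(seeds, d, config = pdna_config()) {
  if (length(seeds) == 0) {
    return(list(scheme = "SC3",
                trace = list(mean_cons = NA_real_, mean_cv_global = NA_real_,
                             mean_prop = NA_real_,
                             reason = "no seeds: treated as no conservation signal")))
  }
  keys <- unique(unlist(lapply(seeds, `[[`, "residues")))
  rows <- d[match(keys, d$reskey), , drop = FALSE]
  m_cons <- mean(rows$cons, na.rm = TRUE)
  m_cvg <- mean(rows$cv_global, na.rm = TRUE)
  m_prop <- mean(rows$prop, na.rm = TRUE)
  trace <- list(mean_cons = m_cons, mean_cv_global = m_cvg,
                mean_prop = m_prop)
  if (m_cons < config$cons_low) {
    trace$reason <- "low conservation signal"
    list(scheme = "SC3", trace = trace)
  } else if (m_cvg > config$cvg_high && m_prop < config$prop_high) {
    trace$reason <- "concave seeds without strong chemistry"
    list(scheme = "SC2", trace = trace)
  } else {
    trace$reason <- "default: conserved seeds with favourable chemistry"
    list(scheme = "SC1", trace = trace)
  }
}

#' Predict a DNA-binding site on a protein surface
#'
#' Full single-round procedure: SC1 seeds are detected first and feed the
#' automated scheme choice (unless a manual scheme is given); the chosen
#' scheme then runs the complete clustering with pocket avoidance, seed
#' extension, outer-layer completion, one relaxation retry if the
#' prediction is undersized, and false-positive filtering.
#'
#' @param struct a \code{pdna_structure} (its protein component is used).
#' @param descriptors a \code{pdna_descriptors} table from
#'   \code{\link{compute_descriptors}}.
#' @param config configuration list.
#' @param scheme "auto" (default) or a manual override "SC1"/"SC2"/"SC3".
#' @param seed RNG seed for the random-patch filter null.
#' @return an object of class \code{pdna_prediction}: patches (each with
#'   residues, per-residue layer and score, scheme and round), chosen
#'   scheme, decision trace, expected size, surface residue keys, and
#'   flags for relaxation and pocket restart.
#' @export
run_prediction <- function(struct, descriptors, config = pdna_config(),
                           scheme = "auto", seed = 1) {
  ds <- descriptors[descriptors$surface, , drop = FALSE]
  if (nrow(ds) == 0) stop("no surface residues: nothing to predict")
  prot <- subset_structure(struct, mol = "protein")
  graph <- adjacency_graph(prot, ds$reskey, config$adjacency_cutoff)
  expected <- expected_interface_size(nrow(ds), config$min_expected)
  seeds_sc1 <- detect_seeds(ds, graph, expected, config, "SC1")
  if (identical(scheme, "auto")) {
    sel <- select_scheme(seeds_sc1, ds, config)
    chosen <- sel$scheme
    trace <- sel$trace
    trace$mode <- "auto"
  } else {
    chosen <- match.arg(toupper(scheme), SCHEMES)
    trace <- list(mode = "manual", reason = "manual scheme override")
  }
  pass <- cluster_pass(ds, graph, expected, config, chosen,
                       exclude = character(0), relax = FALSE)
  pass <- relax_and_retry(pass, ds, graph, expected, config, chosen)
  patches <- filter_patches(pass$patches, graph, expected, config, seed)
  patches <- lapply(patches, function(p) {
    p$scheme <- chosen
    p$round <- 1L
    p
  })
  out <- list(patches = patches, scheme = chosen, trace = trace,
              expected = expected, surface = ds$reskey,
              descriptors = descriptors, graph = graph,
              relaxed = isTRUE(pass$relaxed),
              pocket_restarted = isTRUE(pass$pocket_restarted),
              pocket_excluded = pass$pocket_excluded, seed = seed)
  class(out) <- "pdna_prediction"
  out
}

complementary_scheme <- function(scheme) {
  if (scheme %in% c("SC1", "SC2")) "SC3" else "SC1"
}

#' Two-round (complete) prediction with a complementary scheme
#'
#' Runs \code{\link{run_prediction}}, then a second clustering round with
#' the complementary scheme (SC3 after SC1 or SC2; SC1 after SC3) on the
#' same surface. Round-2 residues already predicted in round 1 are reported
#' once, with the overlap recorded on the round-2 patch (\code{dual}); the
#' output is the union with per-patch scheme and round labels.
#'
#' @inheritParams run_prediction
#' @return a \code{pdna_prediction} whose patches carry round 1 and round 2
#'   provenance.
#' @export
run_complete <- function(struct, descriptors, config = pdna_config(),
                         scheme = "auto", seed = 1) {
  r1 <- run_prediction(struct, descriptors, config, scheme, seed)
  scheme2 <- complementary_scheme(r1$scheme)
  ds <- descriptors[descriptors$surface, , drop = FALSE]
  pass <- cluster_pass(ds, r1$graph, r1$expected, config, scheme2,
                       exclude = character(0), relax = FALSE)
  pass <- relax_and_retry(pass, ds, r1$graph, r1$expected, config, scheme2)
  patches2 <- filter_patches(pass$patches, r1$graph, r1$expected, config,
                             seed)
  r1_keys <- unlist(lapply(r1$patches, `[[`, "residues"), use.names = FALSE)
  patches2 <- lapply(patches2, function(p) {
    overlap <- intersect(p$residues, r1_keys)
    keep <- setdiff(p$residues, r1_keys)
    if (length(keep) == 0) return(NULL)
    p$residues <- keep
    p$layer <- p$layer[keep]
    p$score <- p$score[keep]
    p$dual <- overlap
    p$scheme <- scheme2
    p$round <- 2L
    p
  })
  patches2 <- Filter(Negate(is.null), patches2)
  r1$patches <- c(r1$patches, patches2)
  r1$scheme2 <- scheme2
  r1
}

#' Iterative (consensus) prediction
#'
#' Repeats the prediction \code{n_runs} times; stochasticity enters only
#' through the conservation subsampling (when an alignment is supplied) and
#' the random-patch filter, each run seeded as \code{seed + run - 1}. The
#' per-residue detection probability is detections divided by
#' \code{n_runs}; the consensus prediction keeps residues detected in at
#' least \code{consensus_k} runs, rebuilt into patches as connected
#' components with layer labels taken by majority vote across runs.
#'
#' @param struct a \code{pdna_structure}.
#' @param msa optional alignment (matrix or aligned-FASTA path) for
#'   per-run tree-trace conservation; requires \code{query_id} and
#'   \code{chain}.
#' @param query_id query sequence id within the alignment.
#' @param chain protein chain whose residues (in order) the query
#'   positions map onto; defaults to the first protein chain.
#' @param conservation fixed named conservation vector (alternative to
#'   \code{msa}; runs are then identical).
#' @param propensities scaled propensity vector.
#' @param config configuration list.
#' @param scheme "auto" or a manual scheme.
#' @param n_trees,sample_size tree-trace subsampling controls per run
#'   (see \code{\link{tree_trace_conservation}}).
#' @param n_runs number of runs (default 10).
#' @param consensus_k minimal detections for the consensus set (default 2).
#' @param seed base RNG seed.
#' @return a \code{pdna_prediction} with \code{probability} (named vector),
#'   \code{detections}, \code{n_runs}, \code{consensus_k} and consensus
#'   patches.
#' @export
run_iterative <- function(struct, msa = NULL, query_id = NULL, chain = NULL,
                          conservation = NULL,
                          propensities = read_propensities(),
                          config = pdna_config(), scheme = "auto",
                          n_trees = 10, sample_size = NULL,
                          n_runs = 10, consensus_k = 2, seed = 1) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (consensus_k < 1 || consensus_k > n_runs) {
    stop("consensus_k must lie in [1, n_runs]")
  }
  if (is.null(msa) && is.null(conservation)) {
    stop("either an alignment or fixed conservation scores are required")
  }
  prot <- subset_structure(struct, mol = "protein")
  base_cons <- conservation %||%
    stats::setNames(rep(0, nrow(prot$residues)), prot$residues$reskey)
  d0 <- compute_descriptors(struct, base_cons, propensities, config)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1L
    d <- d0
    if (!is.null(msa)) {
      scores <- tree_trace_conservation(msa, NULL, query_id,
                                        n_trees = n_trees,
                                        sample_size = sample_size,
                                        seed = run_seed)
      cons_r <- map_conservation_to_chain(prot, scores, chain)
      d$cons <- unname(cons_r[d$reskey])
      d$cons[is.na(d$cons)] <- 0
    }
    runs[[r]] <- run_prediction(struct, d, config, scheme, seed = run_seed)
  }
  surface <- runs[[1]]$surface
  det <- stats::setNames(rep(0L, length(surface)), surface)
  layer_votes <- list()
  for (r in seq_len(n_runs)) {
    for (p in runs[[r]]$patches) {
      det[p$residues] <- det[p$residues] + 1L
      for (key in p$residues) {
        layer_votes[[key]] <- c(layer_votes[[key]], p$layer[[key]])
      }
    }
  }
  prob <- det / n_runs
  consensus <- names(det)[det >= consensus_k]
  graph <- runs[[1]]$graph
  patches <- list()
  if (length(consensus)) {
    comp <- igraph::components(igraph::induced_subgraph(graph, consensus))
    groups <- split(names(comp$membership), comp$membership)
    patches <- lapply(unname(groups), function(g) {
      layer <- vapply(g, function(key) {
        votes <- table(layer_votes[[key]])
        # majority vote; ties resolved seed > extension > outer
        winners <- names(votes)[votes == max(votes)]
        LAYERS[min(match(winners, LAYERS))]
      }, character(1))
      list(residues = g, layer = layer,
           score = prob[g], scheme = "consensus", round = 1L)
    })
  }
  out <- runs[[n_runs]]
  out$patches <- patches
  out$probability <- prob
  out$detections <- det
  out$n_runs <- n_runs
  out$consensus_k <- consensus_k
  out$scheme <- if (length(unique(vapply(runs, `[[`, "", "scheme"))) == 1)
    runs[[1]]$scheme else "mixed"
  out
}

map_conservation_to_chain <- function(prot, scores, chain = NULL) {
  chain <- chain %||% prot$residues$chain[1]
  keys <- prot$residues$reskey[prot$residues$chain == chain]
  if (length(keys) != length(scores)) {
    stop("conservation scores (", length(scores), ") do not match chain ",
         chain, " residue count (", length(keys), ")")
  }
  stats::setNames(scores, keys)
}

#' Residues predicted by a prediction object
#'
#' @param pred a \code{pdna_prediction}.
#' @return character vector of predicted residue keys.
#' @export
predicted_residues <- function(pred) {
  unique(unlist(lapply(pred$patches, `[[`, "residues"), use.names = FALSE))
}

#' Per-residue prediction table
#'
#' @param pred a \code{pdna_prediction}.
#' @return data frame over surface residues: chain, resno, insert,
#'   descriptors, score, cluster id, layer, scheme, and detection
#'   probability when the prediction is a consensus.
#' @export
prediction_table <- function(pred) {
  d <- pred$descriptors
  out <- d[match(pred$surface, d$reskey),
           c("reskey", "chain", "resno", "insert", "resid", "cons", "prop",
             "cv_local", "cv_global", "rasa"), drop = FALSE]
  out$score <- NA_real_
  out$cluster <- NA_integer_
  out$layer <- NA_character_
  out$scheme <- NA_character_
  for (i in seq_along(pred$patches)) {
    p <- pred$patches[[i]]
    idx <- match(p$residues, out$reskey)
    out$score[idx] <- unname(p$score[p$residues])
    out$cluster[idx] <- i
    out$layer[idx] <- unname(p$layer[p$residues])
    out$scheme[idx] <- p$scheme %||% pred$scheme
  }
  if (!is.null(pred$probability)) {
    out$probability <- unname(pred$probability[out$reskey])
  }
  rownames(out) <- NULL
  out
}

#' @export
print.pdna_prediction <- function(x, ...) {
  sizes <- patch_sizes(x$patches)
  cat("pdna_prediction: scheme ", x$scheme,
      if (!is.null(x$scheme2)) paste0(" (+", x$scheme2, " round 2)"),
      ", ", length(x$patches), " patch(es) of size ",
      paste(sizes, collapse = ", "),
      "; expected interface size ", x$expected$count,
      " of ", x$expected$n_surface, " surface residues\n", sep = "")
  if (!is.null(x$trace$reason)) {
    cat("decision: ", x$trace$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Write prediction outputs (TSV table, JSON summary, optional PDB)
#'
#' @param pred a \code{pdna_prediction}.
#' @param dir output directory.
#' @param struct optional \code{pdna_structure}; when given (and the
#'   prediction carries detection probabilities), a PDB copy is written
#'   with probability x 100 in the B-factor field.
#' @return invisibly, the paths written.
#' @export
write_prediction <- function(pred, dir, struct = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- prediction_table(pred)
  f_tsv <- file.path(dir, "prediction.tsv")
  utils::write.table(tab, f_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(
    scheme = pred$scheme,
    scheme_round2 = pred$scheme2 %||% NULL,
    decision_trace = pred$trace,
    expected_size = pred$expected$count,
    n_surface = pred$expected$n_surface,
    patch_sizes = patch_sizes(pred$patches),
    relaxed = pred$relaxed,
    pocket_restarted = pred$pocket_restarted
  )
  f_json <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, f_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(f_tsv, f_json)
  if (!is.null(struct) && !is.null(pred$probability)) {
    prot <- subset_structure(struct, mol = "protein")
    b <- pred$probability[prot$atoms$reskey]
    b[is.na(b)] <- 0
    f_pdb <- file.path(dir, "prediction.pdb")
    bio3d::write.pdb(file = f_pdb,
                     xyz = as.numeric(t(atom_xyz(prot))),
                     resno = prot$atoms$resno,
                     resid = prot$atoms$resid,
                     chain = prot$atoms$chain,
                     insert = prot$atoms$insert,
                     elety = prot$atoms$elety,
                     o = prot$atoms$o, b = round(100 * b, 2))
    paths <- c(paths, f_pdb)
  }
  invisible(paths)
}
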