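# Seed -> extension -> outer-layer clustering with dynamic thresholds,
# pocket avoidance, patch merging and false-positive filtering.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Residue adjacency graph
#'
#' Undirected graph over the given residues with an edge wherever the
#' minimal heavy-atom distance between two residues is at most
#' \code{cutoff} Angstrom (default 5, matching the atomic contact cutoff).
#'
#' @param struct a \code{pdna_structure}.
#' @param reskeys residue keys to include as vertices.
#' @param cutoff adjacency distance in Angstrom.
#' @return an \code{igraph} graph with vertices named by residue key.
#' @export
adjacency_graph <- function(struct, reskeys, cutoff = 5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  at <- struct$atoms[struct$atoms$reskey %in% reskeys, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  keys <- at$reskey
  n <- nrow(xyz)
  block <- 512L
  elist <- list()
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(xyz[idx, , drop = FALSE]^2), rowSums(xyz^2), "+") -
      2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hits)) {
      a <- keys[idx[hits[, 1]]]
      b <- keys[hits[, 2]]
      keep <- a < b
      if (any(keep)) {
        elist[[length(elist) + 1]] <- unique(cbind(a[keep], b[keep]))
      }
    }
  }
  if (length(elist)) {
    em <- unique(do.call(rbind, elist))
  } else {
    em <- matrix(character(0), ncol = 2)
  }
  igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = reskeys, stringsAsFactors = FALSE)
  )
}

# rank candidate residues: score desc, conservation desc, then chain and
# residue number for full determinism under ties
ranked_keys <- function(d, scores) {
  ord <- order(-scores, -d$cons, d$chain, d$resno, d$insert)
  d$reskey[ord]
}

# top-of-ranking candidate pool for one layer
layer_pool <- function(d, scheme, layer, frac, expected, exclude,
                       relax_factor = 1) {
  scores <- layer_score(scheme, layer, d)
  if (anyNA(scores)) {
    warning(sum(is.na(scores)),
            " residue(s) with missing descriptors excluded from ranking")
  }
  keep <- !is.na(scores) & !(d$reskey %in% exclude)
  pool_n <- ceiling(frac * expected$count * relax_factor)
  ranked <- ranked_keys(d[keep, , drop = FALSE], scores[keep])
  utils::head(ranked, pool_n)
}

new_patch <- function(keys, scores, layer = "seed") {
  list(residues = keys,
       layer = stats::setNames(rep(layer, length(keys)), keys),
       score = scores[keys])
}

patch_sizes <- function(patches) vapply(patches, function(p)
  length(p$residues), integer(1))

#' Detect seed patches
#'
#' The candidate pool is the top-ranked third (by seed-layer score) of the
#' expected interface size; seeds are the connected components of the pool
#' in the adjacency graph. Components of 1-2 residues are discarded at this
#' stage only when at least one component of size >= 3 exists (the final
#' 1-2 residue filter still applies at the end of the procedure).
#'
#' @param d surface-residue descriptor table.
#' @param graph adjacency graph from \code{\link{adjacency_graph}}.
#' @param expected expected size from \code{\link{expected_interface_size}}.
#' @param config configuration list.
#' @param scheme scoring scheme id.
#' @param exclude residue keys barred from the candidate pool.
#' @param relax logical; enlarge the pool by the relaxation factor.
#' @return list of patches (possibly empty), each with elements
#'   \code{residues}, \code{layer} and \code{score}.
#' @export
detect_seeds <- function(d, graph, expected, config = pdna_config(),
                         scheme = "SC1", exclude = character(),
                         relax = FALSE) {
  pool <- layer_pool(d, scheme, "seed", config$seed_pool_frac, expected,
                     exclude, if (relax) config$relax_factor else 1)
  if (length(pool) == 0) return(list())
  scores <- stats::setNames(layer_score(scheme, "seed", d), d$reskey)
  sub <- igraph::induced_subgraph(graph, pool)
  comp <- igraph::components(sub)
  groups <- split(names(comp$membership), comp$membership)
  sizes <- lengths(groups)
  if (any(sizes >= 3)) groups <- groups[sizes >= 3]
  lapply(unname(groups), function(g) new_patch(g, scores, "seed"))
}

#' Pocket-avoidance check on seed patches
#'
#' Small-ligand binding pockets are deeply buried and often highly
#' conserved; a seed sitting in one is detected by its fraction of highly
#' buried residues (local circular variance above \code{cv_local_high} =
#' 0.9). If that fraction exceeds 20 percent (SC1) or 30 percent (SC2) for
#' any seed, seed detection must be restarted with all highly buried
#' surface residues excluded from the candidate pools. The check does not
#' apply to SC3, which already selects protruding residues.
#'
#' @param patches seed patches from \code{\link{detect_seeds}}.
#' @param d surface-residue descriptor table.
#' @param config configuration list.
#' @param scheme scoring scheme id.
#' @return list with \code{restart} (logical) and \code{excluded} (keys of
#'   highly buried surface residues; empty when no restart).
#' @export
restart_on_pockets <- function(patches, d, config = pdna_config(),
                               scheme = "SC1") {
  if (scheme == "SC3" || length(patches) == 0) {
    return(list(restart = FALSE, excluded = character(0)))
  }
  frac_max <- if (scheme == "SC1") config$pocket_frac_sc1 else
    config$pocket_frac_sc2
  cvl <- stats::setNames(d$cv_local, d$reskey)
  buried_frac <- vapply(patches, function(p) {
    mean(cvl[p$residues] > config$cv_local_high, na.rm = TRUE)
  }, numeric(1))
  if (any(buried_frac > frac_max)) {
    list(restart = TRUE,
         excluded = d$reskey[!is.na(d$cv_local) &
                               d$cv_local > config$cv_local_high])
  } else {
    list(restart = FALSE, excluded = character(0))
  }
}

# shared greedy admission loop for the extension and outer layers
grow_layer <- function(patches, d, graph, expected, config, scheme, layer,
                       frac, exclude, relax, cap = Inf) {
  if (length(patches) == 0) return(patches)
  floor_frac <- config$score_clus *
    (if (relax) config$relax_floor_factor else 1)
  pool <- layer_pool(d, scheme, layer, frac, expected, exclude,
                     if (relax) config$relax_factor else 1)
  scores <- stats::setNames(layer_score(scheme, layer, d), d$reskey)
  rank_of <- stats::setNames(seq_along(pool), pool)
  adj <- lapply(igraph::as_adj_list(graph), igraph::as_ids)
  names(adj) <- igraph::V(graph)$name
  neighbours <- function(key) adj[[key]]
  assigned <- unlist(lapply(patches, `[[`, "residues"), use.names = FALSE)
  repeat {
    if (sum(patch_sizes(patches)) >= cap) break
    cand <- setdiff(pool, assigned)
    if (length(cand) == 0) break
    # which patches is each candidate adjacent to
    admitted <- FALSE
    for (key in cand[order(rank_of[cand])]) {
      nb <- neighbours(key)
      touching <- which(vapply(patches, function(p)
        any(p$residues %in% nb), logical(1)))
      if (length(touching) == 0) next
      # cluster mean under the current layer's score, so the floor
      # compares like with like across layers
      means <- vapply(touching, function(i)
        mean(scores[patches[[i]]$residues], na.rm = TRUE), numeric(1))
      target <- touching[which.max(means)]
      if (scores[key] < floor_frac * max(means)) next
      patches[[target]]$residues <- c(patches[[target]]$residues, key)
      patches[[target]]$layer[key] <- layer
      patches[[target]]$score[key] <- scores[key]
      assigned <- c(assigned, key)
      # merge any other patch now in contact through the admitted residue
      others <- setdiff(touching, target)
      if (length(others)) {
        for (i in others) {
          patches[[target]]$residues <-
            c(patches[[target]]$residues, patches[[i]]$residues)
          patches[[target]]$layer <-
            c(patches[[target]]$layer, patches[[i]]$layer)
          patches[[target]]$score <-
            c(patches[[target]]$score, patches[[i]]$score)
        }
        patches <- patches[-others]
      }
      admitted <- TRUE
      break
    }
    if (!admitted) break
  }
  patches
}

#' Extend seed patches with highly scored neighbours
#'
#' Iteratively admits the highest-ranked unassigned neighbour of any patch
#' (extension-layer score, candidate pool = top two thirds of the expected
#' size) provided its score stays above \code{score_clus} times the current
#' patch mean. Patches that come into contact through an admitted residue
#' are merged and keep both seeds.
#'
#' @inheritParams detect_seeds
#' @param patches seed patches.
#' @return the grown patch list.
#' @export
extend_clusters <- function(patches, d, graph, expected,
                            config = pdna_config(), scheme = "SC1",
                            exclude = character(), relax = FALSE) {
  grow_layer(patches, d, graph, expected, config, scheme, "extension",
             config$ext_pool_frac, exclude, relax)
}

#' Complete patches with an outer layer
#'
#' Same admission loop as \code{\link{extend_clusters}} but scored with the
#' outer-layer formula and a candidate pool of the full expected size;
#' growth stops once the total predicted count reaches the expected count
#' or no candidate passes. The patch set only ever grows.
#'
#' @inheritParams extend_clusters
#' @return the completed patch list.
#' @export
add_outer_layer <- function(patches, d, graph, expected,
                            config = pdna_config(), scheme = "SC1",
                            exclude = character(), relax = FALSE) {
  grow_layer(patches, d, graph, expected, config, scheme, "outer",
             config$outer_pool_frac, exclude, relax, cap = expected$count)
}

# one full seed -> extension -> outer pass (with pocket restart)
cluster_pass <- function(d, graph, expected, config, scheme, exclude,
                         relax) {
  seeds <- detect_seeds(d, graph, expected, config, scheme, exclude, relax)
  pocket <- restart_on_pockets(seeds, d, config, scheme)
  if (pocket$restart) {
    exclude <- union(exclude, pocket$excluded)
    seeds <- detect_seeds(d, graph, expected, config, scheme, exclude, relax)
  }
  patches <- extend_clusters(seeds, d, graph, expected, config, scheme,
                             exclude, relax)
  patches <- add_outer_layer(patches, d, graph, expected, config, scheme,
                             exclude, relax)
  list(patches = patches, pocket_excluded = pocket$excluded,
       pocket_restarted = pocket$restart)
}

#' Re-run the clustering once with relaxed thresholds if undersized
#'
#' If a completed three-step pass predicts fewer residues than 70 percent
#' of the expected interface size, all three steps are re-run once with the
#' candidate pools enlarged by \code{relax_factor} (default 1.5) and the
#' cluster admission floors lowered by 10 percent. The relaxed thresholds
#' remain stricter than unbounded admission.
#'
#' @param pass result of an internal strict clustering pass.
#' @param d,graph,expected,config,scheme,exclude as in
#'   \code{\link{detect_seeds}}.
#' @return a pass result with an added \code{relaxed} flag.
#' @export
relax_and_retry <- function(pass, d, graph, expected,
                            config = pdna_config(), scheme = "SC1",
                            exclude = character()) {
  total <- sum(patch_sizes(pass$patches))
  if (total < config$relax_trigger * expected$count) {
    exclude2 <- union(exclude, pass$pocket_excluded)
    pass2 <- cluster_pass(d, graph, expected, config, scheme, exclude2,
                          relax = TRUE)
    pass2$relaxed <- TRUE
    pass2
  } else {
    pass$relaxed <- FALSE
    pass
  }
}

# largest connected component sizes of random surface subsets: the null
# model against which small patches are size-tested
random_patch_sizes <- function(graph, pool_size, n, seed) {
  keys <- igraph::V(graph)$name
  pool_size <- min(pool_size, length(keys))
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      take <- sample(keys, pool_size)
      comp <- igraph::components(igraph::induced_subgraph(graph, take))
      max(comp$csize)
    }, numeric(1))
  })
}

#' Filter out putative false-positive patches
#'
#' Patches of 1 or 2 residues are always removed. If the remaining
#' prediction still exceeds 70 percent of the expected interface size,
#' patches are tested from the smallest upward against the 95th percentile
#' of the sizes of random connected surface patches (largest component of a
#' random seed-pool-sized residue subset; 1000 seeded draws): a patch below
#' that percentile is removed, and filtering stops once the total drops to
#' 70 percent of the expected size or every remaining patch passes.
#'
#' @param patches patch list after clustering.
#' @param graph adjacency graph over surface residues.
#' @param expected expected size.
#' @param config configuration list.
#' @param seed RNG seed for the random-patch null.
#' @return filtered patch list.
#' @export
filter_patches <- function(patches, graph, expected,
                           config = pdna_config(), seed = 1) {
  patches <- patches[patch_sizes(patches) >= 3]
  if (length(patches) == 0) return(patches)
  total <- sum(patch_sizes(patches))
  if (total <= config$filter_trigger * expected$count) return(patches)
  null_sizes <- random_patch_sizes(
    graph, ceiling(config$seed_pool_frac * expected$count),
    config$filter_n_random, seed)
  thresh <- stats::quantile(null_sizes, config$filter_percentile,
                            names = FALSE)
  ord <- order(patch_sizes(patches))
  drop <- integer(0)
  for (i in ord) {
    if (total <= config$filter_trigger * expected$count) break
    sz <- length(patches[[i]]$residues)
    if (sz < thresh) {
      drop <- c(drop, i)
      total <- total - sz
    } else {
      break  # ascending order: every remaining patch passes too
    }
  }
  if (length(drop)) patches <- patches[-drop]
  patches
}
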