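# A delimitation is represented by its set of "species roots": nodes such
# that every tip has exactly one ancestor-or-self in the set. The edge
# entering a node is a within-species ("W") edge when the node lies strictly
# below a species root, and a speciation ("S") edge otherwise. Branch
# lengths within each class are modelled as exponential with a class rate,
# the rates being the two Poisson processes of the model.

as_phylo_tree <- function(tree) {
  if (inherits(tree, "support_tree")) tree <- tree$phy
  if (!inherits(tree, "phylo")) stop("tree must be a phylo or support_tree")
  tree
}

edge_children_index <- function(phy) {
  split(seq_len(nrow(phy$edge)), factor(phy$edge[, 1L],
        levels = seq_len(length(phy$tip.label) + phy$Nnode)))
}

# edge indices in parent-before-child order, regardless of storage order
topo_edge_order <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ch <- split(seq_len(nrow(phy$edge)), factor(phy$edge[, 1L], levels = 1:nnode))
  ord <- integer(0)
  queue <- ntip + 1L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    es <- ch[[v]]
    ord <- c(ord, es)
    queue <- c(queue, phy$edge[es, 2L])
  }
  ord
}

# edge classes ("S"/"W" per row of phy$edge) induced by a species-root set
roots_to_classes <- function(phy, roots, ord = topo_edge_order(phy)) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  in_roots <- rep(FALSE, nnode); in_roots[roots] <- TRUE
  inside <- rep(FALSE, nnode)   # strictly below a species root
  classes <- character(nrow(phy$edge))
  for (e in ord) {
    p <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
    inside[v] <- inside[p] || in_roots[p]
    classes[e] <- if (inside[v]) "W" else "S"
  }
  classes
}

validate_roots <- function(phy, roots) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  if (any(roots < 1L | roots > nnode)) stop("species root out of range")
  in_roots <- rep(FALSE, nnode); in_roots[roots] <- TRUE
  cover <- rep(0L, ntip)
  for (tip in seq_len(ntip)) {
    v <- tip
    repeat {
      if (in_roots[v]) cover[tip] <- cover[tip] + 1L
      e <- which(phy$edge[, 2L] == v)
      if (length(e) == 0L) break
      v <- phy$edge[e, 1L]
    }
  }
  if (any(cover != 1L))
    stop("invalid delimitation: every tip needs exactly one species root ",
         "on its root path")
  invisible(TRUE)
}

class_loglik_term <- function(n, s) if (n == 0L) 0 else n * log(n / s) - n

#' Poisson-tree-processes log-likelihood of a branch classification
#'
#' Branch lengths in each class (speciation `"S"`, within-species `"W"`) are
#' treated as independent exponential draws; the class rates are the
#' maximum-likelihood plug-ins (count / total length), giving
#' `sum_class [ n log(n / sum_b) - n ]`. Zero-length branches are floored at
#' `1e-8` before evaluation.
#'
#' @param tree Rooted `phylo` or [support_tree()] with branch lengths.
#' @param assignment Character vector of `"S"`/`"W"` over the rows of the
#'   tree's edge matrix; must describe a valid delimitation (each species a
#'   connected tip-containing subtree).
#' @return Log-likelihood (scalar); rates are given in the `rates`
#'   attribute.
#' @export
ptp_loglik <- function(tree, assignment) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (length(assignment) != nrow(phy$edge) ||
      any(!assignment %in% c("S", "W")))
    stop("assignment must be 'S'/'W' per edge")
  # validity: a node entered by a W edge must pass W on to all children,
  # and the children of any internal node must be class-homogeneous
  ntip <- length(phy$tip.label)
  ch <- edge_children_index(phy)
  for (e in seq_len(nrow(phy$edge))) {
    v <- phy$edge[e, 2L]
    if (v <= ntip) next
    kids <- ch[[v]]
    if (length(unique(assignment[kids])) > 1L)
      stop("invalid assignment: mixed child classes under one node")
    if (assignment[e] == "W" && any(assignment[kids] == "S"))
      stop("invalid assignment: speciation branch inside a species subtree")
  }
  root <- ntip + 1L
  rkids <- ch[[root]]
  if (length(unique(assignment[rkids])) > 1L)
    stop("invalid assignment: mixed child classes at the root")
  b <- pmax(phy$edge.length, 1e-8)
  nS <- sum(assignment == "S"); sS <- sum(b[assignment == "S"])
  nW <- sum(assignment == "W"); sW <- sum(b[assignment == "W"])
  ll <- class_loglik_term(nS, sS) + class_loglik_term(nW, sW)
  attr(ll, "rates") <- c(lambda_between = if (nS) nS / sS else NA_real_,
                         lambda_within  = if (nW) nW / sW else NA_real_)
  ll
}

roots_loglik <- function(phy, roots, b = pmax(phy$edge.length, 1e-8),
                         ord = topo_edge_order(phy)) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  in_roots <- rep(FALSE, nnode); in_roots[roots] <- TRUE
  inside <- rep(FALSE, nnode)
  parent <- phy$edge[, 1L]; child <- phy$edge[, 2L]
  nW <- 0L; sW <- 0; nS <- 0L; sS <- 0
  for (e in ord) {
    ins <- inside[parent[e]] || in_roots[parent[e]]
    inside[child[e]] <- ins
    if (ins) { nW <- nW + 1L; sW <- sW + b[e] }
    else     { nS <- nS + 1L; sS <- sS + b[e] }
  }
  class_loglik_term(nS, sS) + class_loglik_term(nW, sW)
}

roots_to_partition <- function(phy, roots) {
  memb <- character(length(phy$tip.label))
  for (i in seq_along(roots)) {
    tips <- tips_under(phy, roots[i])
    memb[tips] <- sprintf("P%02d", i)
  }
  bc_partition(setNames(memb, phy$tip.label))
}

make_ptp_partition <- function(phy, roots) {
  roots <- sort(roots)
  validate_roots(phy, roots)
  cl <- roots_to_classes(phy, roots)
  ll <- ptp_loglik(phy, cl)
  structure(list(roots = roots, classes = cl,
                 partition = roots_to_partition(phy, roots),
                 loglik = as.numeric(ll), rates = attr(ll, "rates")),
            class = "ptp_partition")
}

#' @export
print.ptp_partition <- function(x, ...) {
  cat(sprintf("ptp_partition: %d entities, logL %.4f\n",
              n_entities(x$partition), x$loglik))
  invisible(x)
}

# all species-root sets of the subtree rooted at v
enumerate_rootsets <- function(phy, v, ch = edge_children_index(phy)) {
  ntip <- length(phy$tip.label)
  if (v <= ntip) return(list(v))
  kid_nodes <- phy$edge[ch[[v]], 2L]
  kid_sets <- lapply(kid_nodes, enumerate_rootsets, phy = phy, ch = ch)
  combos <- Reduce(function(acc, ks) {
    out <- list()
    for (a in acc) for (k in ks) out <- c(out, list(c(a, k)))
    out
  }, kid_sets, accumulate = FALSE)
  c(list(v), combos)
}

# split/merge neighbourhood of a root set
ptp_moves <- function(phy, roots) {
  ntip <- length(phy$tip.label)
  in_roots <- rep(FALSE, ntip + phy$Nnode); in_roots[roots] <- TRUE
  splits <- roots[roots > ntip]
  parents <- unique(phy$edge[phy$edge[, 2L] %in% roots, 1L])
  merges <- parents[vapply(parents, function(p) {
    kids <- phy$edge[phy$edge[, 1L] == p, 2L]
    all(in_roots[kids])
  }, logical(1))]
  list(splits = splits, merges = merges,
       n = length(splits) + length(merges))
}

apply_move <- function(phy, roots, type, node) {
  if (type == "split") {
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    c(setdiff(roots, node), kids)
  } else {
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    c(setdiff(roots, kids), node)
  }
}

better <- function(ll_a, k_a, ll_b, k_b, tol = 1e-9) {
  ll_a > ll_b + tol || (abs(ll_a - ll_b) <= tol && k_a < k_b)
}

random_rootset <- function(phy, p_stop = 0.4) {
  ntip <- length(phy$tip.label)
  roots <- integer(0)
  recurse <- function(v) {
    if (v <= ntip || stats::runif(1) < p_stop) {
      roots <<- c(roots, v)
    } else {
      for (k in phy$edge[phy$edge[, 1L] == v, 2L]) recurse(k)
    }
  }
  recurse(ntip + 1L)
  roots
}

#' Maximum-likelihood Poisson-tree-processes delimitation
#'
#' Trees with up to `max_exhaustive` tips are solved by exhaustive search
#' over every valid delimitation; larger trees by greedy hill-climbing over
#' split/merge moves from several starts (one species, all singletons, and
#' `restarts` random delimitations). Likelihood ties are broken toward
#' fewer entities.
#'
#' @param tree Rooted `phylo` or [support_tree()] with branch lengths.
#' @param max_exhaustive Tip count up to which the search is exhaustive.
#' @param restarts Random hill-climbing restarts for larger trees (uses the
#'   current RNG state; seed with [set.seed()] for reproducibility).
#' @return A `ptp_partition`: species roots, edge classes, induced
#'   [bc_partition()], rates and log-likelihood.
#' @export
ptp_ml <- function(tree, max_exhaustive = 12, restarts = 10) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  if (ntip < 2L) stop("need at least two tips")
  b <- pmax(phy$edge.length, 1e-8)
  ord <- topo_edge_order(phy)
  if (ntip <= max_exhaustive) {
    sets <- enumerate_rootsets(phy, ntip + 1L)
    best <- NULL; best_ll <- -Inf; best_k <- Inf
    for (rs in sets) {
      ll <- roots_loglik(phy, rs, b, ord)
      if (better(ll, length(rs), best_ll, best_k)) {
        best <- rs; best_ll <- ll; best_k <- length(rs)
      }
    }
    return(make_ptp_partition(phy, best))
  }
  climb <- function(roots) {
    ll <- roots_loglik(phy, roots, b, ord)
    repeat {
      mv <- ptp_moves(phy, roots)
      cand_best <- NULL; cand_ll <- ll; cand_k <- length(roots)
      for (s in mv$splits) {
        rs <- apply_move(phy, roots, "split", s)
        l2 <- roots_loglik(phy, rs, b, ord)
        if (better(l2, length(rs), cand_ll, cand_k)) {
          cand_best <- rs; cand_ll <- l2; cand_k <- length(rs)
        }
      }
      for (m in mv$merges) {
        rs <- apply_move(phy, roots, "merge", m)
        l2 <- roots_loglik(phy, rs, b, ord)
        if (better(l2, length(rs), cand_ll, cand_k)) {
          cand_best <- rs; cand_ll <- l2; cand_k <- length(rs)
        }
      }
      if (is.null(cand_best)) return(list(roots = roots, ll = ll))
      roots <- cand_best; ll <- cand_ll
    }
  }
  starts <- c(list(ntip + 1L, seq_len(ntip)),
              replicate(restarts, random_rootset(phy), simplify = FALSE))
  best <- NULL; best_ll <- -Inf; best_k <- Inf
  for (s0 in starts) {
    res <- climb(s0)
    if (better(res$ll, length(res$roots), best_ll, best_k)) {
      best <- res$roots; best_ll <- res$ll; best_k <- length(res$roots)
    }
  }
  make_ptp_partition(phy, best)
}

#' MCMC configuration for Bayesian PTP
#'
#' Defaults follow the standard schedule: one million iterations, sampling
#' every 1000, first 25% discarded as burn-in.
#'
#' @param iterations,sample_every,burnin_fraction MCMC schedule.
#' @param seed Optional integer seed applied at the start of the run.
#' @export
ptp_mcmc_config <- function(iterations = 1e6, sample_every = 1000,
                            burnin_fraction = 0.25, seed = NULL) {
  stopifnot(iterations > 0, sample_every >= 1,
            burnin_fraction >= 0, burnin_fraction < 1)
  list(iterations = as.integer(iterations),
       sample_every = as.integer(sample_every),
       burnin_fraction = burnin_fraction, seed = seed)
}

#' Bayesian Poisson-tree-processes delimitation
#'
#' Metropolis-Hastings over valid delimitations with a uniform prior;
#' proposals split one species into its child subtrees or merge sibling
#' species into their parent, chosen uniformly among the eligible moves
#' (with the usual Hastings correction for the move-count asymmetry).
#' Per-entity support is the fraction of retained samples in which exactly
#' that tip set forms one species. The log-likelihood trace should be
#' inspected for stationarity.
#'
#' @param tree Rooted `phylo` or [support_tree()] with branch lengths.
#' @param config A [ptp_mcmc_config()].
#' @param init Optional starting `ptp_partition` (defaults to the ML
#'   delimitation).
#' @return A `ptp_bayes` object: `supports` (entity tip sets with posterior
#'   support), `trace` (iteration, log-likelihood), `map` (highest
#'   log-likelihood sampled delimitation), `n_samples`.
#' @export
ptp_bayes <- function(tree, config = ptp_mcmc_config(), init = NULL) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!is.null(config$seed)) set.seed(config$seed)
  b <- pmax(phy$edge.length, 1e-8)
  ord <- topo_edge_order(phy)
  if (is.null(init)) init <- ptp_ml(tree)
  roots <- init$roots
  ll <- roots_loglik(phy, roots, b, ord)
  mv <- ptp_moves(phy, roots)
  burn <- floor(config$iterations * config$burnin_fraction)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  n_samples <- 0L
  trace_it <- integer(0); trace_ll <- numeric(0)
  map_roots <- roots; map_ll <- ll
  tip_key <- function(r) entity_key(phy$tip.label[tips_under(phy, r)])
  for (it in seq_len(config$iterations)) {
    pick <- sample.int(mv$n, 1L)
    if (pick <= length(mv$splits)) {
      type <- "split"; node <- mv$splits[pick]
    } else {
      type <- "merge"; node <- mv$merges[pick - length(mv$splits)]
    }
    prop <- apply_move(phy, roots, type, node)
    prop_mv <- ptp_moves(phy, prop)
    prop_ll <- roots_loglik(phy, prop, b, ord)
    log_alpha <- (prop_ll - ll) + log(mv$n) - log(prop_mv$n)
    if (log(stats::runif(1)) < log_alpha) {
      roots <- prop; ll <- prop_ll; mv <- prop_mv
      if (ll > map_ll) { map_ll <- ll; map_roots <- roots }
    }
    if (it %% config$sample_every == 0L) {
      trace_it <- c(trace_it, it); trace_ll <- c(trace_ll, ll)
      if (it > burn) {
        n_samples <- n_samples + 1L
        for (r in roots) {
          key <- tip_key(r)
          counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
        }
      }
    }
  }
  keys <- ls(counts)
  supports <- data.frame(
    entity = keys,
    n_tips = lengths(strsplit(keys, "|", fixed = TRUE)),
    support = vapply(keys, function(k) counts[[k]] / n_samples, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  supports <- supports[order(-supports$support, supports$entity), ]
  structure(list(supports = supports,
                 trace = data.frame(iteration = trace_it, loglik = trace_ll),
                 map = make_ptp_partition(phy, map_roots),
                 n_samples = n_samples, config = config),
            class = "ptp_bayes")
}

#' @export
print.ptp_bayes <- function(x, ...) {
  cat(sprintf("ptp_bayes: %d retained samples; MAP has %d entities (logL %.3f)\n",
              x$n_samples, n_entities(x$map$partition), x$map$loglik))
  invisible(x)
}

#' Posterior support of a set of entities
#'
#' Looks up the sampled support for each group of a partition (0 when the
#' exact tip set was never sampled as an entity).
#'
#' @param bayes A `ptp_bayes` result.
#' @param partition A [bc_partition()] (e.g. the truth, or the ML one).
#' @return Named numeric vector of supports per entity of `partition`.
#' @export
entity_support <- function(bayes, partition) {
  keys <- vapply(partition$groups, entity_key, character(1))
  sup <- setNames(numeric(length(keys)), names(keys))
  hit <- match(keys, bayes$supports$entity)
  sup[!is.na(hit)] <- bayes$supports$support[hit[!is.na(hit)]]
  sup
}
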