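# Reference-library simulator. Trees are ultrametric within the library:
# each species is a crown (polytomy) of individuals at its intraspecific
# height, species crowns coalesce at deeper heights inside their genus, and
# genera join on a deep backbone. Sequences then evolve site-independently
# under K80 along the tree, by exponential waiting times (Poisson event
# counts per site with the K80 jump chain), so the realized data match the
# distance estimator's model exactly.

#' Simulation configuration for a synthetic reference library
#'
#' Defaults emulate a grass-tribe-like library scored on its most variable
#' nuclear marker: mean intraspecific K80 divergence 0.68% and mean
#' interspecific (congeneric) divergence 5.94%, with 1-15 individuals per
#' species and three markers of decreasing variability
#' (`rbcL` < `matK` < `ITS`).
#'
#' @param n_genera,species_per_genus Library layout.
#' @param individuals_per_species Inclusive range to draw each species'
#'   sampling depth from.
#' @param marker_lengths Named integer vector of alignment columns.
#' @param marker_rel_rate Substitution-rate multipliers per marker relative
#'   to the most variable one.
#' @param kappa Transition/transversion rate ratio (alpha/beta); scalar or
#'   one value per genus.
#' @param intra_mean,inter_mean Target mean intra- and inter-specific K80
#'   distances on the most variable marker (proportion scale).
#' @param missing_marker_prob Probability that an individual was not
#'   sequenced for a marker (it is then absent from that marker's
#'   alignment; concatenation refills it with `N`).
#' @param ambiguity_rate Per-site probability of recording an IUPAC
#'   ambiguity code (a polymorphic base call) instead of the true base.
#' @param scenario `"gap"` (all species separated by a barcode gap) or
#'   `"radiation"` (overlapping divergence distributions; each genus
#'   contains a pair of recently diverged species drawn from a shared
#'   polymorphic cluster).
#' @param support_noise In `[0,1]`: 0 gives full support (100/1.0) on every
#'   true clade; larger values degrade supports uniformly at random.
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @export
sim_config <- function(n_genera = 4, species_per_genus = 5,
                       individuals_per_species = c(1, 15),
                       marker_lengths = c(rbcL = 1300, matK = 800, ITS = 600),
                       marker_rel_rate = c(rbcL = 0.15, matK = 0.38, ITS = 1),
                       kappa = 2.0,
                       intra_mean = 0.0068, inter_mean = 0.0594,
                       missing_marker_prob = 0.05, ambiguity_rate = 0.001,
                       scenario = c("gap", "radiation"),
                       support_noise = 0, seed = 1) {
  scenario <- match.arg(scenario)
  # accept YAML-style list inputs
  marker_lengths <- unlist(marker_lengths)
  marker_rel_rate <- unlist(marker_rel_rate)
  individuals_per_species <- as.numeric(unlist(individuals_per_species))
  kappa <- as.numeric(unlist(kappa))
  if (is.null(names(marker_lengths)) || is.null(names(marker_rel_rate)))
    stop("marker_lengths and marker_rel_rate must be named by marker")
  stopifnot(n_genera >= 1, species_per_genus >= 2,
            length(individuals_per_species) == 2,
            individuals_per_species[1] >= 1,
            diff(individuals_per_species) >= 0,
            all(marker_lengths > 0), all(marker_rel_rate > 0),
            all(kappa > 0), intra_mean > 0, inter_mean > intra_mean,
            missing_marker_prob >= 0, missing_marker_prob <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            support_noise >= 0, support_noise <= 1)
  if (!identical(names(marker_lengths), names(marker_rel_rate)))
    stop("marker_lengths and marker_rel_rate must name the same markers")
  list(n_genera = n_genera, species_per_genus = species_per_genus,
       individuals_per_species = individuals_per_species,
       marker_lengths = marker_lengths, marker_rel_rate = marker_rel_rate,
       kappa = kappa, intra_mean = intra_mean, inter_mean = inter_mean,
       missing_marker_prob = missing_marker_prob,
       ambiguity_rate = ambiguity_rate, scenario = scenario,
       support_noise = support_noise, seed = seed)
}

# ---- tree construction -----------------------------------------------------

tip_node <- function(id) list(id = id, height = 0, children = NULL)
inner_node <- function(children, height) list(id = NULL, height = height,
                                              children = children)

crown_node <- function(ids, height) {
  if (length(ids) == 1L) tip_node(ids) else
    inner_node(lapply(ids, tip_node), height)
}

# merge clusters bottom-up at the given ascending heights, random pairs
merge_clusters <- function(clusters, heights) {
  for (h in heights) {
    pick <- sample.int(length(clusters), 2L)
    joined <- inner_node(clusters[pick], h)
    clusters <- c(clusters[-pick], list(joined))
  }
  stopifnot(length(clusters) == 1L)
  clusters[[1L]]
}

# Build one genus: species crowns + coalescent merges whose heights are
# affinely adjusted (keeping the floor `lo`) so the expected mean
# interspecific distance equals 2 * target_height.
build_genus <- function(cfg, genus, g) {
  k <- cfg$species_per_genus
  n_s <- sample(seq(cfg$individuals_per_species[1],
                    cfg$individuals_per_species[2]), k, replace = TRUE)
  half_intra <- cfg$intra_mean / 2
  gap <- cfg$scenario == "gap"
  # gap scenario: crowns sit exactly at the intraspecific scale and species
  # merges are floored well above it, so the realized distance gap survives
  # the binomial sampling noise of finite alignments
  h_s <- if (gap) rep(half_intra, k) else half_intra * stats::runif(k, 0.25, 1.75)
  species <- sprintf("sp%02d", seq_len(k))
  ids <- lapply(seq_len(k), function(s)
    sprintf("G%02dS%02dI%02d", g, s, seq_len(n_s[s])))

  if (gap) {
    lo <- 4.0 * cfg$intra_mean
    clusters <- lapply(seq_len(k), function(s) crown_node(ids[[s]], h_s[s]))
    cluster_sizes <- n_s
    crown_pairs <- data.frame(h = numeric(0), n = numeric(0))
  } else {
    # a species complex: the last two species are drawn from one shared
    # polymorphic cluster, interleaved, so labels are not monophyletic
    lo <- 1.0 * cfg$intra_mean
    h_cx <- half_intra * stats::runif(1, 0.9, 1.3)
    cx_ids <- c(rbind(c(ids[[k - 1L]], rep(NA, max(0, n_s[k] - n_s[k - 1L]))),
                      c(ids[[k]], rep(NA, max(0, n_s[k - 1L] - n_s[k])))))
    cx_ids <- cx_ids[!is.na(cx_ids)]
    clusters <- c(lapply(seq_len(k - 2L), function(s)
                    crown_node(ids[[s]], h_s[s])),
                  list(crown_node(cx_ids, h_cx)))
    cluster_sizes <- c(n_s[seq_len(k - 2L)], n_s[k - 1L] + n_s[k])
    crown_pairs <- data.frame(h = h_cx, n = n_s[k - 1L] * n_s[k])
  }
  n_cl <- length(clusters)
  target_h <- cfg$inter_mean / 2
  if (n_cl >= 2L) {
    if (target_h <= lo)
      stop("infeasible scenario: mean interspecific target below the ",
           "divergence floor (genus ", genus, ")")
    spread <- max(2 * (target_h - lo), 0.2 * lo)
    raw <- sort(lo + stats::runif(n_cl - 1L, 0, spread))
    # cross-cluster pair counts per merge, for the pair-weighted mean height
    order_pick <- vector("list", n_cl - 1L)
    sizes <- cluster_sizes
    pair_n <- numeric(n_cl - 1L)
    for (j in seq_len(n_cl - 1L)) {
      pick <- sample.int(length(sizes), 2L)
      order_pick[[j]] <- pick
      pair_n[j] <- sizes[pick[1L]] * sizes[pick[2L]]
      sizes <- c(sizes[-pick], sizes[pick[1L]] + sizes[pick[2L]])
    }
    N <- sum(pair_n) + sum(crown_pairs$n)
    s <- (N * target_h - sum(crown_pairs$h * crown_pairs$n) -
            sum(lo * pair_n)) / sum((raw - lo) * pair_n)
    if (!is.finite(s) || s <= 0.05)
      stop("infeasible scenario: interspecific target too close to the ",
           "intraspecific floor (genus ", genus, ")")
    heights <- lo + s * (raw - lo)
    for (j in seq_len(n_cl - 1L)) {
      pick <- order_pick[[j]]
      joined <- inner_node(clusters[pick], heights[j])
      clusters <- c(clusters[-pick], list(joined))
    }
  }
  clusters[[1L]]$kappa_idx <- g
  info <- data.frame(
    individual_id = unlist(ids),
    genus = genus,
    species = rep(species, n_s),
    stringsAsFactors = FALSE)
  list(node = clusters[[1L]], info = info)
}

tree_height <- function(node) node$height

# Newick emission with per-node support labels
emit_newick <- function(node, parent_height, support_noise) {
  if (is.null(node$children)) {
    sprintf("%s:%.10f", node$id, parent_height - node$height)
  } else {
    kids <- vapply(node$children, emit_newick, character(1),
                   parent_height = node$height,
                   support_noise = support_noise)
    bs <- 100 * (1 - support_noise * stats::runif(1))
    pp <- 1 - support_noise * stats::runif(1)
    lab <- sprintf("%.4g/%.4g", bs, pp)
    if (is.na(parent_height)) {
      sprintf("(%s)%s", paste(kids, collapse = ","), lab)
    } else {
      sprintf("(%s)%s:%.10f", paste(kids, collapse = ","), lab,
              parent_height - node$height)
    }
  }
}

# ---- sequence evolution ----------------------------------------------------

TS_PARTNER <- c(3L, 4L, 1L, 2L)                  # A<->G, C<->T
TV_PARTNERS <- list(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))

# evolve an integer-coded sequence for expected `t` substitutions/site
evolve_seq <- function(seq, t, kappa, events) {
  if (t <= 0) return(seq)
  nm <- stats::rpois(length(seq), t)
  hit <- which(nm > 0L)
  p_ts <- kappa / (kappa + 2)
  for (i in hit) {
    base <- seq[i]
    for (m in seq_len(nm[i])) {
      if (stats::runif(1) < p_ts) {
        base <- TS_PARTNER[base]
        events$ts <- events$ts + 1L
      } else {
        base <- TV_PARTNERS[[base]][sample.int(2L, 1L)]
        events$tv <- events$tv + 1L
      }
    }
    seq[i] <- base
  }
  seq
}

# `kappa_by_genus` takes over at each genus subtree root (tagged kappa_idx)
evolve_tree <- function(node, seq, rate, kappa, kappa_by_genus, events, out) {
  if (!is.null(node$kappa_idx)) kappa <- kappa_by_genus[node$kappa_idx]
  if (is.null(node$children)) {
    out[[node$id]] <- seq
    return(invisible(NULL))
  }
  for (child in node$children) {
    k2 <- if (is.null(child$kappa_idx)) kappa
          else kappa_by_genus[child$kappa_idx]
    t <- (node$height - child$height) * rate
    evolve_tree(child, evolve_seq(seq, t, k2, events), rate, k2,
                kappa_by_genus, events, out)
  }
  invisible(NULL)
}

AMBIG_FOR <- list(c("R", "M", "W"), c("M", "S", "Y"),
                  c("R", "S", "K"), c("W", "K", "Y"))

#' Simulate a multi-genus, multi-marker barcode reference library
#'
#' Produces per-marker alignments (individuals not sequenced for a marker
#' are absent from it), the taxon table, the true tree with node supports,
#' and the true species partition. Everything is deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `alignments` (named list of [bc_alignment()]),
#'   `info`, `tree` (a dual-support [support_tree()]), `partition` (true
#'   species assignment as a [bc_partition()]), `events` (transition and
#'   transversion event counts), and `config`.
#' @export
simulate_library <- function(config = sim_config()) {
  set.seed(config$seed)
  kappa <- rep_len(config$kappa, config$n_genera)
  genera <- sprintf("Genus%02d", seq_len(config$n_genera))
  built <- lapply(seq_len(config$n_genera), function(g)
    build_genus(config, genera[g], g))
  info <- do.call(rbind, lapply(built, `[[`, "info"))
  nodes <- lapply(built, `[[`, "node")
  if (length(nodes) > 1L) {
    hmax <- max(vapply(nodes, tree_height, numeric(1)))
    h <- 1.5 * hmax
    heights <- numeric(length(nodes) - 1L)
    for (j in seq_along(heights)) { heights[j] <- h; h <- h * 1.3 }
    root <- merge_clusters(nodes, heights)
  } else {
    root <- nodes[[1L]]
  }
  newick <- paste0(emit_newick(root, NA_real_, config$support_noise), ";")
  phy <- ape::read.tree(text = newick)
  sup <- parse_supports(phy$node.label, "dual")
  tree <- support_tree(phy, "dual", bootstrap = sup$bootstrap,
                       posterior = sup$posterior)

  events <- new.env(parent = emptyenv()); events$ts <- 0L; events$tv <- 0L
  alignments <- list()
  for (mk in names(config$marker_lengths)) {
    L <- config$marker_lengths[[mk]]
    out <- new.env(parent = emptyenv())
    rootseq <- sample.int(4L, L, replace = TRUE)
    evolve_tree(root, rootseq, config$marker_rel_rate[[mk]], kappa[1L],
                kappa, events, out)
    tips <- info$individual_id
    keep <- stats::runif(length(tips)) >= config$missing_marker_prob
    tips <- tips[keep]
    chars <- c("A", "C", "G", "T")
    seqs <- vapply(tips, function(id) {
      v <- chars[out[[id]]]
      if (config$ambiguity_rate > 0) {
        amb <- which(stats::runif(L) < config$ambiguity_rate)
        for (i in amb)
          v[i] <- sample(AMBIG_FOR[[out[[id]][i]]], 1L)
      }
      paste0(v, collapse = "")
    }, character(1))
    sel <- match(tips, info$individual_id)
    alignments[[mk]] <- bc_alignment(setNames(seqs, tips),
                                     genus = info$genus[sel],
                                     species = info$species[sel],
                                     marker = mk)
  }
  partition <- bc_partition(setNames(paste(info$genus, info$species),
                                     info$individual_id))
  list(alignments = alignments, info = info, tree = tree,
       partition = partition,
       events = c(ts = events$ts, tv = events$tv), config = config)
}

#' Simulate a two-rate tree for Poisson-tree-processes validation
#'
#' Speciation branches (the species backbone and each species' stem) get
#' exponential lengths with rate `lambda_between`; branches inside species
#' subtrees get rate `rate_ratio * lambda_between` (shorter on average, the
#' within-species process).
#'
#' @param n_species Number of species.
#' @param n_per_species Tips per species (scalar or vector).
#' @param rate_ratio Within- to between-species rate ratio (> 1 means
#'   within-species branches are shorter).
#' @param lambda_between Base rate of the between-species process.
#' @param seed Optional seed.
#' @return List with `tree` (bootstrap [support_tree()], all supports 100),
#'   `partition` (true species assignment), `info` (taxon table).
#' @export
simulate_ptp_tree <- function(n_species, n_per_species, rate_ratio,
                              lambda_between = 1, seed = NULL) {
  if (n_species < 1L) stop("n_species must be at least 1")
  if (rate_ratio <= 0) stop("rate_ratio must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_per <- rep_len(n_per_species, n_species)
  lw <- rate_ratio * lambda_between
  rand_join <- function(parts, rate) {
    while (length(parts) > 1L) {
      pick <- sample.int(length(parts), 2L)
      joined <- sprintf("(%s:%.8f,%s:%.8f)", parts[pick[1L]],
                        stats::rexp(1, rate), parts[pick[2L]],
                        stats::rexp(1, rate))
      parts <- c(parts[-pick], joined)
    }
    parts
  }
  species_txt <- vapply(seq_len(n_species), function(s) {
    tips <- sprintf("S%02dI%02d", s, seq_len(n_per[s]))
    rand_join(tips, lw)
  }, character(1))
  if (n_species == 1L) {
    txt <- if (n_per[1L] > 1L) paste0(species_txt, ";")
           else sprintf("(%s:%.8f);", species_txt, stats::rexp(1, lambda_between))
  } else {
    txt <- paste0(rand_join(species_txt, lambda_between), ";")
  }
  phy <- ape::read.tree(text = txt)
  tree <- support_tree(phy, "bootstrap",
                       bootstrap = rep(100, phy$Nnode))
  species <- sub("I[0-9]+$", "", phy$tip.label)
  partition <- bc_partition(setNames(species, phy$tip.label))
  info <- data.frame(individual_id = phy$tip.label, genus = "Genus01",
                     species = species, stringsAsFactors = FALSE)
  list(tree = tree, partition = partition, info = info)
}
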