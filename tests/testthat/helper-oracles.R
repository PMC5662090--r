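# Independent brute-force oracles, written as literal set-builders over the
# identification rules. They share no code with the package implementation.

# D: symmetric matrix with NA = undefined, ids as dimnames; labels: named
# character; thr: percent scale or NULL
oracle_classify <- function(method, query, D, labels, thr = NULL) {
  ids <- rownames(D)
  others <- setdiff(ids, query)
  dd <- D[query, others]
  def <- others[!is.na(dd)]
  if (method == "NN") {
    if (length(def) == 0) return("unidentifiable")
    dmin <- min(D[query, def])
    closest <- def[D[query, def] == dmin]
    ok <- TRUE
    for (r in closest) if (labels[r] != labels[query]) ok <- FALSE
    return(if (ok) "true" else "false")
  }
  if (method == "BCM") {
    if (length(def) == 0) return("no_identification")
    dmin <- min(D[query, def])
    if (dmin * 100 > thr) return("no_identification")
    closest <- def[D[query, def] == dmin]
    match_flags <- labels[closest] == labels[query]
    if (all(match_flags)) return("correct")
    if (!any(match_flags)) return("incorrect")
    return("ambiguous")
  }
  if (method == "TID") {
    W <- character(0)
    for (r in def) if (D[query, r] * 100 <= thr) W <- c(W, r)
    if (length(W) == 0) return("no_identification")
    match_flags <- labels[W] == labels[query]
    if (all(match_flags)) return("correct")
    if (!any(match_flags)) return("incorrect")
    return("ambiguous")
  }
  stop("unknown method")
}

# brute-force threshold profile: reclassify every query at every grid value
oracle_profile <- function(D, labels, grid, ambiguous_as_fp = TRUE) {
  ids <- rownames(D)
  usable <- vapply(ids, function(q) {
    any(labels[setdiff(ids, q)] == labels[q])
  }, logical(1))
  qs <- ids[usable]
  fp <- integer(length(grid)); fn <- integer(length(grid))
  for (k in seq_along(grid)) {
    for (q in qs) {
      cat_q <- oracle_classify("BCM", q, D, labels, grid[k])
      if (cat_q == "no_identification") fn[k] <- fn[k] + 1L
      else if (cat_q == "incorrect") fp[k] <- fp[k] + 1L
      else if (cat_q == "ambiguous" && ambiguous_as_fp) fp[k] <- fp[k] + 1L
    }
  }
  cum <- fp + fn
  list(fp = fp, fn = fn, cumulative = cum,
       optimum = max(grid[cum == min(cum)]))
}

# random leave-one-out identification instance
random_instance <- function(n_min = 4, n_max = 20) {
  n <- sample(n_min:n_max, 1)
  ids <- sprintf("q%02d", seq_len(n))
  # random label structure over a random number of species
  labels <- setNames(sprintf("sp%d", sample.int(max(2, n %/% 2), n,
                                                replace = TRUE)), ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- round(stats::runif(n * (n - 1) / 2, 0, 0.03), 4)  # rounding -> ties
  D[upper.tri(D)] <- vals
  D <- D + t(D)
  # mask a few pairs
  if (n > 4 && stats::runif(1) < 0.5) {
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    D[i, j] <- D[j, i] <- NA
  }
  list(D = D, labels = labels, ids = ids,
       thr = round(stats::runif(1, 0, 3), 3))
}

bc_dist_from_matrix <- function(D) {
  structure(list(ids = rownames(D), d = D,
                 masked_pairs = character(0)), class = "bc_dist")
}

info_from_labels <- function(labels) {
  # labels are full species names "g sp"; single genus "G" when no space
  parts <- strsplit(labels, " ", fixed = TRUE)
  has_genus <- lengths(parts) == 2
  data.frame(individual_id = names(labels),
             genus = ifelse(has_genus, vapply(parts, `[[`, "", 1L), "G"),
             species = vapply(parts, function(p) p[[length(p)]], ""),
             stringsAsFactors = FALSE)
}

# naive monophyly oracle: intersect root paths for the MRCA, scan descendants
oracle_monophyly <- function(phy, members) {
  parent_of <- function(v) {
    e <- which(phy$edge[, 2] == v)
    if (length(e) == 0) NA_integer_ else phy$edge[e, 1]
  }
  path_to_root <- function(v) {
    out <- v
    while (!is.na(v <- parent_of(v))) out <- c(out, v)
    out
  }
  idx <- match(members, phy$tip.label)
  common <- Reduce(intersect, lapply(idx, path_to_root))
  mrca <- common[1]  # paths list ancestors bottom-up; first shared is MRCA
  desc <- c()
  for (tip in seq_along(phy$tip.label))
    if (mrca %in% path_to_root(tip)) desc <- c(desc, phy$tip.label[tip])
  setequal(desc, members)
}

# congruence oracle via the |E_s| / purity case split
oracle_congruence <- function(groups, species_of) {
  ids <- unlist(groups, use.names = FALSE)
  out <- list()
  for (s in sort(unique(species_of[ids]))) {
    I_s <- ids[species_of[ids] == s]
    E_s <- Filter(function(g) length(intersect(groups[[g]], I_s)) > 0,
                  names(groups))
    if (length(E_s) == 1 && setequal(groups[[E_s]], I_s)) cat_s <- "+"
    else if (length(E_s) == 1) cat_s <- "L"
    else if (all(vapply(E_s, function(g) all(groups[[g]] %in% I_s),
                        logical(1)))) cat_s <- "S"
    else cat_s <- "L/S"
    out[[s]] <- cat_s
  }
  unlist(out)
}

# all set partitions of a vector (Bell number sized; fine for n <= 5)
all_set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- all_set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(x[1], q[[k]])
      out <- c(out, list(q))
    }
    out <- c(out, list(c(list(x[1]), p)))
  }
  out
}

# unrooted split set of a tree: each internal edge's tip set, canonicalized
oracle_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  splits <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    v <- phy$edge[e, 2]
    if (v <= ntip) next
    tips <- sort(phy$tip.label[barcodeval:::tips_under(phy, v)])
    comp <- sort(setdiff(phy$tip.label, tips))
    if (length(tips) < 2 || length(comp) < 2) next
    key <- if (paste(tips, collapse = ",") < paste(comp, collapse = ","))
      paste(tips, collapse = ",") else paste(comp, collapse = ",")
    splits <- c(splits, key)
  }
  sort(unique(splits))
}
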