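#' Construct a support tree
#'
#' A rooted phylogeny whose internal nodes carry clade support, either
#' bootstrap percentages (0-100), Bayesian posterior probabilities (0-1), or
#' both ("dual", as in trees annotated `BS/PP`).
#'
#' @param phy A rooted `ape::phylo` object with tip labels equal to
#'   individual ids.
#' @param support_type `"bootstrap"`, `"posterior"` or `"dual"`.
#' @param bootstrap,posterior Numeric vectors of length `phy$Nnode` aligned
#'   with internal node numbering (`Ntip+1 ...`); `NA` for nodes without a
#'   value (typically the root).
#' @return An object of class `support_tree`.
#' @export
support_tree <- function(phy, support_type = c("bootstrap", "posterior", "dual"),
                         bootstrap = NULL, posterior = NULL) {
  support_type <- match.arg(support_type)
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (anyDuplicated(phy$tip.label) > 0L) stop("tip labels must be unique")
  # basal polytomies are permitted: the root is the structural root node,
  # whether or not it is binary
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length")
  chk <- function(x, lo, hi, what) {
    if (is.null(x)) stop("missing ", what, " support values")
    if (length(x) != phy$Nnode) stop(what, " support length != Nnode")
    if (any(!is.na(x) & (x < lo | x > hi)))
      stop(what, " support outside [", lo, ",", hi, "]")
    as.numeric(x)
  }
  if (support_type %in% c("bootstrap", "dual"))
    bootstrap <- chk(bootstrap, 0, 100, "bootstrap")
  else bootstrap <- NULL
  if (support_type %in% c("posterior", "dual"))
    posterior <- chk(posterior, 0, 1, "posterior")
  else posterior <- NULL
  structure(list(phy = phy, support_type = support_type,
                 bootstrap = bootstrap, posterior = posterior),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("support_tree: %d tips, %d internal nodes, %s supports\n",
              length(x$phy$tip.label), x$phy$Nnode, x$support_type))
  invisible(x)
}

parse_supports <- function(labels, support_type, dual_separator = "/", n = NULL) {
  if (is.null(labels) && !is.null(n)) labels <- rep(NA_character_, n)
  labels[is.na(labels) | labels == ""] <- NA_character_
  num <- function(v) suppressWarnings(as.numeric(v))
  if (support_type == "dual") {
    parts <- strsplit(labels, dual_separator, fixed = TRUE)
    bs <- num(vapply(parts, function(p) if (length(p) >= 1L) p[1L] else NA_character_,
                     character(1)))
    pp <- num(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                     character(1)))
    list(bootstrap = bs, posterior = pp)
  } else if (support_type == "bootstrap") {
    list(bootstrap = num(labels), posterior = NULL)
  } else {
    list(bootstrap = NULL, posterior = num(labels))
  }
}

#' Read a Newick tree with node supports
#'
#' Internal node labels are interpreted as supports: plain numbers for
#' bootstrap or posterior trees, or `BS<sep>PP` pairs for dual-annotated
#' trees (maximum-likelihood bootstrap before the separator, Bayesian
#' posterior probability after it).
#'
#' @param path Newick file.
#' @param support_type `"bootstrap"`, `"posterior"` or `"dual"`.
#' @param dual_separator Separator between the two supports of a dual label.
#' @return A [support_tree()].
#' @export
read_support_tree <- function(path,
                              support_type = c("bootstrap", "posterior", "dual"),
                              dual_separator = "/") {
  support_type <- match.arg(support_type)
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  sup <- parse_supports(phy$node.label, support_type, dual_separator,
                        n = phy$Nnode)
  support_tree(phy, support_type, bootstrap = sup$bootstrap,
               posterior = sup$posterior)
}

support_labels <- function(st) {
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, digits = 10))
  switch(st$support_type,
         bootstrap = fmt(st$bootstrap),
         posterior = fmt(st$posterior),
         dual = {
           lab <- paste(fmt(st$bootstrap), fmt(st$posterior), sep = "/")
           lab[is.na(st$bootstrap) & is.na(st$posterior)] <- ""
           lab
         })
}

#' Write a support tree to Newick
#'
#' @param st A [support_tree()].
#' @param path Output file.
#' @param dual_separator Separator used for dual supports.
#' @export
write_support_tree <- function(st, path, dual_separator = "/") {
  phy <- st$phy
  lab <- support_labels(st)
  if (st$support_type == "dual" && dual_separator != "/")
    lab <- gsub("/", dual_separator, lab, fixed = TRUE)
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Root a tree on an outgroup
#'
#' Roots on the edge subtending the most recent common ancestor of the
#' outgroup tips; node supports travel with the edges they annotate.
#'
#' @param st A [support_tree()] (may wrap an effectively unrooted topology).
#' @param outgroup_ids Tip labels of the outgroup.
#' @return A rooted [support_tree()].
#' @export
root_on_outgroup <- function(st, outgroup_ids) {
  phy <- st$phy
  missing <- setdiff(outgroup_ids, phy$tip.label)
  if (length(missing) > 0L)
    stop("outgroup id(s) not in tree: ", paste(missing, collapse = ", "))
  if (length(outgroup_ids) >= length(phy$tip.label))
    stop("outgroup cannot contain every tip")
  phy$node.label <- support_labels(st)
  re <- ape::root(phy, outgroup = outgroup_ids, resolve.root = TRUE,
                  edgelabel = TRUE)
  sup <- parse_supports(re$node.label, st$support_type, n = re$Nnode)
  support_tree(re, st$support_type, bootstrap = sup$bootstrap,
               posterior = sup$posterior)
}

#' Drop tips from a support tree
#'
#' @param st A [support_tree()].
#' @param tips Tip labels to remove.
#' @return A [support_tree()] without those tips.
#' @export
prune_tips <- function(st, tips) {
  phy <- st$phy
  phy$node.label <- support_labels(st)
  re <- ape::drop.tip(phy, tips)
  if (is.null(re)) stop("pruning removed the whole tree")
  sup <- parse_supports(re$node.label, st$support_type, n = re$Nnode)
  support_tree(re, st$support_type, bootstrap = sup$bootstrap,
               posterior = sup$posterior)
}

# tip indices descending from `node` (tips themselves allowed)
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[, 2L][phy$edge[, 1L] == node]
  out <- integer(0)
  stack <- kids
  while (length(stack) > 0L) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) out <- c(out, v)
    else stack <- c(stack, phy$edge[, 2L][phy$edge[, 1L] == v])
  }
  out
}
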