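#' Collapse unsupported nodes into polytomies
#'
#' Internal nodes whose clade support falls below the cut-off (bootstrap
#' < `min_bootstrap`, or posterior < `min_posterior`; boundaries inclusive,
#' a node at exactly the cut-off is retained) are contracted into their
#' parent. The length of a contracted edge is added to the edges of its
#' children, so root-to-tip path lengths are preserved. Nodes without a
#' support value (typically the root) are retained.
#'
#' @param st A rooted [support_tree()].
#' @param min_bootstrap,min_posterior Support cut-offs.
#' @param use For dual-support trees, which support to apply
#'   (`"bootstrap"` or `"posterior"`); single-support trees use their own.
#' @return A [support_tree()] in which every retained internal node meets
#'   the cut-off.
#' @export
collapse_unsupported <- function(st, min_bootstrap = 65, min_posterior = 0.95,
                                 use = NULL) {
  if (st$support_type == "dual") {
    if (is.null(use) || !use %in% c("bootstrap", "posterior"))
      stop("dual-support tree: say which support to use ",
           "(use = \"bootstrap\" or \"posterior\")")
  } else {
    use <- st$support_type
  }
  sup <- st[[use]]
  cutoff <- if (use == "bootstrap") min_bootstrap else min_posterior
  phy <- st$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  nodes <- root:(ntip + phy$Nnode)
  drop <- !is.na(sup) & sup < cutoff
  drop[1L] <- FALSE                     # never collapse the root
  if (!any(drop)) return(st)

  parent <- integer(ntip + phy$Nnode)
  elen <- numeric(ntip + phy$Nnode)
  has_len <- !is.null(phy$edge.length)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  if (has_len) elen[phy$edge[, 2L]] <- phy$edge.length

  keep_node <- rep(TRUE, ntip + phy$Nnode)
  keep_node[nodes[drop]] <- FALSE
  # effective parent = nearest kept ancestor; accumulate collapsed lengths
  eff_parent <- function(v) {
    p <- parent[v]; acc <- 0
    while (!keep_node[p]) { acc <- acc + elen[p]; p <- parent[p] }
    list(p = p, add = acc)
  }
  kept <- c(seq_len(ntip), nodes[!drop & nodes >= root])
  children <- vector("list", ntip + phy$Nnode)
  len2 <- elen
  for (v in setdiff(kept, root)) {
    ep <- eff_parent(v)
    children[[ep$p]] <- c(children[[ep$p]], v)
    len2[v] <- elen[v] + ep$add
  }
  sup_of <- function(v) {
    i <- v - ntip
    c(bs = if (is.null(st$bootstrap)) NA_real_ else st$bootstrap[i],
      pp = if (is.null(st$posterior)) NA_real_ else st$posterior[i])
  }
  fmt <- function(x) if (is.na(x)) "" else format(x, trim = TRUE, digits = 10)
  label_of <- function(v) {
    s <- sup_of(v)
    switch(st$support_type,
           bootstrap = fmt(s[["bs"]]),
           posterior = fmt(s[["pp"]]),
           dual = if (is.na(s[["bs"]]) && is.na(s[["pp"]])) ""
                  else paste(fmt(s[["bs"]]), fmt(s[["pp"]]), sep = "/"))
  }
  build <- function(v) {
    lab <- if (v <= ntip) phy$tip.label[v]
           else paste0("(", paste(vapply(children[[v]], build, character(1)),
                                  collapse = ","), ")", label_of(v))
    if (has_len && v != root) paste0(lab, ":", format(len2[v], digits = 12))
    else lab
  }
  txt <- paste0(build(root), ";")
  re <- ape::read.tree(text = txt)
  ps <- parse_supports(re$node.label, st$support_type, n = re$Nnode)
  support_tree(re, st$support_type, bootstrap = ps$bootstrap,
               posterior = ps$posterior)
}

#' Liberal tree-based identification of one query tip
#'
#' On a support-collapsed, rooted tree, the query is scored from the taxa of
#' the other tips descending from its parent node: all conspecific (or
#' congeneric, at genus rank) gives `"success"`; a mixture, or a query with
#' no same-taxon individual anywhere in the tree, gives `"ambiguous"`; none
#' matching gives `"misidentified"`. This single rule covers the cherry,
#' sister-clade and polytomy cases of the liberal criteria.
#'
#' @param st A collapsed, rooted [support_tree()].
#' @param query Tip label.
#' @param info Taxon table (`individual_id`, `genus`, `species`).
#' @param rank `"species"` or `"genus"`.
#' @param exclude Tip labels (e.g. outgroup individuals) ignored when
#'   collecting taxon multisets.
#' @return One-row data frame: query, rank, category, evidence.
#' @export
liberal_classify <- function(st, query, info, rank = c("species", "genus"),
                             exclude = character(0)) {
  rank <- match.arg(rank)
  phy <- st$phy
  q <- match(query, phy$tip.label)
  if (is.na(q)) stop("query is not a tip of the tree: ", query)
  labels <- taxon_labels(info, rank)
  unlabeled <- setdiff(setdiff(phy$tip.label, exclude), names(labels))
  if (length(unlabeled) > 0L)
    stop("tip(s) without taxon labels: ",
         paste(utils::head(unlabeled, 5L), collapse = ", "))
  tip_taxa <- labels[phy$tip.label]
  consider <- setdiff(phy$tip.label, c(query, exclude))
  if (!any(labels[consider] == labels[query])) {
    return(data.frame(query = query, rank = rank, category = "ambiguous",
                      evidence = "no same-taxon individual in tree",
                      stringsAsFactors = FALSE))
  }
  parent <- phy$edge[phy$edge[, 2L] == q, 1L]
  sibs <- setdiff(phy$tip.label[tips_under(phy, parent)], c(query, exclude))
  taxa <- tip_taxa[sibs]
  same <- taxa == labels[query]
  category <- if (length(taxa) == 0L) "ambiguous"
              else if (all(same)) "success"
              else if (any(same)) "ambiguous" else "misidentified"
  data.frame(query = query, rank = rank, category = category,
             evidence = sprintf("parent clade: %d conspecific, %d other",
                                sum(same), sum(!same)),
             stringsAsFactors = FALSE)
}

#' Liberal classification of every tip
#'
#' @inheritParams liberal_classify
#' @return Data frame with one row per non-excluded tip.
#' @export
liberal_classify_all <- function(st, info, rank = c("species", "genus"),
                                 exclude = character(0)) {
  rank <- match.arg(rank)
  tips <- setdiff(st$phy$tip.label, exclude)
  do.call(rbind, lapply(tips, function(q)
    liberal_classify(st, q, info, rank, exclude)))
}

#' Taxon monophyly report
#'
#' A taxon with two or more tips is monophyletic when its tips' most recent
#' common ancestor subtends no other (non-excluded) tips; taxa with one tip
#' are flagged `"singleton"`.
#'
#' @inheritParams liberal_classify
#' @return Data frame: taxon, n_tips, status.
#' @export
monophyly_report <- function(st, info, rank = c("species", "genus"),
                             exclude = character(0)) {
  rank <- match.arg(rank)
  phy <- st$phy
  labels <- taxon_labels(info, rank)
  tips <- setdiff(phy$tip.label, exclude)
  taxa <- sort(unique(labels[tips]))
  rows <- lapply(taxa, function(tx) {
    members <- tips[labels[tips] == tx]
    if (length(members) == 1L) {
      status <- "singleton"
    } else {
      mrca <- ape::getMRCA(phy, members)
      clade <- setdiff(phy$tip.label[tips_under(phy, mrca)], exclude)
      status <- if (setequal(clade, members)) "monophyletic"
                else "non-monophyletic"
    }
    data.frame(taxon = tx, n_tips = length(members), status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
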