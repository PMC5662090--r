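# Leave-one-out profile of a query against the reference matrix.
# Distances are kept on the proportion scale internally; thresholds cross the
# user interface on the percent scale and are converted here, once.
query_profile <- function(dm, labels, query) {
  i <- match(query, dm$ids)
  if (is.na(i)) stop("query not in distance matrix: ", query)
  drow <- dm$d[i, -i]
  others <- dm$ids[-i]
  defined <- !is.na(drow)
  if (!any(defined)) {
    return(list(dmin = Inf, tied = character(0), tie_class = NA_character_,
                has_match = any(labels[others] == labels[query])))
  }
  dmin <- min(drow[defined])
  tied <- others[defined & drow == dmin]
  same <- labels[tied] == labels[query]
  tie_class <- if (all(same)) "all" else if (any(same)) "mixed" else "none"
  list(dmin = dmin, tied = tied, tie_class = tie_class,
       has_match = any(labels[others] == labels[query]))
}

id_result <- function(query, method, rank, category, tied, dmin, threshold) {
  data.frame(query = query, method = method, rank = rank, category = category,
             nearest = paste(tied, collapse = ","),
             distance = if (is.finite(dmin)) dmin * 100 else NA_real_,
             threshold = if (is.null(threshold)) NA_real_ else threshold,
             stringsAsFactors = FALSE)
}

#' Nearest-neighbour identification
#'
#' Leave-one-out: the query is `"true"` when every reference individual tied
#' at the minimal defined distance belongs to the query's taxon at the given
#' rank, `"false"` otherwise. When no reference has a defined distance the
#' query is `"unidentifiable"`.
#'
#' @param query Individual id.
#' @param dm A `bc_dist` from [distance_matrix()].
#' @param info Taxon table (`individual_id`, `genus`, `species`).
#' @param rank `"species"` or `"genus"`.
#' @return One-row data frame (query, method, rank, category, nearest tied
#'   ids, nearest distance in percent, threshold used).
#' @export
nearest_neighbour <- function(query, dm, info, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  labels <- taxon_labels(info, rank)
  p <- query_profile(dm, labels, query)
  category <- if (is.na(p$tie_class)) "unidentifiable"
              else if (p$tie_class == "all") "true" else "false"
  id_result(query, "NN", rank, category, p$tied, p$dmin, NULL)
}

#' Best-close-match identification
#'
#' As [nearest_neighbour()], but the tied-nearest set only counts when it
#' lies within the distance threshold: beyond it the query is
#' `"no_identification"`; within it, all/mixed/none of the tied set matching
#' gives `"correct"`/`"ambiguous"`/`"incorrect"`.
#'
#' @inheritParams nearest_neighbour
#' @param threshold Distance threshold, percent scale ("within" is
#'   inclusive, distance <= threshold).
#' @export
best_close_match <- function(query, dm, info, rank = c("species", "genus"),
                             threshold) {
  rank <- match.arg(rank)
  labels <- taxon_labels(info, rank)
  p <- query_profile(dm, labels, query)
  category <- if (p$dmin * 100 > threshold) "no_identification"
              else switch(p$tie_class, all = "correct", mixed = "ambiguous",
                          none = "incorrect")
  id_result(query, "BCM", rank, category,
            if (category == "no_identification") character(0) else p$tied,
            p$dmin, threshold)
}

#' Threshold identification
#'
#' Classifies from the full set `W` of references within the threshold: `W`
#' empty gives `"no_identification"`; all of `W` matching the query's taxon
#' gives `"correct"`, none `"incorrect"`, a mixture `"ambiguous"`.
#'
#' @inheritParams best_close_match
#' @export
threshold_id <- function(query, dm, info, rank = c("species", "genus"),
                         threshold) {
  rank <- match.arg(rank)
  labels <- taxon_labels(info, rank)
  i <- match(query, dm$ids)
  if (is.na(i)) stop("query not in distance matrix: ", query)
  drow <- dm$d[i, -i]
  others <- dm$ids[-i]
  within <- !is.na(drow) & drow * 100 <= threshold
  W <- others[within]
  if (length(W) == 0L) {
    category <- "no_identification"
  } else {
    same <- taxon_labels(info, rank)[W] == taxon_labels(info, rank)[query]
    category <- if (all(same)) "correct" else if (any(same)) "ambiguous"
                else "incorrect"
  }
  dmin <- if (any(!is.na(drow))) min(drow, na.rm = TRUE) else Inf
  id_result(query, "TID", rank, category, W, dmin, threshold)
}

#' Identify every individual in a reference library
#'
#' Applies one method, leave-one-out, to every individual in the matrix.
#'
#' @inheritParams best_close_match
#' @param method `"NN"`, `"BCM"` or `"TID"`.
#' @param threshold Percent threshold (required for BCM and TID).
#' @return Data frame with one row per query.
#' @export
identify_all <- function(dm, info, rank = c("species", "genus"),
                         method = c("NN", "BCM", "TID"), threshold = NULL) {
  rank <- match.arg(rank)
  method <- match.arg(method)
  if (method != "NN" && is.null(threshold))
    stop(method, " requires a threshold")
  fn <- switch(method,
               NN  = function(q) nearest_neighbour(q, dm, info, rank),
               BCM = function(q) best_close_match(q, dm, info, rank, threshold),
               TID = function(q) threshold_id(q, dm, info, rank, threshold))
  do.call(rbind, lapply(dm$ids, fn))
}

default_grid <- function(rank) {
  if (rank == "genus") seq(0.001, 2.5, by = 0.05)
  else seq(0.0001, 2.5, by = 0.005)
}

#' Cumulative-error threshold optimization
#'
#' Scans a grid of candidate thresholds (percent scale); at each value every
#' individual is classified by best close match, false negatives are the
#' `"no_identification"` queries and false positives the `"incorrect"`
#' (plus, by default, `"ambiguous"`) ones. The optimum is the largest grid
#' value attaining the minimal cumulative error (FP + FN).
#'
#' Queries with no same-rank taxon match among the references cannot yield a
#' correct identification at any threshold; they are excluded from the error
#' counts (remove singletons beforehand) and reported in the result.
#'
#' @inheritParams best_close_match
#' @param grid Ascending percent thresholds; defaults to 0.001-2.5 by 0.05
#'   for genus rank and 0.0001-2.5 by 0.005 for species rank.
#' @param ambiguous_as_fp Count ambiguous identifications as false
#'   positives (default) or ignore them in the cumulative error.
#' @return A `threshold_profile`: data frame `profile` (threshold, fp, fn,
#'   cumulative), the `optimum`, and `excluded` query ids.
#' @export
optimize_threshold <- function(dm, info, rank = c("species", "genus"),
                               grid = NULL, ambiguous_as_fp = TRUE) {
  rank <- match.arg(rank)
  if (is.null(grid)) grid <- default_grid(rank)
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  labels <- taxon_labels(info, rank)
  profs <- lapply(dm$ids, function(q) query_profile(dm, labels, q))
  usable <- vapply(profs, `[[`, logical(1), "has_match")
  excluded <- dm$ids[!usable]
  profs <- profs[usable]
  dmin_pct <- vapply(profs, function(p) p$dmin * 100, numeric(1))
  cls <- vapply(profs, function(p)
    if (is.na(p$tie_class)) "none" else p$tie_class, character(1))
  fp_class <- if (ambiguous_as_fp) c("mixed", "none") else "none"
  fn <- vapply(grid, function(t) sum(dmin_pct > t), integer(1))
  fp <- vapply(grid, function(t) sum(dmin_pct <= t & cls %in% fp_class),
               integer(1))
  cum <- fp + fn
  optimum <- max(grid[cum == min(cum)])
  structure(list(profile = data.frame(threshold = grid, fp = fp, fn = fn,
                                      cumulative = cum),
                 optimum = optimum, rank = rank,
                 ambiguous_as_fp = ambiguous_as_fp,
                 excluded = excluded, n_queries = sum(usable)),
            class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  i <- match(x$optimum, x$profile$threshold)
  cat(sprintf(
    "threshold_profile (%s rank, %d queries): optimum %.4f%% (FP %d, FN %d)\n",
    x$rank, x$n_queries, x$optimum, x$profile$fp[i], x$profile$fn[i]))
  if (length(x$excluded))
    cat("  excluded (no same-rank match):", length(x$excluded), "queries\n")
  invisible(x)
}

#' Identification success table
#'
#' Per-category counts and percentages for a set of identification results
#' sharing one method and rank.
#'
#' @param results Data frame from [identify_all()] (or rbind of single-query
#'   results).
#' @return Data frame with category, n and percent; the denominator is
#'   recorded in the `denominator` attribute.
#' @export
success_table <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("no results to summarize")
  if (length(unique(results$method)) != 1L ||
      length(unique(results$rank)) != 1L)
    stop("results must share one method and rank")
  cats <- switch(results$method[1L],
                 NN = c("true", "false", "unidentifiable"),
                 c("correct", "ambiguous", "no_identification", "incorrect"))
  n <- vapply(cats, function(cc) sum(results$category == cc), integer(1))
  out <- data.frame(category = cats, n = unname(n),
                    percent = unname(100 * n / nrow(results)))
  attr(out, "denominator") <- nrow(results)
  attr(out, "method") <- results$method[1L]
  attr(out, "rank") <- results$rank[1L]
  out
}
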