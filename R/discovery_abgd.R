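#' Configuration for barcode-gap discovery
#'
#' Priors on the maximum intraspecific divergence are scanned on a
#' log-spaced grid; the relative gap width `X` sets how wide a gap in the
#' ranked pairwise distances must be, relative to the divergence level at
#' which it occurs, to count as a barcode gap.
#'
#' @param prior_min,prior_max Prior intraspecific divergence range
#'   (proportion scale).
#' @param n_steps Number of log-spaced priors.
#' @param relative_gap_width Gap width multiplier `X`.
#' @param n_bins Bins used for the reported distance histogram.
#' @param ts_tv_ratio Optional transition/transversion ratio, recorded as
#'   provenance (distances themselves use the per-pair K80 estimate).
#' @export
abgd_config <- function(prior_min = 0.001, prior_max = 0.100, n_steps = 20,
                        relative_gap_width = 1.0, n_bins = 20,
                        ts_tv_ratio = NULL) {
  stopifnot(prior_min > 0, prior_min < prior_max, n_steps >= 2, n_bins >= 2,
            relative_gap_width > 0)
  list(prior_min = prior_min, prior_max = prior_max, n_steps = n_steps,
       relative_gap_width = relative_gap_width, n_bins = n_bins,
       ts_tv_ratio = ts_tv_ratio)
}

#' Find a barcode gap in ranked pairwise distances
#'
#' Scans consecutive gaps `g_i = d[i+1] - d[i]` of the ascending distances.
#' A gap qualifies when it ends above the prior (`d[i+1] > P`, so that gaps
#' wholly inside the presumed intraspecific range are ignored) and its width
#' exceeds `X` times the divergence level `d[i]` at which it starts. The
#' first qualifying gap wins and the threshold is its midpoint.
#'
#' @param distances Numeric vector of pairwise distances (proportion scale),
#'   any order.
#' @param prior Prior maximum intraspecific divergence `P`.
#' @param gap_width Relative gap width `X`.
#' @return The gap-midpoint threshold, or `NA` when no qualifying gap
#'   exists.
#' @export
find_gap <- function(distances, prior, gap_width = 1.0) {
  d <- sort(distances[!is.na(distances)])
  if (length(d) < 2L) return(NA_real_)
  for (i in seq_len(length(d) - 1L)) {
    g <- d[i + 1L] - d[i]
    if (d[i + 1L] > prior && g > gap_width * d[i])
      return((d[i] + d[i + 1L]) / 2)
  }
  NA_real_
}

# single-linkage components at a distance threshold (masked = disconnected)
single_linkage <- function(d, threshold) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- k
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

abgd_split <- function(d, ids, prior, gap_width) {
  if (length(ids) < 2L) return(list(ids))
  sub <- d[ids, ids, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  thr <- find_gap(vals, prior, gap_width)
  if (is.na(thr)) return(list(ids))
  comp <- single_linkage(sub, thr)
  if (length(unique(comp)) == 1L) return(list(ids))
  groups <- split(ids, comp)
  out <- list()
  for (g in groups) out <- c(out, abgd_split(d, g, prior, gap_width))
  out
}

#' Barcode-gap partitioning over a grid of priors
#'
#' For each prior on the log-spaced grid, partitions the individuals by
#' single-linkage clustering at the detected gap threshold and recurses
#' within each group (with the same prior) until no further gap is found.
#' Masked pairwise distances are treated as beyond any threshold.
#'
#' @param dm A `bc_dist` from [distance_matrix()].
#' @param config An [abgd_config()].
#' @return An `abgd_result`: `priors`, list of [bc_partition()]s (one per
#'   prior), per-prior entity counts, top-level thresholds, the distance
#'   histogram (with `n_bins` bins), and the config.
#' @export
abgd_partition <- function(dm, config = abgd_config()) {
  if (length(dm$ids) < 2L) stop("need at least two individuals")
  priors <- exp(seq(log(config$prior_min), log(config$prior_max),
                    length.out = config$n_steps))
  d <- dm$d
  parts <- vector("list", length(priors))
  thr <- numeric(length(priors))
  for (k in seq_along(priors)) {
    groups <- abgd_split(d, dm$ids, priors[k], config$relative_gap_width)
    memb <- setNames(rep(NA_character_, length(dm$ids)), dm$ids)
    for (i in seq_along(groups))
      memb[groups[[i]]] <- sprintf("E%02d", i)
    parts[[k]] <- bc_partition(memb)
    thr[k] <- find_gap(d[upper.tri(d)], priors[k], config$relative_gap_width)
  }
  vals <- d[upper.tri(d)]
  vals <- vals[!is.na(vals)]
  hist_breaks <- seq(0, max(vals, 1e-6), length.out = config$n_bins + 1L)
  histo <- graphics::hist(vals, breaks = hist_breaks, plot = FALSE)
  structure(list(priors = priors, partitions = parts,
                 n_entities = vapply(parts, n_entities, integer(1)),
                 thresholds = thr,
                 histogram = data.frame(mid = histo$mids, count = histo$counts),
                 config = config),
            class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  cat("abgd_result over", length(x$priors), "priors (X =",
      x$config$relative_gap_width, ")\n")
  print(data.frame(prior = signif(x$priors, 3), entities = x$n_entities))
  invisible(x)
}

#' Select the headline partition from a prior scan
#'
#' Returns the partition at the prior closest to a reference intraspecific
#' divergence, conventionally the optimal threshold estimated for
#' distance-based identification.
#'
#' @param result An `abgd_result`.
#' @param threshold_pct Reference threshold on the percent scale.
#' @return A [bc_partition()]; the chosen prior is in attribute `prior`.
#' @export
select_partition <- function(result, threshold_pct) {
  k <- which.min(abs(result$priors - threshold_pct / 100))
  out <- result$partitions[[k]]
  attr(out, "prior") <- result$priors[k]
  out
}
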