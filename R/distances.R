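# Base encoding for distance computation: A=1, C=2, G=3, T=4, everything
# else (gaps, N, IUPAC ambiguity codes) 0 = not comparable. With this coding
# two differing bases are a transition iff |a-b| == 2 (A<->G, C<->T).
encode_bases <- function(seqs) {
  key <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(0L, nrow = length(seqs), ncol = nchar(seqs[[1L]]),
              dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1L]]
    v <- key[ch]
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

k80_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

k80_pair <- function(a, b) {
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) return(c(d = NA_real_, P = NA_real_, Q = NA_real_, n = 0))
  da <- a[ok]; db <- b[ok]
  diff <- da != db
  ts <- sum(diff & abs(da - db) == 2L)
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  c(d = k80_from_pq(P, Q), P = P, Q = Q, n = n)
}

#' Kimura (1980) distance between two aligned sequences
#'
#' Sites where either residue is not an unambiguous base (`A`,`C`,`G`,`T`)
#' are excluded pairwise; with transition proportion `P` and transversion
#' proportion `Q` over the comparable sites, the distance is
#' `-log(1 - 2P - Q)/2 - log(1 - 2Q)/4` substitutions per site.
#'
#' @param seq_a,seq_b Equal-length residue strings (IUPAC alphabet).
#' @return The K80 distance (proportion scale), or `NA` when no site is
#'   comparable or the distance is saturated (a log argument is
#'   non-positive).
#' @export
k80_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequence length mismatch")
  m <- encode_bases(c(a = toupper(seq_a), b = toupper(seq_b)))
  unname(k80_pair(m[1L, ], m[2L, ])[["d"]])
}

#' Pairwise K80 distance matrix for an alignment
#'
#' Computes all unordered pairs; pairs with no comparable sites or a
#' saturated distance are left `NA` (masked) and reported in the
#' `masked_pairs` attribute.
#'
#' @param aln A [bc_alignment()] with at least two records.
#' @return A `bc_dist` object: list with `ids` and symmetric matrix `d`
#'   (proportion scale, zero diagonal, `NA` = masked).
#' @export
distance_matrix <- function(aln) {
  n <- length(aln$seq)
  if (n < 2L) stop("need at least two sequences")
  enc <- encode_bases(aln$seq)
  ids <- names(aln$seq)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  masked <- character(0)
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in (i + 1L):n) {
      dij <- k80_pair(ai, enc[j, ])[["d"]]
      d[i, j] <- d[j, i] <- dij
      if (is.na(dij)) masked <- c(masked, paste(ids[i], ids[j], sep = "~"))
    }
  }
  structure(list(ids = ids, d = d, masked_pairs = masked), class = "bc_dist")
}

#' @export
print.bc_dist <- function(x, ...) {
  cat(sprintf("bc_dist: %d individuals, %d masked pair(s)\n",
              length(x$ids), length(x$masked_pairs)))
  invisible(x)
}

#' Remove singleton taxa from an alignment
#'
#' Taxa represented by a single individual cannot be matched to a
#' conspecific (or congeneric) reference and are removed before
#' distance-based identification.
#'
#' @param aln A [bc_alignment()].
#' @param rank Rank at which representation is counted.
#' @return The filtered [bc_alignment()]; removed ids are recorded in the
#'   `removed` attribute.
#' @export
remove_singletons <- function(aln, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  lab <- taxon_labels(aln$info, rank)
  counts <- table(lab)
  keep <- lab %in% names(counts)[counts >= 2L]
  if (!any(keep)) stop("no taxon has two or more individuals")
  out <- bc_alignment(aln$seq[keep], aln$info$genus[keep],
                      aln$info$species[keep], aln$marker)
  attr(out, "removed") <- aln$info$individual_id[!keep]
  out
}

#' Intra- and inter-specific distance summary per genus
#'
#' Splits the within-genus pairwise distances of each genus into
#' intraspecific (same species) and interspecific (different species, same
#' genus) sets, the classical view of the barcode gap. Masked pairs are
#' excluded; between-genus pairs are not summarized.
#'
#' @param dm A `bc_dist` from [distance_matrix()].
#' @param info Taxon table (`individual_id`, `genus`, `species`).
#' @param percent Report on the percent scale (default) or proportion scale.
#' @return A `bc_dist_summary`: per-genus lists of intra/inter distances and
#'   their means, plus overall means pooled over genera.
#' @export
summarize_distances <- function(dm, info, percent = TRUE) {
  scale <- if (percent) 100 else 1
  info <- info[match(dm$ids, info$individual_id), ]
  genus <- info$genus
  species <- paste(info$genus, info$species)
  per_genus <- list()
  for (g in unique(genus)) {
    idx <- which(genus == g)
    if (length(idx) < 2L) next
    intra <- numeric(0); inter <- numeric(0)
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        v <- dm$d[i, j]
        if (is.na(v)) next
        if (species[i] == species[j]) intra <- c(intra, v)
        else inter <- c(inter, v)
      }
    }
    per_genus[[g]] <- list(
      intra = intra * scale, inter = inter * scale,
      mean_intra = if (length(intra)) mean(intra) * scale else NA_real_,
      mean_inter = if (length(inter)) mean(inter) * scale else NA_real_)
  }
  if (length(per_genus) == 0L) stop("no genus with two or more individuals")
  all_intra <- unlist(lapply(per_genus, `[[`, "intra"), use.names = FALSE)
  all_inter <- unlist(lapply(per_genus, `[[`, "inter"), use.names = FALSE)
  structure(list(per_genus = per_genus,
                 mean_intra = if (length(all_intra)) mean(all_intra) else NA_real_,
                 mean_inter = if (length(all_inter)) mean(all_inter) else NA_real_,
                 percent = percent),
            class = "bc_dist_summary")
}

#' @export
print.bc_dist_summary <- function(x, ...) {
  unit <- if (x$percent) "%" else ""
  cat(sprintf("Distance summary (%d genera): mean intra %.3f%s, mean inter %.3f%s\n",
              length(x$per_genus), x$mean_intra, unit, x$mean_inter, unit))
  invisible(x)
}

#' Export a distance matrix as TSV
#'
#' Square matrix with id header row and column; masked pairs written as NA.
#'
#' @param dm A `bc_dist`.
#' @param path Output file.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
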