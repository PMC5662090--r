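#' Partition of individuals into genetic entities
#'
#' @param membership Named character (or factor) vector mapping individual
#'   id to entity label.
#' @return A `bc_partition`: list with `membership` (named character) and
#'   `groups` (named list of id vectors).
#' @export
bc_partition <- function(membership) {
  ids <- names(membership)
  if (is.null(ids) || anyDuplicated(ids) > 0L)
    stop("membership must be named by unique individual ids")
  membership <- setNames(as.character(membership), ids)
  groups <- split(ids, membership)
  structure(list(membership = membership, groups = groups),
            class = "bc_partition")
}

#' @export
print.bc_partition <- function(x, ...) {
  cat(sprintf("bc_partition: %d individuals in %d entities\n",
              length(x$membership), length(x$groups)))
  invisible(x)
}

#' Number of entities in a partition
#' @param partition A [bc_partition()].
#' @export
n_entities <- function(partition) length(partition$groups)

# canonical key for an entity (order-free tip set)
entity_key <- function(ids) paste(sort(ids), collapse = "|")

#' Write a partition as TSV
#' @param partition A [bc_partition()].
#' @param path Output file.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(individual_id = names(partition$membership),
                   entity = unname(partition$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
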