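#' Score genetic entities against named species
#'
#' Each named species is placed in exactly one category by how the entities
#' of a partition cut across it: `"+"` (congruent) when one entity equals
#' the species' individuals exactly; `"L"` (lumped) when its single entity
#' also contains other species' individuals; `"S"` (split) when it spans
#' several entities, all of them pure; `"L/S"` when it spans several
#' entities of which at least one also contains allospecific individuals.
#' A singleton species is `"+"` when its individual is alone in an entity
#' and `"L"` otherwise.
#'
#' @param partition A [bc_partition()] of the analysed individuals.
#' @param info Taxon table (`individual_id`, `genus`, `species`) covering
#'   every individual in the partition.
#' @return Data frame of `congruence_records`: species, n_individuals,
#'   category, entities (comma-separated labels). Species delimited into a
#'   shared entity carry the same `shared_group` code (others `NA`),
#'   mirroring the shared-superscript convention of congruence tables.
#' @export
classify_congruence <- function(partition, info) {
  ids <- names(partition$membership)
  species <- taxon_labels(info, "species")
  if (any(!ids %in% names(species)))
    stop("unlabeled individual(s): ",
         paste(setdiff(ids, names(species)), collapse = ", "))
  sp_of <- species[ids]
  ent_of <- partition$membership[ids]
  rows <- lapply(sort(unique(sp_of)), function(s) {
    I_s <- ids[sp_of == s]
    E_s <- unique(ent_of[I_s])
    is_split <- length(E_s) > 1L
    is_lumped <- any(vapply(E_s, function(e)
      length(setdiff(partition$groups[[e]], I_s)) > 0L, logical(1)))
    category <- if (!is_split && !is_lumped) "+"
                else if (!is_split) "L"
                else if (!is_lumped) "S" else "L/S"
    data.frame(species = s, n_individuals = length(I_s), category = category,
               entities = paste(sort(E_s), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # species sharing an entity get a common group code
  lumped_entities <- names(partition$groups)[vapply(partition$groups,
    function(g) length(unique(sp_of[g])) > 1L, logical(1))]
  out$shared_group <- NA_character_
  for (k in seq_along(lumped_entities)) {
    e <- lumped_entities[k]
    touched <- unique(sp_of[partition$groups[[e]]])
    hit <- out$species %in% touched
    code <- letters[(k - 1L) %% 26L + 1L]
    out$shared_group[hit] <- ifelse(is.na(out$shared_group[hit]), code,
                                    paste0(out$shared_group[hit], code))
  }
  class(out) <- c("congruence_records", class(out))
  out
}

#' Summarize congruence categories
#'
#' @param records Output of [classify_congruence()].
#' @return Data frame of counts and percentages per category (over species
#'   analysed); percentages sum to 100 up to rounding.
#' @export
congruence_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("no congruence records")
  cats <- c("+", "L", "S", "L/S")
  n <- vapply(cats, function(cc) sum(records$category == cc), integer(1))
  data.frame(category = cats, n = unname(n),
             percent = unname(100 * n / nrow(records)))
}
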