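#' @importFrom stats runif rpois setNames
#' @importFrom utils write.table read.table
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Construct a species-labelled alignment
#'
#' An alignment is the unit of a barcode reference library: a set of aligned
#' sequences for one marker (or a declared concatenation of markers), each
#' carrying the genus, species and individual identifier of the voucher it
#' came from.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   individual ids). All must have equal length. Residues are uppercased and
#'   validated against the IUPAC nucleotide alphabet (including `N`, `-`
#'   and `?`).
#' @param genus,species Character vectors parallel to `seqs`.
#' @param marker Marker name, e.g. `"ITS"`, or a concatenation label such as
#'   `"rbcL+matK"`.
#' @return An object of class `bc_alignment` with elements `seq` (named
#'   character vector), `info` (data frame with columns `individual_id`,
#'   `genus`, `species`), `marker` and `length`.
#' @export
bc_alignment <- function(seqs, genus, species, marker) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) > 0L)
    stop("individual ids must be present and unique")
  if (length(seqs) == 0L) stop("alignment has no records")
  if (length(genus) != length(seqs) || length(species) != length(seqs))
    stop("genus/species must be parallel to sequences")
  if (any(!nzchar(genus)) || any(!nzchar(species)))
    stop("genus and species labels must be non-empty")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("empty sequence for: ", ids[lens == 0L][1L])
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths: sequences are not aligned")
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% IUPAC_CODES),
                logical(1))
  if (any(bad)) {
    chars <- setdiff(unique(unlist(strsplit(seqs[bad][1L], ""))), IUPAC_CODES)
    stop("non-IUPAC character(s) ", paste(chars, collapse = ","),
         " in record ", ids[bad][1L])
  }
  structure(list(
    seq    = seqs,
    info   = data.frame(individual_id = ids, genus = genus, species = species,
                        stringsAsFactors = FALSE),
    marker = marker,
    length = unname(lens[1L])
  ), class = "bc_alignment")
}

#' @export
print.bc_alignment <- function(x, ...) {
  cat(sprintf("bc_alignment: %d sequences x %d columns, marker %s\n",
              length(x$seq), x$length, x$marker))
  cat(sprintf("  %d genera, %d species\n", length(unique(x$info$genus)),
              length(unique(paste(x$info$genus, x$info$species)))))
  invisible(x)
}

#' Header label scheme for FASTA records
#'
#' The default scheme expects headers of the form `Genus_species|ID`, i.e.
#' a binomial with genus and species epithet separated by `species_sep`,
#' followed by `id_sep` and the unique individual identifier.
#'
#' @param species_sep Separator between genus and species epithet.
#' @param id_sep Separator between the binomial and the individual id.
#' @export
label_scheme <- function(species_sep = "_", id_sep = "|") {
  list(species_sep = species_sep, id_sep = id_sep)
}

parse_header <- function(header, scheme) {
  id_pos <- regexpr(scheme$id_sep, header, fixed = TRUE)
  if (id_pos < 0L)
    stop("cannot parse FASTA header (no '", scheme$id_sep, "'): ", header)
  binom <- substr(header, 1L, id_pos - 1L)
  id <- substr(header, id_pos + nchar(scheme$id_sep), nchar(header))
  sp_pos <- regexpr(scheme$species_sep, binom, fixed = TRUE)
  if (sp_pos < 0L)
    stop("cannot parse FASTA header (no '", scheme$species_sep, "'): ", header)
  genus <- substr(binom, 1L, sp_pos - 1L)
  species <- substr(binom, sp_pos + nchar(scheme$species_sep), nchar(binom))
  if (!nzchar(genus) || !nzchar(species) || !nzchar(id))
    stop("cannot parse FASTA header (empty field): ", header)
  list(genus = genus, species = species, id = id)
}

#' Read a species-labelled alignment from FASTA
#'
#' @param path FASTA file of pre-aligned sequences.
#' @param marker Marker name to record; defaults to the file name without
#'   extension.
#' @param scheme Header [label_scheme()].
#' @return A [bc_alignment()].
#' @export
read_alignment <- function(path, marker = NULL, scheme = label_scheme()) {
  if (is.null(marker))
    marker <- sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = TRUE)
  headers <- vapply(recs, function(r) attr(r, "name"), character(1))
  parsed <- lapply(headers, parse_header, scheme = scheme)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(parsed, `[[`, character(1), "id")
  bc_alignment(seqs,
               genus   = vapply(parsed, `[[`, character(1), "genus"),
               species = vapply(parsed, `[[`, character(1), "species"),
               marker  = marker)
}

#' Write an alignment to FASTA
#'
#' Headers are rebuilt under the given [label_scheme()], so that
#' `read_alignment(write_alignment(x))` round-trips records and order.
#'
#' @param aln A [bc_alignment()].
#' @param path Output file.
#' @param scheme Header [label_scheme()].
#' @export
write_alignment <- function(aln, path, scheme = label_scheme()) {
  headers <- paste0(aln$info$genus, scheme$species_sep, aln$info$species,
                    scheme$id_sep, aln$info$individual_id)
  seqinr::write.fasta(as.list(unname(aln$seq)), names = headers,
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Concatenate marker alignments
#'
#' Builds a multi-locus alignment over the union of individuals. Where an
#' individual lacks a marker, that marker's block is filled with `N`
#' (missing), following the standard barcode-library convention for
#' concatenated datasets.
#'
#' @param alignments List of [bc_alignment()] objects with distinct markers.
#' @return A [bc_alignment()] whose marker is the `+`-joined marker names.
#' @export
concatenate <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  markers <- vapply(alignments, `[[`, character(1), "marker")
  if (anyDuplicated(markers) > 0L) stop("duplicate markers in concatenation")
  info_all <- do.call(rbind, lapply(alignments, `[[`, "info"))
  # same individual must carry one taxon label across markers
  by_id <- split(info_all[c("genus", "species")], info_all$individual_id)
  conflict <- vapply(by_id, function(d) nrow(unique(d)) > 1L, logical(1))
  if (any(conflict))
    stop("conflicting taxon labels for individual(s): ",
         paste(names(by_id)[conflict], collapse = ", "))
  ids <- unique(info_all$individual_id)
  blocks <- vapply(alignments, function(a) {
    filler <- strrep("N", a$length)
    out <- setNames(rep(filler, length(ids)), ids)
    out[names(a$seq)] <- a$seq
    out
  }, character(length(ids)))
  if (length(ids) == 1L) blocks <- matrix(blocks, nrow = 1L,
                                          dimnames = list(ids, NULL))
  seqs <- apply(blocks, 1L, paste0, collapse = "")
  first <- vapply(by_id[ids], function(d) c(d$genus[1L], d$species[1L]),
                  character(2))
  bc_alignment(setNames(seqs, ids), genus = first[1L, ], species = first[2L, ],
               marker = paste(markers, collapse = "+"))
}

#' Taxon labels at a rank
#'
#' At species rank the label is the full binomial (genus + epithet), so that
#' identically named epithets in different genera are distinct taxa.
#'
#' @param info Data frame with `individual_id`, `genus`, `species` columns
#'   (e.g. the `info` element of a [bc_alignment()]).
#' @param rank `"species"` or `"genus"`.
#' @return Named character vector mapping individual id to taxon label.
#' @export
taxon_labels <- function(info, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  lab <- if (rank == "genus") info$genus else paste(info$genus, info$species)
  setNames(lab, info$individual_id)
}
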