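# tiny in-code fixtures
toy_alignment <- function(seqs, species, genus = "Poa", marker = "ITS") {
  bc_alignment(seqs, genus = rep_len(genus, length(seqs)),
               species = species, marker = marker)
}

write_fasta_text <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

read_tree_text <- function(text, type = "bootstrap", sep = "/") {
  f <- tempfile(fileext = ".nwk")
  writeLines(text, f)
  read_support_tree(f, type, sep)
}
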