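# Reference genome access. Sequences are held as plain uppercase
# character strings; lookups are 1-based inclusive.

#' Load a reference genome from FASTA
#'
#' @param path FASTA file.
#' @param assembly Assembly label to tag the genome with (e.g. "GRCh38"
#'   or a fixture label).
#' @return Object of class `ref_genome`: list with `sequences` (named
#'   uppercase character vector) and `assembly`.
#' @export
read_genome_fasta <- function(path, assembly) {
  seqs <- Biostrings::readDNAStringSet(path)
  s <- toupper(as.character(seqs))
  names(s) <- canon_chrom(sub("\\s.*$", "", names(seqs)))
  ref_genome(s, assembly)
}

#' Construct a reference genome from in-memory sequences
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param assembly Assembly label.
#' @return A `ref_genome`.
#' @export
ref_genome <- function(sequences, assembly) {
  sequences <- toupper(sequences)
  names(sequences) <- canon_chrom(names(sequences))
  structure(list(sequences = sequences, assembly = assembly),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Reference genome [", x$assembly, "]: ",
      length(x$sequences), " sequence(s), ",
      sum(nchar(x$sequences)), " bp\n", sep = "")
  invisible(x)
}

#' Extract reference sequence (1-based inclusive)
#'
#' @param genome A `ref_genome`.
#' @param chrom Chromosome name ("chr" prefix tolerated).
#' @param start,end 1-based inclusive bounds.
#' @return Uppercase sequence string.
#' @export
ref_seq <- function(genome, chrom, start, end) {
  chrom <- canon_chrom(chrom)
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  if (start < 1L || end > nchar(s) || start > end + 1L)
    stop("reference access out of range: ", chrom, ":", start, "-", end)
  if (start > end) return("")
  substr(s, start, end)
}
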