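#' Construct a genome sequence object
#'
#' A single-replicon nucleotide sequence restricted to the unambiguous
#' alphabet ACGT. Phage genomes are single replicons here; multi-contig
#' assemblies are out of scope.
#'
#' @param seq Character scalar over \{A, C, G, T\} (lower case accepted and
#'   upper-cased).
#' @param id Sequence identifier.
#' @param circular Logical; whether the replicon is circular. ORFs spanning
#'   the origin are only reported when this is `TRUE` (see [find_orfs()]).
#' @return An object of class `genome_sequence`: a list with elements `id`,
#'   `seq` and `circular`.
#' @examples
#' g <- genome_sequence("ATGAAATAA")
#' nchar(g$seq)
#' @export
genome_sequence <- function(seq, id = "genome", circular = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("'seq' must be a single character string")
  }
  seq <- toupper(seq)
  if (nchar(seq) < 1L) {
    stop("genome sequence is empty (length must be >= 1)")
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop(sprintf(
      "non-ACGT character '%s' at position %d (ambiguity codes are not supported)",
      substr(seq, bad, bad), bad
    ))
  }
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular)),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf(
    "<genome_sequence> %s: %d bp (%s)\n",
    x$id, nchar(x$seq), if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome A [genome_sequence()].
#' @return Integer length.
#' @export
genome_length <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  nchar(genome$seq)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over ACGT.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Generate a uniform random genome
#'
#' Every base is drawn i.i.d. uniformly from \{A, C, G, T\}, emulating a
#' maximally non-coding sequence used to probe false-positive susceptibility.
#' The same seed always yields the same sequence; the caller's RNG state is
#' left untouched.
#'
#' @param length_bp Positive integer length.
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return A [genome_sequence()].
#' @examples
#' g <- random_genome(400, seed = 17)
#' identical(g$seq, random_genome(400, seed = 17)$seq)
#' @export
random_genome <- function(length_bp, seed, id = "random") {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1) {
    stop("'length_bp' must be a positive integer")
  }
  length_bp <- as.integer(length_bp)
  bases <- withr::with_seed(
    as.integer(seed),
    sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  )
  genome_sequence(paste(bases, collapse = ""), id = id)
}

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @param circular Logical, stored on the returned object.
#' @return A [genome_sequence()].
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  if (length(set) > 1L) {
    stop(
      "FASTA file '", path, "' contains ", length(set),
      " records; a single replicon is required"
    )
  }
  id <- sub("\\s.*$", "", names(set)[1L])
  genome_sequence(as.character(set[[1L]]), id = id, circular = circular)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_sequence"))
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream name,
# so each mock-evidence generator draws from its own independent stream.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}
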