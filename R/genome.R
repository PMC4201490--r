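#' Circular genome object
#'
#' Baculovirus genomes are covalently closed circles; every coordinate
#' operation in this package is therefore modular. A `circular_genome` holds
#' an uppercase DNA sequence over {A,C,G,T,N} together with a name, and all
#' user-facing coordinates are 1-based and inclusive on both ends. Spans that
#' cross the origin are written with `start > end`; that is the only dialect
#' used for origin-spanning features.
#'
#' @param sequence DNA string (case-insensitive; N allowed).
#' @param name label for the genome.
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence` and `length`.
#' @export
circular_genome <- function(sequence, name = "genome") {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L)
    stop("genome sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp\n", x$name,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA or GenBank flat file
#'
#' The file must contain exactly one record; the sequence is uppercased on
#' input. GenBank flat files are read from their ORIGIN block.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return A [circular_genome()].
#' @export
read_genome <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genome file: ", path)
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("no records in ", path)
    if (length(set) > 1L) stop("multiple records in ", path,
                               "; a single-record file is required")
    nm <- sub("\\s.*$", "", names(set)[1L])
    return(circular_genome(as.character(set[[1L]]), name = nm))
  }
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines)
  nm <- if (length(loc)) strsplit(trimws(lines[loc[1L]]), "\\s+")[[1L]][2L]
        else "genome"
  if (length(loc) > 1L) stop("multiple records in ", path,
                             "; a single-record file is required")
  ori <- grep("^ORIGIN", lines)
  if (length(ori) != 1L) stop("no ORIGIN block found in ", path)
  stopat <- grep("^//", lines)
  stopat <- stopat[stopat > ori][1L]
  if (is.na(stopat)) stopat <- length(lines) + 1L
  body <- lines[seq(ori + 1L, stopat - 1L)]
  seqtxt <- gsub("[0-9[:space:]/]", "", paste(body, collapse = ""))
  if (nchar(seqtxt) == 0L) stop("zero-length record in ", path)
  circular_genome(seqtxt, name = nm)
}

#' Base composition of a genome
#'
#' A+T content is the quantity conventionally reported for baculovirus
#' genomes. `N` bases are counted but excluded from the A+T denominator.
#'
#' @param genome a [circular_genome()].
#' @return list with integer counts `a_count`, `c_count`, `g_count`,
#'   `t_count`, `n_count` and `at_percent` (two decimals).
#' @export
genome_composition <- function(genome) {
  stopifnot(inherits(genome, "circular_genome"))
  f <- Biostrings::letterFrequency(Biostrings::DNAString(genome$sequence),
                                   c("A", "C", "G", "T", "N"))
  f <- as.integer(f)
  denom <- genome$length - f[5L]
  list(a_count = f[1L], c_count = f[2L], g_count = f[3L], t_count = f[4L],
       n_count = f[5L],
       at_percent = round(100 * (f[1L] + f[4L]) / denom, 2))
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string.
#' @return the reverse complement, as a plain string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a (possibly origin-spanning) subsequence
#'
#' When `start <= end` the inclusive span `start..end` is returned; when
#' `start > end` the span runs through the origin. `strand = "-"` returns the
#' reverse complement of the plus-strand span.
#'
#' @param genome a [circular_genome()].
#' @param start,end 1-based inclusive positions.
#' @param strand `"+"` or `"-"`.
#' @return DNA string.
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (start < 1L || start > L || end < 1L || end > L)
    stop("positions out of range [1, ", L, "]")
  s <- if (start <= end) substr(genome$sequence, start, end)
       else paste0(substr(genome$sequence, start, L),
                   substr(genome$sequence, 1L, end))
  if (strand == "-") revcomp(s) else s
}

#' Rotate a circular genome so a chosen position becomes base 1
#'
#' Annotation convention for nucleopolyhedroviruses places the coordinate
#' origin at the adenine of the polyhedrin start codon; this rotates (and,
#' for `strand = "-"`, first reverse-complements) the genome so the given
#' position becomes base 1. The rotation offset is recorded in attribute
#' `"offset"` so the operation can be inverted.
#'
#' @param genome a [circular_genome()].
#' @param position 1-based position that becomes the new base 1.
#' @param strand `"+"` keeps the strand; `"-"` reverse-complements first (the
#'   position refers to the original coordinates).
#' @return A rotated [circular_genome()].
#' @export
rotate_to_zero <- function(genome, position, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (position < 1L || position > L) stop("position out of range [1, ", L, "]")
  seqtxt <- genome$sequence
  pos <- position
  if (strand == "-") {
    seqtxt <- revcomp(seqtxt)
    pos <- L - position + 1L
  }
  rotated <- if (pos == 1L) seqtxt
             else paste0(substr(seqtxt, pos, L), substr(seqtxt, 1L, pos - 1L))
  out <- circular_genome(rotated, name = genome$name)
  attr(out, "offset") <- pos - 1L
  out
}

# modular span length of an inclusive arc (start > end wraps the origin)
arc_span <- function(start, end, L) {
  ifelse(start <= end, end - start + 1L, L - start + 1L + end)
}

# decompose an arc into 1 or 2 linear intervals on [1, L]
arc_pieces <- function(start, end, L) {
  if (start <= end) list(c(start, end))
  else list(c(start, L), c(1L, end))
}

# length of the intersection of two circular arcs
arc_overlap <- function(s1, e1, s2, e2, L) {
  p1 <- arc_pieces(s1, e1, L); p2 <- arc_pieces(s2, e2, L)
  tot <- 0L
  for (a in p1) for (b in p2)
    tot <- tot + max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
  tot
}
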