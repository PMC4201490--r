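#' Upstream window of an ORF
#'
#' Returns the `window_len` bases immediately 5' of the start codon on the
#' ORF's coding strand, excluding the start codon itself; the window wraps
#' the origin when needed. Baculovirus promoter scans conventionally use the
#' 150 bp upstream of each start codon.
#'
#' @param genome a [circular_genome()].
#' @param start,end ORF span bounds (plus-strand coordinates, `start > end`
#'   for origin-spanning ORFs).
#' @param strand ORF reading direction; for `"-"` the start codon sits at the
#'   high-coordinate end of the span.
#' @param window_len window width in bases (must be smaller than the genome).
#' @return DNA string in coding-strand orientation.
#' @export
upstream_window <- function(genome, start, end, strand = "+",
                            window_len = 150) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (window_len >= L) stop("window_len must be smaller than the genome")
  if (strand == "+") {
    s <- (start - window_len - 1L) %% L + 1L
    e <- (start - 2L) %% L + 1L
    genome_subseq(genome, s, e, "+")
  } else {
    s <- end %% L + 1L
    e <- (end + window_len - 1L) %% L + 1L
    genome_subseq(genome, s, e, "-")
  }
}

iupac_check <- function(pattern) {
  if (grepl("[^ACGTRYSWKMBDHVN]", pattern))
    stop("invalid IUPAC character in pattern: ", pattern)
  pattern
}

# all start offsets of an IUPAC pattern in a plain ACGT(N) window;
# pattern ambiguity codes are expanded, subject letters are literal
iupac_match_starts <- function(pattern, window) {
  iupac_check(pattern)
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(window),
                                fixed = c(pattern = FALSE, subject = TRUE))
  Biostrings::start(m)
}

#' Classify a promoter window as early, late, both or none
#'
#' The early baculovirus promoter is a TATA element with a CAKT
#' transcription-start motif 20-40 bp downstream; the late motif is DTAAG
#' (IUPAC: K = G/T, D = A/G/T). The spacer is counted from the base after the
#' last base of the TATA element to the first base of the CAKT match, and
#' both motifs must lie wholly inside the window. All motif occurrences are
#' recorded; classification requires at least one.
#'
#' @param window DNA string, coding-strand orientation.
#' @param early_pattern IUPAC pattern for the TATA element.
#' @param tss_pattern IUPAC pattern for the transcription-start motif.
#' @param spacer_min,spacer_max allowed spacer range in bases, inclusive.
#' @param late_pattern IUPAC pattern for the late motif.
#' @return list with `early_hits` (data.frame `tata_start`, `cakt_start`),
#'   `late_hits` (integer offsets) and `promoter_class` in
#'   `{"E","L","EL","none"}`. Offsets are 1-based within the window.
#' @export
classify_promoter <- function(window, early_pattern = "TATAA",
                              tss_pattern = "CAKT", spacer_min = 20,
                              spacer_max = 40, late_pattern = "DTAAG") {
  if (!is.character(window) || nchar(window) == 0L)
    stop("window must be a non-empty DNA string")
  if (grepl("[^ACGTN]", window))
    stop("invalid IUPAC character in window")
  tata <- iupac_match_starts(early_pattern, window)
  cakt <- iupac_match_starts(tss_pattern, window)
  late <- iupac_match_starts(late_pattern, window)
  wE <- nchar(early_pattern)
  hits <- data.frame(tata_start = integer(), cakt_start = integer())
  if (length(tata) && length(cakt)) {
    grid <- expand.grid(tata_start = tata, cakt_start = cakt)
    spacer <- grid$cakt_start - (grid$tata_start + wE - 1L) - 1L
    hits <- grid[spacer >= spacer_min & spacer <= spacer_max, , drop = FALSE]
    hits <- hits[order(hits$tata_start, hits$cakt_start), , drop = FALSE]
    rownames(hits) <- NULL
  }
  cls <- if (nrow(hits) && length(late)) "EL"
         else if (nrow(hits)) "E"
         else if (length(late)) "L"
         else "none"
  list(early_hits = hits, late_hits = late, promoter_class = cls)
}

#' Classify the promoter regions of every ORF in an annotation
#'
#' Fills the `motif` column of the annotation table (`"E"`, `"L"`, `"E,L"` or
#' blank, the dialect of published baculovirus annotation tables) by scanning
#' each ORF's upstream window on its coding strand.
#'
#' @param genome a [circular_genome()].
#' @param table an `annotation_table` whose ORFs lie on `genome`.
#' @param window_len upstream window width.
#' @param ... passed to [classify_promoter()].
#' @return the annotation table with `motif` filled; attribute
#'   `promoter_counts` holds the summary `c(E, L, EL, none)`.
#' @export
classify_promoters <- function(genome, table, window_len = 150, ...) {
  stopifnot(inherits(table, "annotation_table"))
  n <- nrow(table$orfs)
  cls <- character(n)
  for (i in seq_len(n)) {
    w <- upstream_window(genome, table$orfs$start[i], table$orfs$end[i],
                         table$orfs$strand[i], window_len = window_len)
    cls[i] <- classify_promoter(w, ...)$promoter_class
  }
  table$orfs$motif <- c(E = "E", L = "L", EL = "E,L", none = "")[cls]
  counts <- c(E = sum(cls == "E"), L = sum(cls == "L"),
              EL = sum(cls == "EL"), none = sum(cls == "none"))
  attr(table, "promoter_counts") <- counts
  table
}
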