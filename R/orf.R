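#' Six-frame ORF discovery on a circular genome
#'
#' Scans both strands of a circular genome for open reading frames: an ATG
#' start codon through the next in-frame stop codon (TAA, TAG or TGA), with
#' the stop codon included in the genomic span but excluded from the
#' amino-acid length (`aa_length = span/3 - 1`). ORFs crossing the origin are
#' found by scanning a doubled copy of the sequence; a candidate's modular
#' span never exceeds the genome length. Coordinates follow the annotation
#' convention: `start <= end` are the bounds of the span along the plus
#' strand, `start > end` marks an origin-spanning feature, and `strand` gives
#' the reading direction.
#'
#' @param genome a [circular_genome()].
#' @param min_aa minimum amino-acid length (excluding the stop) for a
#'   candidate to be reported; the conventional annotation cutoff is 50.
#' @return data.frame with columns `start`, `end`, `strand`, `aa_length`,
#'   sorted by `start`; attribute `genome_length` carries the genome size.
#' @export
find_orfs <- function(genome, min_aa = 50) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  fwd <- orfs_one_strand(genome$sequence, L, min_aa)
  rev <- orfs_one_strand(revcomp(genome$sequence), L, min_aa)
  res <- rbind(
    if (nrow(fwd)) data.frame(
      start = fwd$pos,
      end = (fwd$pos + fwd$span - 2L) %% L + 1L,
      strand = "+", aa_length = fwd$aa, stringsAsFactors = FALSE),
    if (nrow(rev)) data.frame(
      # position p on the reverse-complement maps to genome coordinate
      # L - p + 1; the span's leftmost plus-strand coordinate becomes start
      start = (L - (rev$pos + rev$span - 1L)) %% L + 1L,
      end = L - rev$pos + 1L,
      strand = "-", aa_length = rev$aa, stringsAsFactors = FALSE)
  )
  if (is.null(res) || nrow(res) == 0L)
    res <- data.frame(start = integer(), end = integer(),
                      strand = character(), aa_length = integer(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "genome_length") <- L
  res
}

# ORFs along one strand of the circle: positions are 1-based on the given
# strand's own sequence; wrap handled via a doubled copy.
orfs_one_strand <- function(seqtxt, L, min_aa) {
  dd <- Biostrings::DNAString(paste0(seqtxt, seqtxt))
  atg <- Biostrings::start(Biostrings::matchPattern("ATG", dd))
  atg <- atg[atg <= L]
  stops <- sort(c(
    Biostrings::start(Biostrings::matchPattern("TAA", dd)),
    Biostrings::start(Biostrings::matchPattern("TAG", dd)),
    Biostrings::start(Biostrings::matchPattern("TGA", dd))
  ))
  out <- data.frame(pos = integer(), span = integer(), aa = integer())
  if (length(atg) == 0L) return(out)
  for (f in 0:2) {
    a <- atg[(atg - 1L) %% 3L == f]
    s <- stops[(stops - 1L) %% 3L == f]
    if (length(a) == 0L || length(s) == 0L) next
    # first in-frame stop at or after a + 3
    idx <- findInterval(a + 2L, s) + 1L
    ok <- idx <= length(s)
    a <- a[ok]; idx <- idx[ok]
    q <- s[idx]
    span <- q - a + 3L
    keep <- span <= L & (span %/% 3L - 1L) >= min_aa
    if (any(keep))
      out <- rbind(out, data.frame(pos = a[keep], span = span[keep],
                                   aa = span[keep] %/% 3L - 1L))
  }
  out
}

#' Resolve overlapping ORF candidates
#'
#' Annotation pipelines keep ORFs "with a minimal overlap": here a greedy
#' longest-first rule. Candidates are taken in order of decreasing amino-acid
#' length (ties: smaller start, then plus strand before minus); a candidate
#' is rejected when its modular overlap with any already-accepted ORF exceeds
#' `max_overlap_frac` of the candidate's own span. Fully nested ORFs are
#' always dropped; slightly overlapping neighbours are both kept.
#'
#' @param candidates data.frame as returned by [find_orfs()].
#' @param max_overlap_frac maximum tolerated overlap, as a fraction of the
#'   candidate's own span.
#' @param genome_length circle size; defaults to the `genome_length`
#'   attribute of `candidates`.
#' @return the retained candidates, re-sorted by `start`.
#' @export
resolve_overlaps <- function(candidates, max_overlap_frac = 0.75,
                             genome_length = attr(candidates, "genome_length")) {
  if (is.null(genome_length)) stop("genome_length is required")
  L <- genome_length
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(-candidates$aa_length, candidates$start,
               candidates$strand != "+")
  cand <- candidates[ord, , drop = FALSE]
  acc <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span_i <- arc_span(cand$start[i], cand$end[i], L)
    ok <- TRUE
    for (j in which(acc)) {
      ov <- arc_overlap(cand$start[i], cand$end[i],
                        cand$start[j], cand$end[j], L)
      if (ov > max_overlap_frac * span_i) { ok <- FALSE; break }
    }
    acc[i] <- ok
  }
  res <- cand[acc, , drop = FALSE]
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "genome_length") <- L
  res
}

#' Annotate a circular genome
#'
#' Composition of [find_orfs()] and [resolve_overlaps()]: ORFs are indexed in
#' genome order from the coordinate origin and given default names
#' `orf1, orf2, ...`.
#'
#' @inheritParams find_orfs
#' @inheritParams resolve_overlaps
#' @return an `annotation_table`: list with `genome_name`, `genome_length`,
#'   `orfs` (data.frame: `index`, `name`, `motif`, `start`, `end`,
#'   `aa_length`, `strand`) and `hrs` (data.frame: `label`, `start`, `end`).
#' @export
annotate_genome <- function(genome, min_aa = 50, max_overlap_frac = 0.75) {
  cand <- find_orfs(genome, min_aa = min_aa)
  kept <- resolve_overlaps(cand, max_overlap_frac = max_overlap_frac)
  orfs <- data.frame(
    index = seq_len(nrow(kept)),
    name = if (nrow(kept)) paste0("orf", seq_len(nrow(kept))) else character(),
    motif = rep(NA_character_, nrow(kept)),
    start = kept$start, end = kept$end,
    aa_length = kept$aa_length, strand = kept$strand,
    stringsAsFactors = FALSE
  )
  annotation_table(genome_name = genome$name, genome_length = genome$length,
                   orfs = orfs)
}

#' Construct an annotation table
#'
#' @param genome_name,genome_length genome identity.
#' @param orfs data.frame of ORF records.
#' @param hrs data.frame of homologous-region records (`label`, `start`,
#'   `end`).
#' @return object of class `annotation_table`.
#' @export
annotation_table <- function(genome_name, genome_length, orfs,
                             hrs = data.frame(label = character(),
                                              start = integer(),
                                              end = integer(),
                                              stringsAsFactors = FALSE)) {
  structure(list(genome_name = genome_name,
                 genome_length = as.integer(genome_length),
                 orfs = orfs, hrs = hrs),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %s (%s bp): %d ORFs, %d hrs\n",
              x$genome_name, format(x$genome_length, big.mark = ","),
              nrow(x$orfs), nrow(x$hrs)))
  invisible(x)
}

#' Strand distribution of annotated ORFs
#'
#' @param table an `annotation_table`.
#' @return named integer vector `c(forward = , reverse = )`.
#' @export
strand_counts <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  c(forward = sum(table$orfs$strand == "+"),
    reverse = sum(table$orfs$strand == "-"))
}

#' Fraction of the genome covered by ORFs
#'
#' Union semantics: a base inside two overlapping ORFs is counted once.
#' Computed by modular interval union (origin-spanning ORFs contribute two
#' linear pieces).
#'
#' @param table an `annotation_table`.
#' @return percent of genome bases inside at least one ORF, one decimal.
#' @export
orf_coverage <- function(table) {
  stopifnot(inherits(table, "annotation_table"))
  L <- table$genome_length
  if (is.na(L) || is.null(L)) stop("genome_length must be set")
  if (nrow(table$orfs) == 0L) return(0)
  pieces <- do.call(rbind, lapply(seq_len(nrow(table$orfs)), function(i) {
    p <- arc_pieces(table$orfs$start[i], table$orfs$end[i], L)
    do.call(rbind, lapply(p, function(q) data.frame(s = q[1L], e = q[2L])))
  }))
  ir <- IRanges::reduce(IRanges::IRanges(pieces$s, pieces$e))
  round(100 * sum(IRanges::width(ir)) / L, 1)
}
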