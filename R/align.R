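#' Global pairwise alignment identity
#'
#' Needleman-Wunsch global alignment under a fixed, declared scoring scheme
#' (match +1, mismatch -1, linear gap -1). Percent identity is the number of
#' matched columns over the alignment length. Among score-optimal alignments
#' the one maximising matches (then minimising length) is used, which makes
#' the identity symmetric in its arguments; remaining traceback ties prefer
#' the diagonal, then the vertical move.
#'
#' Works for protein sequences (20-letter alphabet plus X) and for DNA.
#'
#' @param a,b sequences as plain strings.
#' @param alignment if `TRUE`, return the gapped aligned strings too.
#' @return list with `score`, `matches`, `alignment_length`,
#'   `identity_percent` (one decimal) and, when requested, `aligned_a` /
#'   `aligned_b`.
#' @export
global_identity <- function(a, b, alignment = FALSE) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  r <- .nw_align(a, b, alignment)
  out <- list(score = r$score, matches = r$matches,
              alignment_length = r$length,
              identity_percent = round(100 * r$matches / r$length, 1))
  if (alignment) {
    out$aligned_a <- r$aligned_a
    out$aligned_b <- r$aligned_b
  }
  out
}

# identity fraction (unrounded) between two sequences
identity_fraction <- function(a, b) {
  r <- .nw_align(toupper(a), toupper(b), FALSE)
  r$matches / r$length
}
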