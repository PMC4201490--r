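#' Palindromy of a DNA sequence
#'
#' Homologous regions (hrs) of baculovirus genomes are arrays of imperfect
#' palindromes: sequences similar to their own reverse complement. Palindromy
#' is measured as the identity fraction between a sequence and its reverse
#' complement under global alignment (match +1, mismatch -1, gap -1). A
#' perfect palindrome scores 1; a homopolymer scores 0. By construction
#' `palindromy(x) == palindromy(revcomp(x))`.
#'
#' Note that under gapped alignment, random sequence does not score near 0:
#' AT-rich random 99-mers centre around ~0.53. Thresholds are interpreted
#' accordingly (see [find_repeat_seeds()]).
#'
#' @param seq DNA string over {A,C,G,T}.
#' @return identity fraction in [0, 1].
#' @export
palindromy <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("N", seq)) stop("palindromy is undefined for sequences with N")
  identity_fraction(seq, revcomp(seq))
}

#' Scan a circular genome for palindromic repeat seeds
#'
#' Every circular window of width `unit_len` (at the given stride) is scored
#' for palindromy; windows at or above `min_palindromy` are kept and merged
#' to locally maximal ones: qualifying windows are taken in order of
#' decreasing palindromy (ties: smaller start) and a window is dropped if it
#' overlaps an already-kept one. In a tandem array this retains one seed per
#' repeat unit; seed positions are subsequently phase-refined against the
#' family consensus by [cluster_hrs()].
#'
#' @param genome a [circular_genome()].
#' @param unit_len repeat unit length in bases; hrs of nucleopolyhedroviruses
#'   are typically built from ~99 bp units.
#' @param min_palindromy seed threshold. Genuine hr units score ~0.8-1.0;
#'   random AT-rich windows centre around ~0.53 under gapped alignment, so
#'   the default 0.6 admits a thin tail of background windows that the
#'   family-identity filter of [cluster_hrs()] later removes.
#' @param step scan stride in bases.
#' @return data.frame `start`, `end`, `palindromy`, sorted by `start`
#'   (`start > end` for windows spanning the origin); attributes
#'   `genome_length` and `unit_len`.
#' @export
find_repeat_seeds <- function(genome, unit_len = 99, min_palindromy = 0.6,
                              step = 1) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (unit_len >= L) stop("unit_len must be smaller than the genome")
  if (grepl("N", genome$sequence))
    stop("repeat scanning requires an N-free genome")
  p <- .palindromy_scan(genome$sequence, as.integer(unit_len),
                        as.integer(step))
  starts <- seq.int(1L, L, by = step)
  keep <- p >= min_palindromy
  starts <- starts[keep]; p <- p[keep]
  sel <- integer(0)
  if (length(starts)) {
    ord <- order(-p, starts)
    occupied <- logical(L)
    for (i in ord) {
      span <- (starts[i]:(starts[i] + unit_len - 1L) - 1L) %% L + 1L
      if (!any(occupied[span])) {
        occupied[span] <- TRUE
        sel <- c(sel, i)
      }
    }
  }
  res <- data.frame(start = starts[sel],
                    end = (starts[sel] + unit_len - 2L) %% L + 1L,
                    palindromy = p[sel])
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "genome_length") <- L
  attr(res, "unit_len") <- unit_len
  res
}

# column-majority consensus of equal-length sequences (ties: alphabetical)
consensus_string <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  }), collapse = "")
}

# best (identity, orientation) of the window of width ulen at `start`
# against the consensus
window_vs_consensus <- function(genome, start, ulen, cons) {
  L <- genome$length
  st <- as.integer((start - 1L) %% L + 1L)
  en <- as.integer((st + ulen - 2L) %% L + 1L)
  w <- genome_subseq(genome, st, en, "+")
  f <- identity_fraction(w, cons)
  r <- identity_fraction(revcomp(w), cons)
  if (r > f) list(start = st, end = en, identity = r, orientation = "-",
                  sequence = revcomp(w))
  else list(start = st, end = en, identity = f, orientation = "+",
            sequence = w)
}

#' Cluster palindromic repeat seeds into homologous regions
#'
#' Builds the genome-wide repeat family and reports its regions. The family
#' consensus is seeded from the highest-palindromy unit (so that the thin
#' tail of background windows passing the seed threshold cannot dominate it)
#' and refined by majority vote over units within `min_family_identity` of
#' it. Each seed is then phase-refined: its window is slid up to half a unit
#' either way to the offset maximising identity to the consensus, on the
#' better-scoring strand — this snaps unit boundaries onto the repeat phase.
#' Units below `min_family_identity` percent identity to the consensus are
#' dropped; the consensus' own strand is fixed by majority vote over the
#' retained units, ties toward plus. Retained units within `max_gap` of each
#' other are chained into regions; regions with at least `min_copies` units
#' are reported with boundaries from the first unit start to the last unit
#' end and labels `hr1, hr2, ...` in genome order.
#'
#' @param seeds output of [find_repeat_seeds()].
#' @param genome the same [circular_genome()] the seeds came from.
#' @param max_gap maximum gap in bases between consecutive units of one
#'   region.
#' @param min_copies minimum number of repeat units per reported region.
#' @param min_family_identity percent identity to the family consensus below
#'   which a unit is discarded.
#' @return an `hr_profile`: list with `regions` (data.frame `label`, `start`,
#'   `end`, `copy_number`, `length`, `min_pairwise_identity`), `units`
#'   (data.frame `region`, `start`, `end`, `orientation`,
#'   `identity_to_consensus`, `sequence`), `consensus`, `core` (see
#'   [core_palindrome()]), `genome_coverage_percent` and `genome_length`.
#'   Region `length` follows the published convention `end - start`.
#' @export
cluster_hrs <- function(seeds, genome, max_gap = 300, min_copies = 2,
                        min_family_identity = 90) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  empty <- structure(list(
    regions = data.frame(label = character(), start = integer(),
                         end = integer(), copy_number = integer(),
                         length = integer(),
                         min_pairwise_identity = numeric()),
    units = data.frame(region = character(), start = integer(),
                       end = integer(), orientation = character(),
                       identity_to_consensus = numeric(),
                       sequence = character(), stringsAsFactors = FALSE),
    consensus = NA_character_, core = NULL,
    genome_coverage_percent = 0, genome_length = L),
    class = "hr_profile")
  if (is.null(seeds) || nrow(seeds) == 0L) return(empty)
  ulen <- attr(seeds, "unit_len")
  if (is.null(ulen)) ulen <- as.integer(stats::median(
    (seeds$end - seeds$start) %% L + 1L))
  minf <- min_family_identity / 100
  half <- ulen %/% 2L

  s <- seeds[order(seeds$start), , drop = FALSE]

  snap_to <- function(start0, target, range, step = 7L) {
    coarse <- seq.int(-range, range, by = step)
    ev <- lapply(coarse, function(d)
      window_vs_consensus(genome, start0 + d, ulen, target))
    best <- coarse[which.max(vapply(ev, `[[`, numeric(1L), "identity"))]
    fine <- setdiff(seq.int(best - step %/% 2L, best + step %/% 2L), coarse)
    ev <- c(ev, lapply(fine, function(d)
      window_vs_consensus(genome, start0 + d, ulen, target)))
    ev[[which.max(vapply(ev, `[[`, numeric(1L), "identity"))]]
  }
  as_units <- function(snap) {
    u <- data.frame(start = vapply(snap, `[[`, integer(1L), "start"),
                    end = vapply(snap, `[[`, integer(1L), "end"),
                    orientation = vapply(snap, `[[`, character(1L),
                                         "orientation"),
                    identity = vapply(snap, `[[`, numeric(1L), "identity"),
                    sequence = vapply(snap, `[[`, character(1L), "sequence"),
                    stringsAsFactors = FALSE)
    # snapped seeds may converge on one position; keep the best claimant
    u <- u[order(-u$identity, u$start), , drop = FALSE]
    drop <- logical(nrow(u))
    for (i in seq_len(nrow(u))[-1L]) {
      for (j in seq_len(i - 1L)[!drop[seq_len(i - 1L)]]) {
        if (arc_overlap(u$start[i], u$end[i], u$start[j], u$end[j],
                        L) > ulen / 2) { drop[i] <- TRUE; break }
      }
    }
    u[!drop, , drop = FALSE]
  }

  # stage 1 -- provisional family, anchored on the most palindromic seed:
  # snap every seed onto the reference's phase (either strand) and keep
  # clear family members. Background windows sit near ~0.55 identity, far
  # below the 0.75 admission bar.
  ref <- genome_subseq(genome, s$start[which.max(s$palindromy)],
                       s$end[which.max(s$palindromy)], "+")
  u <- as_units(lapply(s$start, snap_to, target = ref, range = half))
  u <- u[u$identity >= min(0.75, minf), , drop = FALSE]
  if (nrow(u) == 0L) return(empty)

  # stage 2 -- phase search: the reference may sit mid-unit (in a tandem
  # palindrome array, windows straddling a unit junction can be the most
  # palindromic ones). Slide the family phase; at each candidate phase the
  # members re-snap locally (inter-unit gaps vary by a few bases) against
  # the phase's reference window, and the phase whose column-stack
  # consensus the members agree with best wins. The true unit phase beats
  # junction phases because junction windows mix gap sequence and the
  # orientation-dependent halves of two different copies.
  refwin_d <- function(d) genome_subseq(
    genome, (u$start[1L] + d - 1L) %% L + 1L,
    (u$start[1L] + d + ulen - 2L) %% L + 1L, "+")
  phase_score <- function(d, range) {
    rw <- refwin_d(d)
    seqsd <- vapply(u$start, function(st) {
      if (range > 0L) snap_to(st + d, rw, range = range, step = 3L)$sequence
      else window_vs_consensus(genome, st + d, ulen, rw)$sequence
    }, character(1L))
    cons_d <- consensus_string(seqsd)
    mean(vapply(seqsd, identity_fraction, numeric(1L), b = cons_d,
                USE.NAMES = FALSE))
  }
  if (nrow(u) >= 2L) {
    # a junction-anchored reference can sit up to half a unit plus the
    # inter-unit gap away from the true phase, so cover a full period both
    # ways (re-snapping folds equivalent phases onto one another)
    cand_d <- seq.int(-ulen, ulen, by = 7L)
    sc <- vapply(cand_d, phase_score, numeric(1L), range = 6L)
    fine <- setdiff(seq.int(cand_d[which.max(sc)] - 3L,
                            cand_d[which.max(sc)] + 3L), cand_d)
    cand_d <- c(cand_d, fine)
    sc <- c(sc, vapply(fine, phase_score, numeric(1L), range = 6L))
    # members re-snap during scoring, so neighbouring phases tie; break the
    # plateau by how well members agree at exactly their slid positions,
    # preferring the smallest shift among residual ties
    plateau <- cand_d[sc >= max(sc) - 1e-9]
    plateau <- plateau[order(abs(plateau))]
    if (length(plateau) > 1L) {
      exact <- vapply(plateau, phase_score, numeric(1L), range = 0L)
      bestd <- plateau[which.max(exact)]
    } else bestd <- plateau
  } else {
    bestd <- 0L   # a single member defines the phase by itself
  }


  # final units: build the consensus at the chosen phase from the members,
  # then place units by a dense identity sweep around every member (one and
  # a half units either side, so terminal copies are reached), greedily
  # keeping non-overlapping positions in order of decreasing identity
  rw <- refwin_d(bestd)
  anchor <- vapply(u$start, function(st)
    snap_to(st + bestd, rw, range = 6L, step = 3L)$sequence, character(1L))
  cons <- consensus_string(anchor)
  margin <- as.integer(1.5 * ulen) + 20L
  # two placement passes: the second runs against the consensus rebuilt
  # from the first pass's units, which pins any residual one-base phase
  # offset of the provisional consensus
  for (pass in 1:2) {
    swept <- logical(L)
    for (st in u$start)
      swept[((st - margin):(st + margin) - 1L) %% L + 1L] <- TRUE
    cand <- which(swept)
    ev <- lapply(cand, function(st) window_vs_consensus(genome, st, ulen,
                                                        cons))
    u <- data.frame(start = vapply(ev, `[[`, integer(1L), "start"),
                    end = vapply(ev, `[[`, integer(1L), "end"),
                    orientation = vapply(ev, `[[`, character(1L),
                                         "orientation"),
                    identity = vapply(ev, `[[`, numeric(1L), "identity"),
                    sequence = vapply(ev, `[[`, character(1L), "sequence"),
                    stringsAsFactors = FALSE)
    u <- u[u$identity >= minf, , drop = FALSE]
    if (nrow(u) == 0L) return(empty)
    u <- u[order(-u$identity, u$start), , drop = FALSE]
    occupied <- logical(L)
    takei <- logical(nrow(u))
    for (i in seq_len(nrow(u))) {
      span <- ((u$start[i]:(u$start[i] + ulen - 1L)) - 1L) %% L + 1L
      # a few bases of slack so recovered units may abut, while off-by-one
      # echoes of an already-placed unit are suppressed
      if (sum(occupied[span]) <= 5L) {
        occupied[span] <- TRUE
        takei[i] <- TRUE
      }
    }
    u <- u[takei, , drop = FALSE]
    cons <- consensus_string(u$sequence)
  }
  for (i in seq_len(nrow(u))) {
    v <- window_vs_consensus(genome, u$start[i], ulen, cons)
    u$orientation[i] <- v$orientation
    u$identity[i] <- v$identity
    u$sequence[i] <- v$sequence
  }
  u <- u[u$identity >= minf, , drop = FALSE]
  if (nrow(u) == 0L) return(empty)
  if (sum(u$orientation == "-") > sum(u$orientation == "+")) {
    cons <- revcomp(cons)
    u$orientation <- ifelse(u$orientation == "-", "+", "-")
    u$sequence <- vapply(u$sequence, revcomp, character(1L),
                         USE.NAMES = FALSE)
  }
  if (sum(u$orientation == "-") > sum(u$orientation == "+")) {
    cons <- revcomp(cons)
    u$orientation <- ifelse(u$orientation == "-", "+", "-")
    u$sequence <- vapply(u$sequence, revcomp, character(1L),
                         USE.NAMES = FALSE)
  }

  # chain retained units into regions along the circle
  u <- u[order(u$start), , drop = FALSE]
  n <- nrow(u)
  nxt <- c(seq_len(n)[-1L], 1L)
  gap <- (u$start[nxt] - u$end - 1L) %% L
  if (all(gap <= max_gap)) {
    members <- list(seq_len(n))
  } else {
    breaks <- which(gap > max_gap)
    first <- breaks[length(breaks)] %% n + 1L
    ordc <- ((first - 1L + seq_len(n) - 1L) %% n) + 1L
    members <- list(); cur <- integer(0)
    for (k in ordc) {
      cur <- c(cur, k)
      if (k %in% breaks) {
        members[[length(members) + 1L]] <- cur
        cur <- integer(0)
      }
    }
  }
  members <- members[vapply(members, length, integer(1L)) >= min_copies]
  if (length(members) == 0L) return(empty)

  reg <- do.call(rbind, lapply(members, function(k) {
    data.frame(start = u$start[k[1L]], end = u$end[k[length(k)]],
               copy_number = length(k),
               min_pairwise_identity = if (length(k) >= 2L)
                 repeat_identity(u$sequence[k])$min_pairwise
               else NA_real_)
  }))
  reg$length <- (reg$end - reg$start) %% L
  ordreg <- order(reg$start)
  reg <- reg[ordreg, , drop = FALSE]
  reg$label <- paste0("hr", seq_len(nrow(reg)))
  units <- do.call(rbind, lapply(seq_along(ordreg), function(r) {
    k <- members[[ordreg[r]]]
    data.frame(region = reg$label[r], start = u$start[k], end = u$end[k],
               orientation = u$orientation[k],
               identity_to_consensus = round(100 * u$identity[k], 1),
               sequence = u$sequence[k], stringsAsFactors = FALSE)
  }))
  rownames(units) <- rownames(reg) <- NULL
  core <- if (nrow(units) >= 2L) core_palindrome(units$sequence) else NULL
  structure(list(
    regions = reg[, c("label", "start", "end", "copy_number", "length",
                      "min_pairwise_identity")],
    units = units, consensus = cons, core = core,
    genome_coverage_percent = round(100 * sum(reg$length) / L, 1),
    genome_length = L), class = "hr_profile")
}

#' @export
print.hr_profile <- function(x, ...) {
  cat(sprintf("<hr_profile> %d regions, %d repeat units, %.1f%% of %s bp\n",
              nrow(x$regions), nrow(x$units), x$genome_coverage_percent,
              format(x$genome_length, big.mark = ",")))
  invisible(x)
}

#' Summary statistics of homologous regions
#'
#' Region length follows the published convention `end - start` (not `+ 1`);
#' coverage is the summed region length as a percent of the genome, one
#' decimal.
#'
#' @param x an `hr_profile` from [cluster_hrs()], or a data.frame with
#'   `start` and `end` columns (e.g. the hr block of an annotation table).
#' @param genome_length circle size; taken from the profile when `x` is one.
#' @return list with `n_regions`, `lengths`, `min_length`, `max_length`,
#'   `coverage_percent` and (when available) `copy_range`.
#' @export
hr_stats <- function(x, genome_length = NULL) {
  if (inherits(x, "hr_profile")) {
    if (is.null(genome_length)) genome_length <- x$genome_length
    reg <- x$regions
    copy_range <- if (nrow(reg)) range(reg$copy_number) else NULL
  } else {
    reg <- x
    copy_range <- NULL
  }
  if (is.null(genome_length)) stop("genome_length is required")
  if (nrow(reg) == 0L) stop("no regions to summarise")
  len <- (reg$end - reg$start) %% genome_length
  list(n_regions = nrow(reg), lengths = len,
       min_length = min(len), max_length = max(len),
       coverage_percent = round(100 * sum(len) / genome_length, 1),
       copy_range = copy_range)
}

#' Pairwise identity within a repeat family
#'
#' All-pairs global-alignment identity of the oriented unit sequences.
#'
#' @param units character vector of oriented unit sequences, or a data.frame
#'   with a `sequence` column (as in an `hr_profile`).
#' @return list with `min_pairwise` and `mean_pairwise` percent identity,
#'   one decimal.
#' @export
repeat_identity <- function(units) {
  if (is.data.frame(units)) units <- units$sequence
  if (length(units) < 2L) stop("at least two repeat units are required")
  pr <- utils::combn(length(units), 2L)
  ids <- vapply(seq_len(ncol(pr)), function(k)
    100 * identity_fraction(units[pr[1L, k]], units[pr[2L, k]]),
    numeric(1L))
  list(min_pairwise = round(min(ids), 1), mean_pairwise = round(mean(ids), 1))
}

#' Core palindrome of a repeat family
#'
#' Per-column majority consensus over equal-length oriented units, and the
#' longest contiguous run of columns whose conservation (majority-base
#' frequency) is at or above `min_conservation`. hr repeats typically carry
#' a near-invariant core palindrome inside more variable flanks.
#'
#' @param units character vector of oriented, equal-length unit sequences, or
#'   a data.frame with a `sequence` column.
#' @param min_conservation column conservation threshold.
#' @return list with `consensus` (core subsequence; empty string when no
#'   column qualifies), `offset` (1-based start column; `NA` for an empty
#'   run), `length`, `full_consensus` and per-column `conservation`.
#' @export
core_palindrome <- function(units, min_conservation = 0.99) {
  if (is.data.frame(units)) units <- units$sequence
  if (length(units) < 2L) stop("at least two repeat units are required")
  if (length(unique(nchar(units))) != 1L)
    stop("units must have equal length")
  m <- do.call(rbind, strsplit(units, ""))
  cons <- apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    c(names(tb)[1L], tb[1L] / length(col))
  })
  full <- paste(cons[1L, ], collapse = "")
  conservation <- as.numeric(cons[2L, ])
  ok <- conservation >= min_conservation
  if (!any(ok)) {
    return(list(consensus = "", offset = NA_integer_, length = 0L,
                full_consensus = full, conservation = conservation))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]    # ties: earliest run
  list(consensus = substr(full, starts[best], ends[best]),
       offset = starts[best], length = r$lengths[best],
       full_consensus = full, conservation = conservation)
}
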