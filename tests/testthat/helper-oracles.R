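# Independent oracles used across the suite. Each deliberately takes a
# different code path from the package implementation it checks.

# character-wise complement map + reversal (no Biostrings)
oracle_revcomp <- function(x) {
  v <- rev(strsplit(x, "")[[1L]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v], collapse = "")
}

# per-base tally with a different traversal order (backwards)
oracle_composition <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  for (i in rev(seq_along(v))) counts[v[i]] <- counts[v[i]] + 1L
  counts
}

# doubled-string ORF enumeration: walk every ATG on both strands and
# translate codon by codon to the first stop, using substring() throughout
oracle_orfs <- function(seq, min_aa) {
  L <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    dd <- paste0(s, s)
    for (p in seq_len(L)) {
      if (substr(dd, p, p + 2L) != "ATG") next
      q <- p + 3L
      repeat {
        if (q + 2L > 2L * L) { q <- NA; break }
        cod <- substr(dd, q, q + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) break
        q <- q + 3L
      }
      if (is.na(q)) next
      span <- q + 2L - p + 1L
      if (span > L) next
      aa <- span %/% 3L - 1L
      if (aa < min_aa) next
      if (strand == "+") {
        start <- p; end <- (p + span - 2L) %% L + 1L
      } else {
        start <- (L - (p + span - 1L)) %% L + 1L; end <- L - p + 1L
      }
      res[[length(res) + 1L]] <- data.frame(start = start, end = end,
                                            strand = strand, aa_length = aa)
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), aa_length = integer()))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the set of genome positions covered by an inclusive (modular) arc
oracle_arc_positions <- function(start, end, L) {
  if (start <= end) start:end else c(start:L, 1:end)
}

# quadratic pairwise overlap resolution on explicit position sets
oracle_resolve <- function(cand, max_frac, L) {
  ord <- order(-cand$aa_length, cand$start, cand$strand != "+")
  cand <- cand[ord, , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    pos_i <- oracle_arc_positions(cand$start[i], cand$end[i], L)
    ok <- TRUE
    for (k in kept) {
      if (length(intersect(pos_i, k)) > max_frac * length(pos_i)) {
        ok <- FALSE; break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- pos_i
    cand$keep[i] <- ok
  }
  out <- cand[cand$keep, c("start", "end", "strand", "aa_length"),
              drop = FALSE]
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# boolean base-marking coverage
oracle_coverage <- function(orfs, L) {
  hit <- logical(L)
  for (i in seq_len(nrow(orfs)))
    hit[oracle_arc_positions(orfs$start[i], orfs$end[i], L)] <- TRUE
  round(100 * sum(hit) / L, 1)
}

# exhaustive enumeration of all global alignments (exponential recursion,
# no DP): optimal score under match +1, mismatch -1, gap -1
oracle_align_score <- function(a, b) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -.Machine$integer.max
    if (i > 0L && j > 0L) {
      sc <- rec(i - 1L, j - 1L) +
        (if (substr(a, i, i) == substr(b, j, j)) 1L else -1L)
      if (sc > best) best <- sc
    }
    if (i > 0L) {
      sc <- rec(i - 1L, j) - 1L
      if (sc > best) best <- sc
    }
    if (j > 0L) {
      sc <- rec(i, j - 1L) - 1L
      if (sc > best) best <- sc
    }
    best
  }
  rec(nchar(a), nchar(b))
}

# regex-based promoter classifier built by independent IUPAC expansion
oracle_classify <- function(window, spacer_min = 20, spacer_max = 40) {
  expand <- c(A = "A", C = "C", G = "G", T = "T", K = "[GT]", D = "[AGT]",
              W = "[AT]", R = "[AG]", Y = "[CT]", S = "[CG]", M = "[AC]",
              B = "[CGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  to_re <- function(p)
    paste(expand[strsplit(p, "")[[1L]]], collapse = "")
  allm <- function(p) {   # overlapping matches via lookahead
    m <- gregexpr(paste0("(?=", to_re(p), ")"), window, perl = TRUE)[[1L]]
    m[m > 0L]
  }
  tata <- allm("TATAA"); cakt <- allm("CAKT"); late <- allm("DTAAG")
  early <- FALSE
  for (t in tata) for (cc in cakt) {
    spacer <- cc - (t + 4L) - 1L
    if (spacer >= spacer_min && spacer <= spacer_max &&
        cc + 3L <= nchar(window)) early <- TRUE
  }
  late_hit <- length(late) > 0L
  if (early && late_hit) "EL" else if (early) "E"
  else if (late_hit) "L" else "none"
}

# all-pairs Hamming identity (equal-length, gap-free families)
oracle_hamming_min_mean <- function(seqs) {
  n <- length(seqs)
  ids <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- strsplit(seqs[i], "")[[1L]]; b <- strsplit(seqs[j], "")[[1L]]
    ids <- c(ids, 100 * mean(a == b))
  }
  list(min = round(min(ids), 1), mean = round(mean(ids), 1))
}

# brute force over all O(n^2) candidate runs of consecutive points
oracle_longest_run <- function(pts, max_jump = 2) {
  pts <- pts[order(pts$x), , drop = FALSE]
  n <- nrow(pts)
  best <- c(len = 1L, start = 1L)
  for (i in seq_len(n)) for (j in i:n) {
    if (j > i) {
      dy <- diff(pts$y[i:j])
      if (!(all(dy > 0) || all(dy < 0)) || any(abs(dy) > max_jump)) next
    }
    if (j - i + 1L > best["len"]) best <- c(len = j - i + 1L, start = i)
  }
  list(length = unname(best["len"]),
       start_x = pts$x[best["start"]],
       end_x = pts$x[best["start"] + best["len"] - 1L])
}

# random genome helper (AT-biased i.i.d. background)
random_genome <- function(L, at = 0.6, name = "rnd") {
  circular_genome(paste(sample(c("A", "T", "C", "G"), L, replace = TRUE,
                               prob = c(at / 2, at / 2, (1 - at) / 2,
                                        (1 - at) / 2)),
                        collapse = ""), name = name)
}
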