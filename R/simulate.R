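STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1L, paste, collapse = ""),
  STOP_CODONS)
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Parameters for the synthetic-genome generator
#'
#' Defaults emulate the architecture of a group II alphabaculovirus genome:
#' a 135,952 bp circle at 61.34% A+T carrying 131 planted ORFs (60 forward /
#' 71 reverse as a strand mix), promoter classes in the proportions
#' 24 E : 61 L : 10 EL : 36 none, and seven hr arrays of 4-8 imperfect
#' palindromic 99 bp repeats copied from one genome-wide master unit at 2%
#' per-base mutation.
#'
#' @param genome_length circle size in bases.
#' @param at_fraction background A+T fraction (0-1).
#' @param n_orfs number of planted ORFs.
#' @param orf_length_range amino-acid length range (uniform, inclusive).
#' @param strand_mix fraction of ORFs on the forward strand.
#' @param promoter_mix probabilities over classes E, L, EL, none.
#' @param n_hrs number of planted hr arrays.
#' @param units_per_hr_range repeat copies per array (uniform, inclusive).
#' @param unit_length repeat unit length in bases.
#' @param unit_palindromy approximate palindromy of the master unit; below 1
#'   so that unit orientation is identifiable.
#' @param unit_mutation_rate per-base substitution rate applied to each
#'   planted copy of the master unit.
#' @param unit_gap_range bases between consecutive units of an array.
#' @param window_len upstream promoter window width.
#' @param seed integer seed governing all randomness.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 135952, at_fraction = 0.6134,
                       n_orfs = 131, orf_length_range = c(50, 250),
                       strand_mix = 60 / 131,
                       promoter_mix = c(E = 24, L = 61, EL = 10,
                                        none = 36) / 131,
                       n_hrs = 7, units_per_hr_range = c(4, 8),
                       unit_length = 99, unit_palindromy = 0.85,
                       unit_mutation_rate = 0.02, unit_gap_range = c(0, 10),
                       window_len = 150, seed = 1) {
  stopifnot(genome_length > 0, at_fraction >= 0, at_fraction <= 1,
            n_orfs >= 0, n_hrs >= 0, length(orf_length_range) == 2L,
            orf_length_range[1L] <= orf_length_range[2L],
            all(promoter_mix >= 0), unit_mutation_rate >= 0,
            unit_mutation_rate <= 1, window_len > 3)
  promoter_mix <- promoter_mix / sum(promoter_mix)
  if (!all(c("E", "L", "EL", "none") %in% names(promoter_mix)))
    stop("promoter_mix must be named with E, L, EL, none")
  structure(as.list(environment()), class = "sim_params")
}

rand_bases <- function(n, at) {
  if (n == 0L) return(character(0))
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

has_start_triplet <- function(x) grepl("ATG", x) || grepl("CAT", x)

frame_has_stop <- function(x) {
  # every frame of both strands must contain a stop codon
  for (s in c(x, revcomp(x))) {
    v <- strsplit(s, "")[[1L]]
    for (f in 0:2) {
      k <- seq.int(1L + f, length(v) - 2L, by = 3L)
      if (length(k) == 0L) return(FALSE)
      cod <- paste0(v[k], v[k + 1L], v[k + 2L])
      if (!any(cod %in% STOP_CODONS)) return(FALSE)
    }
  }
  TRUE
}

# master repeat unit: an imperfect palindrome without start triplets and
# with stops in all six frames (so ORFs cannot thread through the arrays)
make_master_unit <- function(unit_length, unit_palindromy, at) {
  half <- unit_length %/% 2L
  centre <- unit_length - 2L * half
  n_imp <- max(1L, round((1 - unit_palindromy) * unit_length / 2))
  for (try in 1:500) {
    left <- rand_bases(half, at)
    unit <- c(left,
              if (centre) rand_bases(centre, at),
              strsplit(revcomp(paste(left, collapse = "")), "")[[1L]])
    pos <- sample.int(half, min(n_imp, half))
    for (p in pos) unit[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                             unit[p]), 1L)
    u <- paste(unit, collapse = "")
    if (!has_start_triplet(u) && frame_has_stop(u)) return(u)
  }
  stop("could not build a master repeat unit under the constraints")
}

mutate_copy <- function(unit_chars, rate) {
  hit <- which(stats::runif(length(unit_chars)) < rate)
  for (p in hit)
    unit_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), unit_chars[p]), 1L)
  list(seq = unit_chars, mutated = hit)
}

# remove every ATG/CAT occurrence by flipping one unprotected base of it
# (checking a +-2 neighbourhood so the flip creates no new occurrence);
# windows free of start triplets on both strands cannot seed chance ORFs
strip_start_triplets <- function(w, protected_idx) {
  for (round in 1:200) {
    ws <- paste(w, collapse = "")
    hits <- sort(unique(c(gregexpr("(?=ATG)", ws, perl = TRUE)[[1L]],
                          gregexpr("(?=CAT)", ws, perl = TRUE)[[1L]])))
    hits <- hits[hits > 0L]
    if (length(hits) == 0L) return(w)
    h <- hits[1L]
    fixed <- FALSE
    for (pos in setdiff(h:(h + 2L), protected_idx)) {
      for (b in sample(setdiff(c("A", "C", "G", "T"), w[pos]))) {
        w2 <- w; w2[pos] <- b
        nb <- paste(w2[max(1L, pos - 2L):min(length(w2), pos + 2L)],
                    collapse = "")
        if (!grepl("ATG", nb) && !grepl("CAT", nb) &&
            !grepl("ATG", paste(w2[h:(h + 2L)], collapse = "")) &&
            !grepl("CAT", paste(w2[h:(h + 2L)], collapse = ""))) {
          w <- w2; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed) stop("start triplet overlaps protected motif")
  }
  stop("could not clear start triplets")
}

# draw a window (coding orientation) matching the target promoter class.
# The last three bases are a fixed in-frame TAA that blocks upstream start
# extensions of the planted ORF; the window carries no ATG/CAT on either
# strand, so no chance ORF can start inside it.
draw_window <- function(window_len, class, at) {
  free <- window_len - 3L
  for (try in 1:300) {
    w <- c(rand_bases(free, at), "T", "A", "A")
    prot <- (free + 1L):window_len
    if (class %in% c("E", "EL")) {
      spacer <- sample(20:40, 1L)
      tlen <- 5L + spacer + 4L
      if (tlen > free) stop("window too short for an early element")
      t0 <- sample.int(free - tlen + 1L, 1L)
      w[t0:(t0 + 4L)] <- c("T", "A", "T", "A", "A")
      w[(t0 + 5L + spacer):(t0 + 8L + spacer)] <- c("C", "A", "G", "T")
      prot <- c(prot, t0:(t0 + 8L + spacer))
    }
    if (class %in% c("L", "EL")) {
      ok <- setdiff(seq_len(free - 4L), unique(c(outer(prot, 0:4, "-"))))
      if (length(ok) == 0L) next
      l0 <- if (length(ok) == 1L) ok else sample(ok, 1L)
      w[l0:(l0 + 4L)] <- c(sample(c("A", "G", "T"), 1L), "T", "A", "A", "G")
      prot <- c(prot, l0:(l0 + 4L))
    }
    w <- tryCatch(strip_start_triplets(w, prot), error = function(e) NULL)
    if (is.null(w)) next
    if (classify_promoter(paste(w, collapse = ""))$promoter_class == class)
      return(w)
  }
  stop("could not draw a ", class, " window after bounded retries")
}

#' Simulate a circular genome with planted features
#'
#' Generates an i.i.d. background at the requested A+T fraction and plants,
#' pairwise disjoint: ORFs (ATG + uniform sense codons + stop) whose 150 bp
#' upstream windows carry the requested promoter class (windows are
#' rejection-sampled until they classify exactly as planted), and hr arrays
#' copied from one genome-wide master palindrome with per-base mutation and
#' random unit orientations. The background is then made stop-dense: any
#' chance ORF of >= 50 aa that is not a planted feature is disrupted by an
#' in-frame stop written into non-feature sequence, so that annotation
#' recovers exactly the planted ORFs. Identical seeds give identical output.
#'
#' @param params a [sim_params()] object.
#' @return list with `genome` (a [circular_genome()]) and `truth` (planted
#'   ORFs with promoter classes and window spans, hr regions and units with
#'   orientations and mutated positions, the master unit, and the realised
#'   background composition).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  L <- params$genome_length
  at <- params$at_fraction
  wl <- params$window_len

  # ---- feature blocks -------------------------------------------------
  blocks <- list()
  if (params$n_orfs > 0L) {
    aa <- sample(params$orf_length_range[1L]:params$orf_length_range[2L],
                 params$n_orfs, replace = TRUE)
    strand <- ifelse(stats::runif(params$n_orfs) < params$strand_mix,
                     "+", "-")
    class <- sample(names(params$promoter_mix), params$n_orfs,
                    replace = TRUE, prob = params$promoter_mix)
    for (i in seq_len(params$n_orfs)) {
      orf <- c("A", "T", "G",
               strsplit(paste(sample(SENSE_CODONS, aa[i] - 1L,
                                     replace = TRUE), collapse = ""),
                        "")[[1L]],
               strsplit(sample(STOP_CODONS, 1L), "")[[1L]])
      win <- draw_window(wl, class[i], at)
      if (strand[i] == "+") {
        seqc <- c(win, orf)
        orf_rel <- c(wl + 1L, wl + length(orf))
        win_rel <- c(1L, wl)
      } else {
        seqc <- strsplit(revcomp(paste(c(win, orf), collapse = "")),
                         "")[[1L]]
        orf_rel <- c(1L, length(orf))
        win_rel <- c(length(orf) + 1L, length(orf) + wl)
      }
      blocks[[length(blocks) + 1L]] <- list(
        type = "orf", seq = seqc, strand = strand[i], aa = aa[i],
        class = class[i], orf_rel = orf_rel, win_rel = win_rel)
    }
  }
  master <- make_master_unit(params$unit_length, params$unit_palindromy, at)
  if (params$n_hrs > 0L) {
    for (h in seq_len(params$n_hrs)) {
      k <- sample(params$units_per_hr_range[1L]:
                  params$units_per_hr_range[2L], 1L)
      seqc <- character(0)
      units <- list()
      for (u in seq_len(k)) {
        cp <- mutate_copy(strsplit(master, "")[[1L]],
                          params$unit_mutation_rate)
        ori <- sample(c("+", "-"), 1L)
        placed <- if (ori == "-")
          strsplit(revcomp(paste(cp$seq, collapse = "")), "")[[1L]]
        else cp$seq
        units[[u]] <- list(rel = length(seqc) + 1L, ori = ori,
                           mutated_rel = cp$mutated)
        seqc <- c(seqc, placed)
        if (u < k) {
          g <- sample(params$unit_gap_range[1L]:params$unit_gap_range[2L],
                      1L)
          if (g > 0L) {
            gb <- rand_bases(g, at)
            for (try in 1:50) {
              if (!has_start_triplet(paste(gb, collapse = ""))) break
              gb <- rand_bases(g, at)
            }
            seqc <- c(seqc, gb)
          }
        }
      }
      blocks[[length(blocks) + 1L]] <- list(type = "hr", seq = seqc,
                                            units = units)
    }
  }

  # ---- layout ---------------------------------------------------------
  nb <- length(blocks)
  total <- sum(vapply(blocks, function(b) length(b$seq), integer(1L)))
  min_gap <- 10L
  free <- L - total - nb * min_gap
  if (nb > 0L && free < 0L)
    stop("infeasible packing: requested features need ",
         total + nb * min_gap, " bases but the genome has ", L)
  blocks <- blocks[sample.int(nb)]
  gaps <- if (nb) min_gap + as.integer(stats::rmultinom(1L, free,
                                                        rep(1, nb)))
          else integer(0)
  genome <- rand_bases(L, at)
  pos <- 1L
  for (i in seq_len(nb)) {
    pos <- pos + gaps[i]
    b <- blocks[[i]]
    blocks[[i]]$at <- pos
    genome[pos:(pos + length(b$seq) - 1L)] <- b$seq
    pos <- pos + length(b$seq)
  }

  # ---- truth ----------------------------------------------------------
  orf_truth <- list(); hr_truth <- list(); hr_units <- list()
  hr_mut <- integer(0)
  for (b in blocks) {
    if (b$type == "orf") {
      orf_truth[[length(orf_truth) + 1L]] <- data.frame(
        start = b$at + b$orf_rel[1L] - 1L, end = b$at + b$orf_rel[2L] - 1L,
        strand = b$strand, aa_length = b$aa, promoter_class = b$class,
        window_start = b$at + b$win_rel[1L] - 1L,
        window_end = b$at + b$win_rel[2L] - 1L, stringsAsFactors = FALSE)
    } else {
      ulen <- params$unit_length
      us <- vapply(b$units, function(u) b$at + u$rel - 1L, integer(1L))
      hr_units[[length(hr_units) + 1L]] <- data.frame(
        region = length(hr_truth) + 1L, start = us, end = us + ulen - 1L,
        orientation = vapply(b$units, function(u) u$ori, character(1L)),
        stringsAsFactors = FALSE)
      hr_mut <- c(hr_mut, unlist(lapply(b$units, function(u)
        b$at + u$rel - 1L + u$mutated_rel - 1L)))
      hr_truth[[length(hr_truth) + 1L]] <- data.frame(
        start = us[1L], end = us[length(us)] + ulen - 1L,
        copy_number = length(us), stringsAsFactors = FALSE)
    }
  }
  orfs <- if (length(orf_truth)) do.call(rbind, orf_truth)
          else data.frame(start = integer(), end = integer(),
                          strand = character(), aa_length = integer(),
                          promoter_class = character(),
                          window_start = integer(), window_end = integer())
  orfs <- orfs[order(orfs$start), , drop = FALSE]; rownames(orfs) <- NULL
  hrs <- if (length(hr_truth)) do.call(rbind, hr_truth)
         else data.frame(start = integer(), end = integer(),
                         copy_number = integer())
  units <- if (length(hr_units)) do.call(rbind, hr_units)
           else data.frame(region = integer(), start = integer(),
                           end = integer(), orientation = character())
  if (nrow(hrs)) {
    ord <- order(hrs$start)
    hrs <- hrs[ord, , drop = FALSE]
    units$region <- match(units$region, ord)
    units <- units[order(units$region, units$start), , drop = FALSE]
    hrs$label <- paste0("hr", seq_len(nrow(hrs)))
    units$region <- hrs$label[units$region]
    rownames(hrs) <- rownames(units) <- NULL
  }
  truth <- list(orfs = orfs, hrs = hrs, hr_units = units,
                hr_mutated_positions = sort(hr_mut), master_unit = master,
                params = params)

  # ---- stop-dense background: disrupt chance ORFs ---------------------
  sc <- scrub_genome(genome, truth, params)
  genome <- sc$genome
  g <- circular_genome(paste(genome, collapse = ""),
                       name = sprintf("sim_seed%d", params$seed))
  # A+T of the background proper: planted ORFs draw uniform sense codons,
  # so composition is only controlled outside the feature blocks; bases the
  # stop-scrub overwrote are excluded as well
  feat <- logical(L)
  for (b in blocks)
    feat[b$at:(b$at + length(b$seq) - 1L)] <- TRUE
  feat[sc$edited] <- TRUE
  bg <- genome[!feat]
  truth$background_at <-
    if (length(bg)) round(100 * mean(bg %in% c("A", "T")), 2) else NA_real_
  truth$n_background <- sum(!feat)
  truth$scrub_edited_positions <- sort(sc$edited)
  list(genome = g, truth = truth)
}

# genomic positions of an arc in reading order for the given strand
reading_positions <- function(start, end, L, strand) {
  p <- if (start <= end) start:end else c(start:L, 1:end)
  if (strand == "-") rev(p) else p
}

write_read_bases <- function(genome, positions, bases, strand) {
  if (strand == "-") genome[positions] <- unname(COMP[bases])
  else genome[positions] <- bases
  genome
}

# disrupt every >=50 aa ORF that is not planted, editing only non-feature
# bases (windows may be touched and are then re-drawn); iterate with window
# verification to a joint fixed point
scrub_genome <- function(genome, truth, params) {
  L <- params$genome_length
  protected <- logical(L)
  win_of <- integer(0)
  for (i in seq_len(nrow(truth$orfs)))
    protected[reading_positions(truth$orfs$start[i], truth$orfs$end[i], L,
                                "+")] <- TRUE
  for (i in seq_len(nrow(truth$hr_units)))
    protected[truth$hr_units$start[i]:truth$hr_units$end[i]] <- TRUE
  in_window <- integer(L)             # 0 = none, else planted-ORF row
  for (i in seq_len(nrow(truth$orfs))) {
    wp <- reading_positions(truth$orfs$window_start[i],
                            truth$orfs$window_end[i], L, "+")
    in_window[wp] <- i
    # the window's guard TAA (last three bases in coding orientation) stays
    # untouched so upstream start-extensions remain blocked
    wl <- length(wp)
    rp <- reading_positions(truth$orfs$window_start[i],
                            truth$orfs$window_end[i], L,
                            truth$orfs$strand[i])
    protected[rp[(wl - 2L):wl]] <- TRUE
  }

  truth_key <- with(truth$orfs, paste(start, end, strand))
  edited <- integer(0)
  for (iter in 1:60) {
    g <- circular_genome(paste(genome, collapse = ""))
    ann <- annotate_genome(g, min_aa = 50,
                           max_overlap_frac = 0.75)
    found_key <- with(ann$orfs, paste(start, end, strand))
    spurious <- ann$orfs[!(found_key %in% truth_key), , drop = FALSE]
    broken <- window_mismatches(genome, truth, params)
    if (nrow(spurious) == 0L && length(broken) == 0L &&
        all(truth_key %in% found_key))
      return(list(genome = genome, edited = unique(edited)))
    for (i in seq_len(nrow(spurious))) {
      rp <- reading_positions(spurious$start[i], spurious$end[i], L,
                              spurious$strand[i])
      nc <- length(rp) %/% 3L
      did_edit <- FALSE
      for (pref in 1:2) {             # pass 1 avoids windows, pass 2 allows
        ok <- integer(0)
        for (j in 2:(nc - 1L)) {
          p3 <- rp[(3L * j - 2L):(3L * j)]
          if (any(protected[p3])) next
          if (pref == 1L && any(in_window[p3] > 0L)) next
          ok <- c(ok, j)
        }
        if (length(ok)) {
          j <- if (length(ok) == 1L) ok else sample(ok, 1L)
          p3 <- rp[(3L * j - 2L):(3L * j)]
          genome <- write_read_bases(genome, p3, c("T", "A", "A"),
                                     spurious$strand[i])
          edited <- c(edited, p3)
          did_edit <- TRUE
          break
        }
      }
      if (!did_edit) {
        # fully nested in planted features: resample the host ORF's codons
        host <- which(vapply(seq_len(nrow(truth$orfs)), function(k)
          arc_overlap(spurious$start[i], spurious$end[i],
                      truth$orfs$start[k], truth$orfs$end[k], L) > 0L,
          logical(1L)))
        if (length(host) == 0L)
          stop("cannot disrupt a chance ORF inside planted repeats")
        k <- host[1L]
        rp2 <- reading_positions(truth$orfs$start[k], truth$orfs$end[k], L,
                                 truth$orfs$strand[k])
        aa <- truth$orfs$aa_length[k]
        body <- strsplit(paste(sample(SENSE_CODONS, aa - 1L,
                                      replace = TRUE), collapse = ""),
                         "")[[1L]]
        genome <- write_read_bases(genome, rp2[4:(3L * aa)], body,
                                   truth$orfs$strand[k])
      }
    }
    for (i in window_mismatches(genome, truth, params)) {
      w <- draw_window(params$window_len, truth$orfs$promoter_class[i],
                       params$at_fraction)
      rp <- reading_positions(truth$orfs$window_start[i],
                              truth$orfs$window_end[i], L,
                              truth$orfs$strand[i])
      genome <- write_read_bases(genome, rp, w, truth$orfs$strand[i])
    }
  }
  stop("could not reach a clean genome after bounded repair iterations")
}

# rows of truth$orfs whose upstream window misclassifies
window_mismatches <- function(genome, truth, params) {
  if (nrow(truth$orfs) == 0L) return(integer(0))
  g <- circular_genome(paste(genome, collapse = ""))
  bad <- integer(0)
  for (i in seq_len(nrow(truth$orfs))) {
    w <- upstream_window(g, truth$orfs$start[i], truth$orfs$end[i],
                         truth$orfs$strand[i],
                         window_len = params$window_len)
    if (classify_promoter(w)$promoter_class != truth$orfs$promoter_class[i])
      bad <- c(bad, i)
  }
  bad
}

#' Apply extra point mutations to a simulated genome
#'
#' Uniform substitutions outside the start and stop codons of planted ORFs,
#' for robustness experiments. The truth record is extended with the mutated
#' positions.
#'
#' @param genome a [circular_genome()] from [simulate_genome()].
#' @param truth the matching truth record.
#' @param extra_mutation_rate per-base substitution probability in [0, 0.2].
#' @return list with the mutated `genome` and updated `truth`.
#' @export
corrupt_genome <- function(genome, truth, extra_mutation_rate) {
  if (extra_mutation_rate < 0 || extra_mutation_rate > 0.2)
    stop("extra_mutation_rate must be in [0, 0.2]")
  L <- genome$length
  eligible <- rep(TRUE, L)
  for (i in seq_len(nrow(truth$orfs))) {
    rp <- reading_positions(truth$orfs$start[i], truth$orfs$end[i], L,
                            truth$orfs$strand[i])
    eligible[rp[1:3]] <- FALSE
    eligible[rp[(length(rp) - 2L):length(rp)]] <- FALSE
  }
  v <- strsplit(genome$sequence, "")[[1L]]
  hit <- which(eligible & stats::runif(L) < extra_mutation_rate)
  for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  truth$extra_mutated_positions <- hit
  list(genome = circular_genome(paste(v, collapse = ""),
                                name = genome$name),
       truth = truth)
}
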