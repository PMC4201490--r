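# a stop-free stretch of sense codons wrapped as ATG ... stop
make_orf_seq <- function(aa, stop = "TAA") {
  sense <- setdiff(apply(expand.grid(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G")),
                         1L, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, aa - 1L, replace = TRUE),
                      collapse = ""), stop)
}

# background that cannot hold a long ORF on either strand: the TTAA tile
# is its own reverse complement and puts a stop in every frame within a
# few codons, and contains no start triplet
stop_dense <- function(n) substr(strrep("TTAA", ceiling(n / 4) + 1), 1, n)

test_that("ORF finder honours the length threshold boundary", {
  set.seed(21)
  g <- circular_genome(paste0(stop_dense(90), make_orf_seq(50),
                              stop_dense(90)))
  f <- find_orfs(g, min_aa = 50)
  expect_equal(nrow(f), 1L)
  expect_equal(f$aa_length, 50L)
  expect_equal(f$start, 91L)
  expect_equal(f$end, 91L + 153L - 1L)
  expect_equal(nrow(find_orfs(g, min_aa = 51)), 0L)
})

test_that("ORFs crossing the origin are found with start > end", {
  set.seed(22)
  orf <- make_orf_seq(60)           # 186 bases
  g0 <- paste0(stop_dense(120), orf, stop_dense(120))
  # make a position inside the ORF the new base 1, so the ORF straddles
  # the origin
  g <- rotate_to_zero(circular_genome(g0), 200L)
  f <- find_orfs(g, min_aa = 50)
  # internal in-frame ATGs legitimately yield nested same-stop candidates;
  # the planted 60 aa frame is the longest and must wrap
  planted <- f[f$aa_length == 60L, ]
  expect_equal(nrow(planted), 1L)
  expect_gt(planted$start, planted$end)
  expect_equal(max(f$aa_length), 60L)
  # overlap resolution collapses the nest to the planted ORF
  ann <- annotate_genome(g, min_aa = 50)
  expect_equal(nrow(ann$orfs), 1L)
  expect_equal(ann$orfs$aa_length, 60L)
})

test_that("ORF finder agrees with the doubled-string enumeration oracle", {
  set.seed(23)
  g <- random_genome(20000)
  got <- find_orfs(g, min_aa = 50)
  want <- oracle_orfs(g$sequence, 50)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_equal(got$aa_length, want$aa_length)
  # smaller thresholds exercise many more candidates
  g2 <- random_genome(3000)
  got2 <- find_orfs(g2, min_aa = 10)
  want2 <- oracle_orfs(g2$sequence, 10)
  expect_equal(got2[, 1:4], want2, ignore_attr = TRUE)
})

test_that("ORF calls are rotation-invariant up to the coordinate shift", {
  set.seed(24)
  g <- random_genome(4000)
  base <- find_orfs(g, min_aa = 20)
  for (p in c(500L, 3999L)) {
    r <- find_orfs(rotate_to_zero(g, p), min_aa = 20)
    shift <- function(x) (x - p) %% 4000L + 1L
    expect_setequal(paste(shift(base$start), shift(base$end), base$strand),
                    paste(r$start, r$end, r$strand))
  }
})

test_that("overlap resolution keeps disjoint ORFs and drops nested ones", {
  L <- 1000L
  cand <- data.frame(start = c(100L, 100L), end = c(400L, 400L),
                     strand = c("+", "-"), aa_length = c(99L, 99L))
  kept <- resolve_overlaps(cand, genome_length = L)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$strand, "+")      # tie broken toward plus

  cand <- data.frame(start = c(100L, 500L), end = c(400L, 800L),
                     strand = c("+", "+"), aa_length = c(99L, 99L))
  expect_equal(nrow(resolve_overlaps(cand, genome_length = L)), 2L)
})

test_that("overlap resolution matches the quadratic position-set oracle", {
  set.seed(25)
  L <- 2000L
  for (rep in 1:4) {
    n <- 50L
    start <- sample.int(L, n)
    len <- 3L * (sample(10:80, n, replace = TRUE) + 1L)
    cand <- data.frame(start = start, end = (start + len - 2L) %% L + 1L,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       aa_length = len %/% 3L - 1L)
    got <- resolve_overlaps(cand, 0.75, genome_length = L)
    want <- oracle_resolve(cand, 0.75, L)
    expect_equal(got[, c("start", "end", "strand", "aa_length")], want,
                 ignore_attr = TRUE)
    # never grows, and idempotent
    expect_lte(nrow(got), n)
    again <- resolve_overlaps(got, 0.75, genome_length = L)
    expect_equal(got[, 1:4], again[, 1:4], ignore_attr = TRUE)
  }
})

test_that("annotation of a genome without ATG is empty", {
  g <- circular_genome(strrep("TAACCC", 50))
  tab <- annotate_genome(g)
  expect_s3_class(tab, "annotation_table")
  expect_equal(nrow(tab$orfs), 0L)
  expect_equal(unname(strand_counts(tab)), c(0L, 0L))
})

test_that("strand counts agree with a direct tally", {
  ann <- suju_annotation()
  expect_equal(strand_counts(ann), c(forward = 60L, reverse = 71L))
  expect_equal(sum(strand_counts(ann)), nrow(ann$orfs))
  expect_equal(unname(strand_counts(ann)["forward"]),
               sum(ann$orfs$strand == "+"))
})

test_that("coverage uses interval union and matches the marking oracle", {
  tab <- annotation_table("t", 1000L, data.frame(
    index = 1L, name = "a", motif = NA, start = 1L, end = 500L,
    aa_length = 100L, strand = "+"))
  expect_equal(orf_coverage(tab), 50)
  tab$orfs <- rbind(tab$orfs, tab$orfs)    # fully overlapping duplicate
  expect_equal(orf_coverage(tab), 50)

  set.seed(26)
  L <- 5000L
  n <- 40L
  start <- sample.int(L, n)
  end <- (start + sample(50:900, n, replace = TRUE)) %% L + 1L
  tab <- annotation_table("r", L, data.frame(
    index = seq_len(n), name = paste0("orf", seq_len(n)), motif = NA,
    start = start, end = end, aa_length = 0L,
    strand = sample(c("+", "-"), n, TRUE)))
  expect_equal(orf_coverage(tab),
               oracle_coverage(data.frame(start = start, end = end), L))
})
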