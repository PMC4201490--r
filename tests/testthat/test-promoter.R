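test_that("upstream windows sit 5' of the start codon on the coding strand", {
  set.seed(31)
  g <- random_genome(2000)
  # plus strand: bases start-150 .. start-1
  w <- upstream_window(g, 500L, 800L, "+")
  expect_equal(w, genome_subseq(g, 350L, 499L))
  # minus strand: reverse complement of end+1 .. end+150
  w <- upstream_window(g, 500L, 800L, "-")
  expect_equal(w, genome_subseq(g, 801L, 950L, "-"))
  # wrap across the origin
  w <- upstream_window(g, 40L, 400L, "+")
  expect_equal(w, genome_subseq(g, 1890L, 39L))
  expect_equal(nchar(w), 150L)
  # doubled-string cross-check for arbitrary windows
  dd <- paste0(g$sequence, g$sequence)
  w <- upstream_window(g, 40L, 400L, "+")
  expect_equal(w, substr(dd, 1890L, 2039L))
  expect_error(upstream_window(g, 500L, 800L, "+", window_len = 2000),
               "smaller")
})

test_that("classification follows the motif and spacer rules exactly", {
  pad <- function(n) strrep("C", n)
  # constructed early: TATAA + 25 spacer + CAGT
  w <- paste0(pad(20), "TATAA", pad(25), "CAGT", pad(60))
  r <- classify_promoter(w)
  expect_equal(r$promoter_class, "E")
  expect_equal(nrow(r$early_hits), 1L)
  expect_equal(r$early_hits$tata_start, 21L)
  expect_equal(r$early_hits$cakt_start, 51L)

  # IUPAC D matches A in the late motif
  expect_equal(classify_promoter(paste0(pad(40), "ATAAG",
                                        pad(40)))$promoter_class, "L")

  # spacer one below the minimum: no early call
  w <- paste0(pad(20), "TATAA", pad(19), "CAGT", pad(60))
  expect_equal(classify_promoter(w)$promoter_class, "none")
  # spacer exactly at the bounds
  w <- paste0(pad(20), "TATAA", pad(20), "CAGT", pad(60))
  expect_equal(classify_promoter(w)$promoter_class, "E")
  w <- paste0(pad(20), "TATAA", pad(40), "CAGT", pad(60))
  expect_equal(classify_promoter(w)$promoter_class, "E")
  w <- paste0(pad(20), "TATAA", pad(41), "CAGT", pad(60))
  expect_equal(classify_promoter(w)$promoter_class, "none")

  # both motifs present
  w <- paste0(pad(10), "TATAA", pad(25), "CATT", pad(20), "GTAAG", pad(30))
  expect_equal(classify_promoter(w)$promoter_class, "EL")

  expect_error(classify_promoter("ACGTX"), "invalid IUPAC|outside")
  expect_error(classify_promoter(""), "non-empty")
})

test_that("classifier agrees with an independent IUPAC-regex oracle", {
  set.seed(32)
  for (k in 1:1000) {
    w <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
    expect_equal(classify_promoter(w)$promoter_class, oracle_classify(w),
                 info = w)
  }
})

test_that("classification is local to the window and monotone in the spacer", {
  set.seed(33)
  g1 <- random_genome(1000)
  orf <- list(start = 400L, end = 700L, strand = "+")
  w1 <- upstream_window(g1, orf$start, orf$end, orf$strand)
  c1 <- classify_promoter(w1)$promoter_class
  # mutate everything outside the window: call unchanged
  v <- strsplit(g1$sequence, "")[[1L]]
  outside <- setdiff(seq_len(1000L), 250:399)
  v[outside] <- sample(c("A", "C", "G", "T"), length(outside), TRUE)
  g2 <- circular_genome(paste(v, collapse = ""))
  w2 <- upstream_window(g2, orf$start, orf$end, orf$strand)
  expect_equal(w2, w1)
  expect_equal(classify_promoter(w2)$promoter_class, c1)

  # widening the spacer never loses early calls
  for (k in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    narrow <- classify_promoter(w, spacer_min = 22, spacer_max = 36)
    wide <- classify_promoter(w, spacer_min = 20, spacer_max = 40)
    expect_gte(nrow(wide$early_hits), nrow(narrow$early_hits))
  }
})

test_that("whole-table classification recovers planted classes and sums", {
  p <- sim_params(genome_length = 25000, n_orfs = 14, n_hrs = 0, seed = 34)
  sim <- simulate_genome(p)
  tab <- annotate_genome(sim$genome)
  tab <- classify_promoters(sim$genome, tab)
  counts <- attr(tab, "promoter_counts")
  expect_equal(sum(counts), nrow(tab$orfs))
  tok <- c(E = "E", L = "L", EL = "E,L", none = "")
  expect_equal(tab$orfs$motif,
               unname(tok[sim$truth$orfs$promoter_class]))

  empty <- annotation_table("e", 1000L, data.frame(
    index = integer(), name = character(), motif = character(),
    start = integer(), end = integer(), aa_length = integer(),
    strand = character()))
  e2 <- classify_promoters(sim$genome, empty)
  expect_equal(sum(attr(e2, "promoter_counts")), 0L)
})
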