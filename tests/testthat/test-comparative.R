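test_that("global identity scores trivial and random cases correctly", {
  a <- "MKVLA"
  expect_equal(global_identity(a, a)$identity_percent, 100)
  expect_equal(global_identity("AAAA", "CCCC")$identity_percent, 0)
  expect_error(global_identity("", "A"), "empty")

  r <- global_identity("MKVLA", "MKQLA", alignment = TRUE)
  expect_equal(nchar(r$aligned_a), r$alignment_length)
  expect_equal(gsub("-", "", r$aligned_a), "MKVLA")
  expect_equal(gsub("-", "", r$aligned_b), "MKQLA")
})

test_that("optimal score equals exhaustive enumeration for short sequences", {
  set.seed(51)
  for (k in 1:12) {
    n <- sample.int(8L, 1); m <- sample.int(8L, 1)
    a <- paste(sample(c("A", "R", "N", "D"), n, TRUE), collapse = "")
    b <- paste(sample(c("A", "R", "N", "D"), m, TRUE), collapse = "")
    expect_equal(global_identity(a, b)$score, oracle_align_score(a, b),
                 info = paste(a, b))
  }
  # include the full 8x8 case
  a <- "ARNDARND"; b <- "RNDARNDA"
  expect_equal(global_identity(a, b)$score, oracle_align_score(a, b))
})

test_that("identity is symmetric in its arguments", {
  set.seed(52)
  for (k in 1:60) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:25, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:25, 1), TRUE),
               collapse = "")
    x <- global_identity(a, b); y <- global_identity(b, a)
    expect_equal(x$score, y$score)
    expect_equal(x$identity_percent, y$identity_percent)
  }
})

test_that("homologue pairing is one-to-one and keeps the better identity", {
  ann <- suju_annotation()
  h <- homolog_table(ann, "HearNPV")
  expect_false(any(duplicated(h$index_b)))
  expect_false(any(duplicated(h$index_a)))
  # HearNPV ordinal 77 is claimed by two ORFs; the higher identity wins
  expect_true(72L %in% h$index_a[h$index_b == 77L])
  expect_false(75L %in% h$index_a)
  expect_error(homolog_table(ann, "NoSuchVirus"), "unknown virus")
})

test_that("parity coordinates express order and inversions", {
  mk <- function(n, index_b, strand = "same") {
    structure(data.frame(index_a = seq_len(n), index_b = index_b,
                         identity = NA_real_, strand_agreement = strand),
              class = c("homolog_table", "data.frame"))
  }
  n <- 8L
  pts <- parity_coordinates(mk(n, seq_len(n)))
  expect_equal(pts$y, pts$x)
  pts <- parity_coordinates(mk(n, rev(seq_len(n)), "opposite"))
  expect_equal(pts$y, -(n + 1L - pts$x))
  set.seed(53)
  perm <- sample.int(n)
  pts <- parity_coordinates(mk(n, perm))
  expect_equal(pts$y[order(pts$x)], perm)
})

test_that("longest collinear run matches brute force and spans Suju60-86", {
  pts <- data.frame(x = 1:10, y = 1:10)
  expect_equal(longest_collinear_run(pts)$length, 10L)
  pts <- data.frame(x = 1:6, y = c(1, 40, 2, 41, 3, 42))
  expect_equal(longest_collinear_run(pts)$length, 1L)
  expect_error(longest_collinear_run(data.frame(x = integer(),
                                                y = integer())),
               "at least one point")

  ann <- suju_annotation()
  pts <- parity_coordinates(homolog_table(ann, "HearNPV"))
  run <- longest_collinear_run(pts)
  want <- oracle_longest_run(pts)
  expect_equal(run$length, want$length)
  expect_equal(run$start_x, want$start_x)
  expect_equal(run$end_x, want$end_x)
  expect_lte(run$start_x, 60L)
  expect_gte(run$end_x, 86L)

  set.seed(54)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    pts <- data.frame(x = sort(sample.int(100L, n)),
                      y = sample.int(60L, n))
    got <- longest_collinear_run(pts)
    want <- oracle_longest_run(pts)
    expect_equal(got$length, want$length)
    expect_equal(got$start_x, want$start_x)
  }
})

test_that("shared counts tally recorded homologues and identities", {
  ann <- suju_annotation()
  want <- list(AcMNPV = 103L, HearNPV = 109L, CpGV = 78L, NeleNPV = 43L,
               CuniNPV = 39L)   # independent column tallies of the fixture
  for (v in names(want)) {
    s <- shared_counts(ann, v)
    expect_equal(s$shared, want[[v]])
    pos <- ann$orfs[[paste0("pos_", v)]]
    idr <- ann$orfs[[paste0("id_", v)]]
    expect_equal(s$shared, sum(pos != "" | idr != ""))
    ids <- suppressWarnings(as.numeric(idr[idr != ""]))
    expect_equal(s$mean_identity, round(mean(ids), 1))
    expect_equal(s$shared + (nrow(ann$orfs) - s$shared), nrow(ann$orfs))
  }
  empty <- annotation_table("e", 1000L, data.frame(
    index = 1L, name = "a", motif = "", start = 1L, end = 300L,
    aa_length = 99L, strand = "+", pos_AcMNPV = "", id_AcMNPV = ""))
  s <- shared_counts(empty, "AcMNPV")
  expect_equal(s$shared, 0L)
  expect_true(is.na(s$mean_identity))
})

test_that("conservation tiers classify by name and sum to the ORF count", {
  ann <- suju_annotation()
  tiers <- suju_tiers()
  expect_length(tiers$core, 37L)
  expect_length(tiers$lepidopteran, 24L)
  expect_length(tiers$unique, 5L)
  ct <- conservation_tiers(ann, tiers)
  expect_equal(unname(ct$counts["core"]), 37L)
  expect_equal(unname(ct$counts["lepidopteran"]), 24L)
  expect_equal(unname(ct$counts["unique"]), 5L)
  expect_equal(sum(ct$counts), nrow(ann$orfs))

  empty <- annotation_table("e", 1L, data.frame(
    index = integer(), name = character(), motif = character(),
    start = integer(), end = integer(), aa_length = integer(),
    strand = character()))
  expect_equal(sum(conservation_tiers(empty, tiers)$counts), 0L)

  # collisions across tiers are rejected
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("tier\torf\tname", "core\t1\tph", "unique\t2\tph"), bad)
  expect_error(read_tiers(bad), "more than one tier")
})

test_that("name pairing records strand agreement", {
  a <- annotation_table("A", 1000L, data.frame(
    index = 1:3, name = c("x", "y", "z"), motif = "",
    start = c(1L, 101L, 201L), end = c(90L, 190L, 290L),
    aa_length = 29L, strand = c("+", "-", "+")))
  b <- annotation_table("B", 1000L, data.frame(
    index = 1:3, name = c("y", "z", "w"), motif = "",
    start = c(1L, 101L, 201L), end = c(90L, 190L, 290L),
    aa_length = 29L, strand = c("-", "-", "+")))
  h <- pair_by_names(a, b)
  expect_equal(nrow(h), 2L)
  expect_equal(h$strand_agreement, c("same", "opposite"))
})
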