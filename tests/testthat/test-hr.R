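# a perfect palindrome of the given (odd or even) length
perfect_palindrome <- function(n, at = 0.6) {
  half <- n %/% 2L
  left <- paste(sample(c("A", "T", "C", "G"), half, TRUE,
                       prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
                collapse = "")
  centre <- if (n %% 2L) "A" else ""
  paste0(left, centre, oracle_revcomp(left))
}

test_that("palindromy scores its defining cases and is strand-symmetric", {
  expect_equal(palindromy("ACGT"), 1)
  expect_equal(palindromy("AAAA"), 0)
  expect_error(palindromy(""), "empty")
  expect_error(palindromy("ACNGT"), "N")
  set.seed(41)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    expect_equal(palindromy(s), palindromy(oracle_revcomp(s)))
    expect_gte(palindromy(s), 0); expect_lte(palindromy(s), 1)
  }
})

test_that("alignment scores match Biostrings global alignment", {
  set.seed(42)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
               collapse = "")
    want <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 1,
                                          scoreOnly = TRUE)
    expect_equal(global_identity(a, b)$score, want)
  }
})

test_that("seed scanning finds planted palindromes and nothing in homopolymer", {
  set.seed(43)
  pal <- perfect_palindrome(99)
  # homopolymer flanks score palindromy 0, so the planted palindrome is the
  # only qualifying window after local-maximum merging
  g <- circular_genome(paste0(strrep("A", 1200), pal, strrep("A", 1200)))
  seeds <- find_repeat_seeds(g)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$start, 1201L)
  # an odd-length palindrome mismatches only at its centre base
  expect_equal(seeds$palindromy, 98 / 99)

  g0 <- circular_genome(strrep("A", 2000))
  expect_equal(nrow(find_repeat_seeds(g0)), 0L)
})

test_that("every planted repeat unit is overlapped by a seed", {
  p <- sim_params(genome_length = 20000, n_orfs = 4, n_hrs = 2,
                  units_per_hr_range = c(4, 5), seed = 44)
  sim <- simulate_genome(p)
  seeds <- find_repeat_seeds(sim$genome)
  for (i in seq_len(nrow(sim$truth$hr_units))) {
    u <- sim$truth$hr_units[i, ]
    expect_true(any(seeds$start <= u$end & seeds$end >= u$start),
                info = paste("unit at", u$start))
  }
})

test_that("clustering recovers planted arrays: copies, bounds, orientations", {
  p <- sim_params(genome_length = 20000, n_orfs = 4, n_hrs = 2,
                  units_per_hr_range = c(4, 5), seed = 44)
  sim <- simulate_genome(p)
  prof <- cluster_hrs(find_repeat_seeds(sim$genome), sim$genome)
  tr <- sim$truth
  expect_equal(nrow(prof$regions), nrow(tr$hrs))
  expect_equal(prof$regions$copy_number, tr$hrs$copy_number)
  expect_lte(max(abs(prof$regions$start - tr$hrs$start)), 99)
  expect_lte(max(abs(prof$regions$end - tr$hrs$end)), 99)
  expect_lte(max(abs(sort(prof$units$start) - sort(tr$hr_units$start))), 2)
  # regions are mutually disjoint and cover less than the genome
  expect_lte(sum(prof$regions$length), sim$genome$length)
  ir <- IRanges::IRanges(prof$regions$start, prof$regions$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
               sum(IRanges::width(ir)))
})

test_that("mutation-free arrays are recovered base-exactly", {
  p <- sim_params(genome_length = 20000, n_orfs = 5, n_hrs = 2,
                  units_per_hr_range = c(4, 5), unit_mutation_rate = 0,
                  seed = 3)
  sim <- simulate_genome(p)
  prof <- cluster_hrs(find_repeat_seeds(sim$genome), sim$genome)
  expect_equal(sort(prof$units$start), sort(sim$truth$hr_units$start))
  expect_equal(sort(prof$units$end), sort(sim$truth$hr_units$end))
  # orientations agree exactly, up to one global strand flip
  m <- merge(prof$units[, c("start", "orientation")],
             sim$truth$hr_units[, c("start", "orientation")], by = "start")
  agree <- mean(m$orientation.x == m$orientation.y)
  expect_true(agree %in% c(0, 1))
  # family identity at mutation zero matches the Hamming oracle
  got <- repeat_identity(prof$units$sequence)
  want <- oracle_hamming_min_mean(prof$units$sequence)
  expect_equal(got$min_pairwise, want$min)
  expect_equal(got$mean_pairwise, want$mean)
})

test_that("isolated seeds below the copy floor yield no region", {
  set.seed(45)
  pal <- perfect_palindrome(99)
  g <- circular_genome(paste0(strrep("A", 2000), pal, strrep("A", 2000)))
  seeds <- find_repeat_seeds(g)
  prof <- cluster_hrs(seeds, g, min_copies = 2)
  expect_equal(nrow(prof$regions), 0L)
  expect_equal(prof$genome_coverage_percent, 0)
})

test_that("hr summary statistics follow the end-minus-start convention", {
  ann <- suju_annotation()
  st <- hr_stats(ann$hrs, ann$genome_length)
  expect_equal(st$n_regions, 7L)
  expect_equal(st$min_length, 590L)
  expect_equal(st$max_length, 971L)
  expect_equal(st$coverage_percent, 3.7)

  one <- data.frame(label = "hr1", start = 1L, end = 1L + 250L)
  expect_equal(hr_stats(one, 10000L)$lengths, 250L)
})

test_that("pairwise identity and core palindrome behave on constructed families", {
  u <- strrep("ACGTT", 20)
  expect_equal(repeat_identity(c(u, u)),
               list(min_pairwise = 100, mean_pairwise = 100))
  expect_error(repeat_identity(u), "two repeat units")

  core <- core_palindrome(c(u, u))
  expect_equal(core$consensus, u)
  expect_equal(core$offset, 1L)

  # units differing only in the first 10 columns: run excludes exactly them
  set.seed(46)
  base <- strsplit(strrep("ACGTT", 20), "")[[1L]]
  v1 <- base; v2 <- base
  v2[1:10] <- ifelse(base[1:10] == "A", "C", "A")
  core <- core_palindrome(c(paste(v1, collapse = ""),
                            paste(v2, collapse = "")))
  expect_equal(core$offset, 11L)
  expect_equal(core$length, 90L)

  # planted mutation-free centre inside mutated flanks
  centre <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  mk <- function() {
    fl <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    paste0(fl(30), centre, fl(29))
  }
  fam <- replicate(6, mk())
  core <- core_palindrome(fam, min_conservation = 0.99)
  expect_gte(core$offset, 1L)
  expect_true(core$offset <= 31 && core$offset + core$length - 1 >= 70)
})

test_that("detection is invariant under rotation and reverse complement", {
  p <- sim_params(genome_length = 15000, n_orfs = 3, n_hrs = 2,
                  units_per_hr_range = c(3, 4), seed = 47)
  sim <- simulate_genome(p)
  g <- sim$genome
  L <- g$length
  base <- cluster_hrs(find_repeat_seeds(g), g)

  rot <- rotate_to_zero(g, 5000L)
  prot <- cluster_hrs(find_repeat_seeds(rot), rot)
  expect_equal(nrow(prot$regions), nrow(base$regions))
  shift <- function(x) (x - 5000L) %% L + 1L
  expect_setequal(shift(base$units$start), prot$units$start)

  rc <- circular_genome(revcomp(g$sequence))
  prc <- cluster_hrs(find_repeat_seeds(rc), rc)
  expect_equal(nrow(prc$regions), nrow(base$regions))
  mirror <- function(x) L - x + 1L
  expect_setequal(mirror(base$units$end), prc$units$start)
})
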