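#' Homologue pairing from an annotation table's homologue columns
#'
#' Published baculovirus annotation tables record, for each ORF, the ordinal
#' position of its homologue in reference genomes plus the percent amino-acid
#' identity. This builds a one-to-one pairing for one reference virus:
#' homologue positions are parsed from their leading integer (entries such as
#' ranges or names yield no usable ordinal and are skipped); when two ORFs
#' claim the same homologue, the pair with the higher recorded identity wins
#' (ties: the smaller ORF index).
#'
#' @param annotation an `annotation_table` carrying `pos_<virus>` /
#'   `id_<virus>` columns.
#' @param virus reference virus label, e.g. `"HearNPV"`.
#' @return a `homolog_table`: data.frame `index_a`, `index_b`, `identity`,
#'   `strand_agreement`, with attributes `genome_a`, `genome_b`.
#' @export
homolog_table <- function(annotation, virus) {
  stopifnot(inherits(annotation, "annotation_table"))
  orfs <- annotation$orfs
  pc <- paste0("pos_", virus); ic <- paste0("id_", virus)
  if (!pc %in% names(orfs)) stop("unknown virus label: ", virus)
  posraw <- as.character(orfs[[pc]])
  idraw <- suppressWarnings(as.numeric(as.character(orfs[[ic]])))
  posnum <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", posraw)))
  posnum[is.na(posraw) | posraw == ""] <- NA_integer_
  ok <- !is.na(posnum)
  df <- data.frame(index_a = orfs$index[ok], index_b = posnum[ok],
                   identity = idraw[ok], stringsAsFactors = FALSE)
  # enforce one-to-one on index_b: keep the better-identity claimant
  df <- df[order(df$index_b, -ifelse(is.na(df$identity), -Inf, df$identity),
                 df$index_a), , drop = FALSE]
  df <- df[!duplicated(df$index_b), , drop = FALSE]
  df <- df[order(df$index_a), , drop = FALSE]
  df$strand_agreement <- "same"
  rownames(df) <- NULL
  structure(df, class = c("homolog_table", "data.frame"),
            genome_a = annotation$genome_name, genome_b = virus)
}

#' Pair two annotations by gene name
#'
#' Alternative pairing route for two annotation tables that share gene
#' names; strand agreement is recorded from the two strand columns.
#'
#' @param table_a,table_b `annotation_table` objects.
#' @return a `homolog_table` (see [homolog_table()]).
#' @export
pair_by_names <- function(table_a, table_b) {
  a <- table_a$orfs; b <- table_b$orfs
  m <- match(a$name, b$name)
  ok <- !is.na(m) & !duplicated(m)
  df <- data.frame(index_a = a$index[ok], index_b = b$index[m[ok]],
                   identity = NA_real_,
                   strand_agreement = ifelse(a$strand[ok] == b$strand[m[ok]],
                                             "same", "opposite"),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("homolog_table", "data.frame"),
            genome_a = table_a$genome_name, genome_b = table_b$genome_name)
}

#' Gene-parity coordinates
#'
#' One point per homologue pair: `x` is the gene's ordinal in genome A,
#' `y` the signed ordinal in genome B (negative when the strands disagree).
#' Diagonal stretches of the resulting scatter indicate conserved gene order
#' (collinearity).
#'
#' @param homologs a `homolog_table`.
#' @return data.frame `x`, `y` sorted by ascending `x`.
#' @export
parity_coordinates <- function(homologs) {
  stopifnot(inherits(homologs, "homolog_table"))
  pts <- data.frame(
    x = homologs$index_a,
    y = ifelse(homologs$strand_agreement == "opposite",
               -homologs$index_b, homologs$index_b))
  pts <- pts[order(pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Longest collinear run in a gene-parity plot
#'
#' The longest stretch of successive parity points whose `y` values are
#' monotone with steps of at most `max_jump` in absolute difference;
#' `max_jump = 2` tolerates the single-gene inversions and drifts seen
#' between related baculovirus genomes. Ties are broken toward the smaller
#' starting `x`.
#'
#' @param points data.frame from [parity_coordinates()].
#' @param max_jump largest tolerated |y step| between successive points.
#' @return list with `start_x`, `end_x`, `length` (number of points) and
#'   `points` (the run itself).
#' @export
longest_collinear_run <- function(points, max_jump = 2) {
  if (nrow(points) == 0L) stop("at least one point is required")
  pts <- points[order(points$x), , drop = FALSE]
  n <- nrow(pts)
  up <- dn <- rep(1L, n)
  for (i in seq_len(n)[-1L]) {
    dy <- pts$y[i] - pts$y[i - 1L]
    if (dy > 0 && dy <= max_jump) up[i] <- up[i - 1L] + 1L
    if (dy < 0 && -dy <= max_jump) dn[i] <- dn[i - 1L] + 1L
  }
  best <- pmax(up, dn)
  len <- max(best)
  ends <- which(best == len)
  starts_x <- pts$x[ends - len + 1L]
  e <- ends[which.min(starts_x)]
  run <- pts[(e - len + 1L):e, , drop = FALSE]
  rownames(run) <- NULL
  list(start_x = run$x[1L], end_x = run$x[len], length = len, points = run)
}

#' Shared-gene count and mean identity for one reference virus
#'
#' An ORF is shared when the annotation records a homologue for that virus
#' (a position, an identity, or both); the mean identity averages only rows
#' with a recorded identity.
#'
#' @inheritParams homolog_table
#' @return list with `shared`, `mean_identity` (one decimal; `NA` when no
#'   identity is recorded) and `n_identity`.
#' @export
shared_counts <- function(annotation, virus) {
  stopifnot(inherits(annotation, "annotation_table"))
  orfs <- annotation$orfs
  pc <- paste0("pos_", virus); ic <- paste0("id_", virus)
  if (!pc %in% names(orfs) || !ic %in% names(orfs))
    stop("unknown virus label: ", virus)
  pos <- as.character(orfs[[pc]]); idr <- as.character(orfs[[ic]])
  pos[is.na(pos)] <- ""; idr[is.na(idr)] <- ""
  shared <- sum(pos != "" | idr != "")
  ids <- suppressWarnings(as.numeric(idr[idr != ""]))
  list(shared = shared,
       mean_identity = if (length(ids)) round(mean(ids), 1) else NA_real_,
       n_identity = length(ids))
}

#' Read conservation-tier gene lists
#'
#' @param path TSV with columns `tier` (`core`, `lepidopteran`, `unique`),
#'   `orf` and `name`; `#` lines are comments.
#' @return list of character vectors `core`, `lepidopteran`, `unique`.
#' @export
read_tiers <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  tiers <- split(df$name, df$tier)[c("core", "lepidopteran", "unique")]
  all_names <- unlist(tiers)
  if (anyDuplicated(all_names))
    stop("gene name(s) present in more than one tier: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  tiers
}

#' Classify annotated ORFs into conservation tiers
#'
#' Each ORF is classified by name matching against the packaged tier lists:
#' `core` (present in all completely sequenced baculovirus genomes),
#' `lepidopteran` (conserved in lepidopteran baculoviruses), `unique`
#' (taken from the packaged list of genome-specific genes, not computed) or
#' `common` otherwise.
#'
#' @param annotation an `annotation_table`.
#' @param tiers list from [read_tiers()] / [suju_tiers()].
#' @return list with `counts` (named: core, lepidopteran, common, unique)
#'   and `tier` (character vector, one entry per ORF).
#' @export
conservation_tiers <- function(annotation, tiers) {
  stopifnot(inherits(annotation, "annotation_table"))
  nm <- annotation$orfs$name
  tier <- rep("common", length(nm))
  tier[nm %in% tiers$core] <- "core"
  tier[nm %in% tiers$lepidopteran] <- "lepidopteran"
  tier[nm %in% tiers$unique] <- "unique"
  counts <- c(core = sum(tier == "core"),
              lepidopteran = sum(tier == "lepidopteran"),
              common = sum(tier == "common"),
              unique = sum(tier == "unique"))
  list(counts = counts, tier = tier)
}

#' Plot a gene-parity scatter
#'
#' @param points data.frame from [parity_coordinates()].
#' @param run optional result of [longest_collinear_run()], highlighted.
#' @param ... passed to [plot()].
#' @export
plot_parity <- function(points, run = NULL, ...) {
  plot(points$x, points$y, pch = 20, xlab = "gene ordinal, genome A",
       ylab = "signed gene ordinal, genome B", ...)
  abline(h = 0, col = "grey70", lty = 2)
  if (!is.null(run))
    points(run$points$x, run$points$y, pch = 20, col = "red3")
  invisible(points)
}
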