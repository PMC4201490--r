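#' Read an annotation table in the published TSV dialect
#'
#' The dialect mirrors published baculovirus annotation tables: columns
#' `orf`, `name`, `motif`, `start`, `end`, `length_aa`, `strand`, a block of
#' homologue positions (`pos_<virus>`) and a block of identities
#' (`id_<virus>`). Homologous-region rows carry a blank `orf` field and a
#' label plus `start`/`end` only. `#` lines are comments. Rows whose printed
#' amino-acid length disagrees with `span/3 - 1` are kept but flagged with a
#' warning (attribute `aa_inconsistent`).
#'
#' @param path TSV file.
#' @param genome_name,genome_length genome identity carried on the table
#'   (the dialect itself does not store them).
#' @return an `annotation_table`.
#' @export
read_annotation <- function(path, genome_name = "genome",
                            genome_length = NA_integer_) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("orf", "name", "motif", "start", "end", "length_aa", "strand")
  if (!all(need %in% names(df)))
    stop("not in the annotation dialect; missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[is.na(df)] <- ""
  is_hr <- df$orf == ""
  bad <- which(!is_hr & (df$start == "" | df$end == ""))
  if (length(bad))
    stop("malformed row(s) at line ", paste(bad, collapse = ", "),
         ": missing coordinates")
  orfs <- df[!is_hr, , drop = FALSE]
  orfs_out <- data.frame(
    index = as.integer(orfs$orf), name = orfs$name, motif = orfs$motif,
    start = as.integer(orfs$start), end = as.integer(orfs$end),
    aa_length = as.integer(orfs$length_aa), strand = orfs$strand,
    stringsAsFactors = FALSE)
  for (cn in grep("^(pos|id)_", names(df), value = TRUE))
    orfs_out[[cn]] <- orfs[[cn]]
  hrs <- df[is_hr, , drop = FALSE]
  hrs_out <- data.frame(label = hrs$name, start = as.integer(hrs$start),
                        end = as.integer(hrs$end), stringsAsFactors = FALSE)
  span <- orfs_out$end - orfs_out$start + 1L
  inconsistent <- span %% 3L != 0L | span %/% 3L - 1L != orfs_out$aa_length
  if (any(inconsistent))
    warning("printed aa length inconsistent with coordinates for: ",
            paste(orfs_out$name[inconsistent], collapse = ", "))
  tab <- annotation_table(genome_name = genome_name,
                          genome_length = genome_length,
                          orfs = orfs_out, hrs = hrs_out)
  attr(tab, "aa_inconsistent") <- orfs_out$name[inconsistent]
  tab
}

#' Write an annotation table in the published TSV dialect
#'
#' Round-trips with [read_annotation()].
#'
#' @param table an `annotation_table`.
#' @param path output file.
#' @export
write_annotation <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  orfs <- table$orfs
  homcols <- grep("^(pos|id)_", names(orfs), value = TRUE)
  out <- data.frame(orf = as.character(orfs$index), name = orfs$name,
                    motif = ifelse(is.na(orfs$motif), "", orfs$motif),
                    start = orfs$start, end = orfs$end,
                    length_aa = orfs$aa_length, strand = orfs$strand,
                    stringsAsFactors = FALSE)
  for (cn in homcols) out[[cn]] <- orfs[[cn]]
  if (nrow(table$hrs)) {
    hr <- data.frame(orf = "", name = table$hrs$label, motif = "",
                     start = table$hrs$start, end = table$hrs$end,
                     length_aa = "", strand = "", stringsAsFactors = FALSE)
    for (cn in homcols) hr[[cn]] <- ""
    out <- rbind(out, hr)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GRanges for the annotation, splitting origin-spanning features into two
# parts that share an ID
annotation_granges <- function(table) {
  L <- table$genome_length
  rows <- list()
  add <- function(start, end, strand, type, id, name) {
    pieces <- arc_pieces(start, end, L)
    phase <- rep(NA_integer_, length(pieces))
    if (type == "CDS") {
      # phase: bases to skip in this piece to reach a codon start; the
      # 5'-most piece of the reading frame is phase 0
      if (length(pieces) == 1L) phase <- 0L
      else {
        first <- if (strand == "+") 1L else 2L
        len1 <- pieces[[first]][2L] - pieces[[first]][1L] + 1L
        phase[first] <- 0L
        phase[-first] <- (3L - len1 %% 3L) %% 3L
      }
    }
    for (k in seq_along(pieces))
      rows[[length(rows) + 1L]] <<- data.frame(
        start = pieces[[k]][1L], end = pieces[[k]][2L], strand = strand,
        type = type, ID = id, Name = name, phase = phase[k],
        stringsAsFactors = FALSE)
  }
  o <- table$orfs
  for (i in seq_len(nrow(o)))
    add(o$start[i], o$end[i], o$strand[i], "CDS",
        paste0("cds-", o$index[i]), o$name[i])
  h <- table$hrs
  for (i in seq_len(nrow(h)))
    add(h$start[i], h$end[i], "+", "repeat_region",
        paste0("hr-", i), h$label[i])
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = table$genome_name,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type; gr$ID <- df$ID; gr$Name <- df$Name
  gr$phase <- df$phase
  if (!is.na(L))
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(L, table$genome_name)
  gr
}

#' Write an annotation as GFF3
#'
#' One CDS feature per ORF and one repeat_region per hr, 1-based inclusive.
#' Origin-spanning features are written as two parts sharing one `ID`
#' attribute.
#'
#' @param table an `annotation_table`.
#' @param path output file.
#' @export
write_gff3 <- function(table, path) {
  stopifnot(inherits(table, "annotation_table"))
  gr <- annotation_granges(table)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write homologous regions as BED
#'
#' BED is 0-based half-open; the conversion from the package's 1-based
#' inclusive coordinates is handled by the exporter. Origin-spanning regions
#' are written as two lines sharing one name.
#'
#' @param x an `hr_profile` or an `annotation_table` with hr rows.
#' @param path output file.
#' @param genome_name sequence name for the BED records.
#' @export
write_hr_bed <- function(x, path, genome_name = NULL) {
  if (inherits(x, "hr_profile")) {
    reg <- x$regions; L <- x$genome_length
    if (is.null(genome_name)) genome_name <- "genome"
  } else {
    reg <- data.frame(label = x$hrs$label, start = x$hrs$start,
                      end = x$hrs$end)
    L <- x$genome_length
    if (is.null(genome_name)) genome_name <- x$genome_name
  }
  rows <- list()
  for (i in seq_len(nrow(reg)))
    for (p in arc_pieces(reg$start[i], reg$end[i], L))
      rows[[length(rows) + 1L]] <- data.frame(start = p[1L], end = p[2L],
                                              name = reg$label[i])
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(genome_name, IRanges::IRanges(df$start, df$end),
                               name = df$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Machine-readable genome summary
#'
#' Collects the headline quantities of an annotation run in one list:
#' genome length, composition, ORF count and strand split, promoter-class
#' counts, conservation-tier counts, hr count and coverage. Written as JSON
#' when `path` is given.
#'
#' @param table an `annotation_table`.
#' @param composition optional result of [genome_composition()].
#' @param tiers optional result of [conservation_tiers()].
#' @param hr_profile optional `hr_profile`; when absent the table's hr rows
#'   are summarised instead (if any).
#' @param path optional JSON output file.
#' @return the summary, invisibly when written to `path`.
#' @export
genome_report <- function(table, composition = NULL, tiers = NULL,
                          hr_profile = NULL, path = NULL) {
  stopifnot(inherits(table, "annotation_table"))
  sc <- strand_counts(table)
  rep <- list(genome_name = table$genome_name,
              genome_length = table$genome_length,
              orf_count = nrow(table$orfs),
              forward = unname(sc["forward"]),
              reverse = unname(sc["reverse"]))
  if (!is.null(composition)) rep$at_percent <- composition$at_percent
  pc <- attr(table, "promoter_counts")
  if (!is.null(pc)) rep$promoter_counts <- as.list(pc)
  if (!is.null(tiers)) rep$tier_counts <- as.list(tiers$counts)
  if (!is.null(hr_profile)) {
    rep$hr_count <- nrow(hr_profile$regions)
    rep$hr_coverage_percent <- hr_profile$genome_coverage_percent
  } else if (nrow(table$hrs)) {
    st <- hr_stats(table$hrs, table$genome_length)
    rep$hr_count <- st$n_regions
    rep$hr_coverage_percent <- st$coverage_percent
  } else {
    rep$hr_count <- 0L
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}

#' Packaged SujuNPV annotation
#'
#' The published annotation of the Sucra jujuba nucleopolyhedrovirus genome
#' (GenBank KJ676450; 135,952 bp): 131 ORFs and 7 homologous regions, with
#' homologue positions and identities for five reference baculoviruses.
#'
#' @return an `annotation_table`.
#' @export
suju_annotation <- function() {
  path <- system.file("extdata", "suju_annotation.tsv",
                      package = "baculannot", mustWork = TRUE)
  suppressWarnings(read_annotation(path, genome_name = "SujuNPV",
                                   genome_length = 135952L))
}

#' Packaged SujuNPV conservation tiers
#'
#' The published gene-function classification: 37 baculovirus core genes,
#' 24 lepidopteran-baculovirus-conserved genes and the 5 SujuNPV-unique
#' genes.
#'
#' @return list of character vectors `core`, `lepidopteran`, `unique`.
#' @export
suju_tiers <- function() {
  read_tiers(system.file("extdata", "suju_tiers.tsv",
                         package = "baculannot", mustWork = TRUE))
}
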