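#' Partition a reference genome into fixed-size sub-regions
#'
#' Tiles every contig left-to-right with non-overlapping windows of
#' `region_size` bases. These sub-regions are the atomic unit of all
#' similarity scoring. A trailing remainder window is kept when it is at
#' least `k` bases long (so it can contribute at least one k-mer) and
#' dropped otherwise; this retains subtelomeric sequence without creating
#' unscorable regions.
#'
#' Coordinates are 0-based half-open throughout, matching the BED
#' convention used on disk.
#'
#' @param contig_lengths named integer vector (or named list) of contig
#'   lengths, e.g. from [read_fai()].
#' @param region_size window size in bases (default 2000).
#' @param k k-mer length the regions will be scored with (default 21);
#'   must not exceed `region_size`.
#' @param subgenome optional named character vector tagging contigs with a
#'   sub-genome label (e.g. parental origin); recycled onto the regions.
#' @return A data.frame with columns `contig`, `start`, `end`, `id`
#'   (`"contig:start-end"`) and `subgenome`, ordered by (contig order,
#'   start).
#' @examples
#' partition_reference(c(chrI = 5000), region_size = 2000)
#' @export
partition_reference <- function(contig_lengths, region_size = 2000L,
                                k = 21L, subgenome = NULL) {
  region_size <- as.integer(region_size)
  k <- as.integer(k)
  if (is.na(region_size) || region_size < 1L) stop("region_size must be >= 1")
  if (region_size < k) stop("region_size must be >= k")
  lens <- unlist(contig_lengths)
  if (is.null(names(lens)) || any(!nzchar(names(lens)))) {
    stop("contig_lengths must be named by contig")
  }
  out <- lapply(names(lens), function(ctg) {
    len <- as.integer(lens[[ctg]])
    if (len < k) return(NULL)
    starts <- seq.int(0L, len - 1L, by = region_size)
    ends <- pmin(starts + region_size, len)
    keep <- (ends - starts) >= k
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(NULL)
    data.frame(contig = ctg, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  df <- if (length(out)) {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  } else {
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  }
  df$id <- sprintf("%s:%d-%d", df$contig, df$start, df$end)
  df$subgenome <- if (is.null(subgenome)) {
    rep(NA_character_, nrow(df))
  } else {
    unname(subgenome[df$contig])
  }
  df
}

#' Write / read sub-regions as BED
#'
#' BED3+1 (contig, start, end, id), 0-based half-open, with an optional
#' fifth column holding the sub-genome tag. Commented `#` header lines are
#' written and skipped on read.
#'
#' @param regions data.frame as produced by [partition_reference()].
#' @param path file path.
#' @param header optional character vector of extra header lines (without
#'   leading `#`).
#' @return `write_bed` returns `path` invisibly; `read_bed` the regions
#'   data.frame.
#' @export
write_bed <- function(regions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s", c(sprintf("kpaint bed v%s",
                                      utils::packageVersion("kpaint")),
                              header)), con)
  cols <- c("contig", "start", "end", "id")
  df <- regions[, cols, drop = FALSE]
  if (!all(is.na(regions$subgenome))) df$subgenome <- regions$subgenome
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("contig", "start", "end", "id",
                                 "subgenome")[1:max(count.fields(
                                   path, sep = "\t", comment.char = "#"))],
                   fill = TRUE)
  if (is.null(df$id)) df$id <- sprintf("%s:%d-%d", df$contig, df$start, df$end)
  if (is.null(df$subgenome)) df$subgenome <- NA_character_
  df
}

#' Read contig lengths from a FASTA index (.fai) style table
#'
#' Only the first two columns (name, length) are used, so any two-column
#' TSV works as well.
#'
#' @param path path to a `.fai` (or name/length TSV) file.
#' @return named integer vector of contig lengths.
#' @export
read_fai <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(df[[2]]), df[[1]])
}

#' Contig lengths of an in-memory genome
#'
#' @param genome named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else {
    setNames(nchar(genome), names(genome))
  }
}
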