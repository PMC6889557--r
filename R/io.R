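# Shared file-format helpers. Sequence I/O goes through Biostrings; SAM
# reading goes through Rsamtools/GenomicAlignments. Genomes travel in R as
# named character vectors (one element per contig) for cheap substring work.

#' Read / write genomes as FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome` returns a named character vector of contig
#'   sequences (uppercased); `write_genome` returns `path` invisibly.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_genome
#' @param genome named character vector of contig sequences.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Writes a minimal valid SAM file (header `@HD`/`@SQ` lines plus one record
#' per read) from a data.frame of alignments such as produced by
#' [simulate_reads()].
#'
#' @param reads data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based leftmost), `mapq`, `cigar`, `seq`.
#' @param contig_lengths named integer vector naming the reference contigs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(unlist(contig_lengths)))), con)
  if (nrow(reads)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       reads$qname, as.integer(reads$flag), reads$rname,
                       as.integer(reads$pos), as.integer(reads$mapq),
                       reads$cigar, reads$seq), con)
  }
  invisible(path)
}

# Read a SAM (or BAM) file into a GAlignments object with sequences,
# dropping unmapped, secondary and supplementary records. SAM text is
# converted through Rsamtools::asBam in a temporary directory.
.read_alignments <- function(path) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    suppressMessages(Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                      indexDestination = FALSE))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "seq")
  GenomicAlignments::readGAlignments(bam, param = param)
}

# TSV writing with a reproducible '#' comment header recording the tool
# version, the writing operation and its parameters.
.format_header <- function(op, params = list()) {
  pstr <- if (length(params)) {
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         character(1))), collapse = " ")
  } else ""
  c(sprintf("kpaint v%s", utils::packageVersion("kpaint")),
    sprintf("op=%s %s", op, pstr))
}

#' Write a data.frame as TSV with a comment header
#'
#' All kpaint outputs share this layout: `#`-prefixed header lines carrying
#' the tool version, operation and parameters, then a column-named TSV body.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param op operation name recorded in the header.
#' @param params named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(df, path, op = "table", params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s", .format_header(op, params)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a kpaint TSV (skipping comment header lines)
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_output <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write a sample-to-lineage map
#'
#' Two-column TSV (`sample`, `lineage`), the standard way to attach
#' previously defined population lineages to panel strains.
#'
#' @param path file path.
#' @return `read_lineage_map` returns a named character vector mapping
#'   sample to lineage.
#' @export
read_lineage_map <- function(path) {
  df <- read_tsv_output(path)
  if (ncol(df) < 2) df <- read.table(path, sep = "\t", comment.char = "#",
                                     stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), df[[1]])
}

#' @rdname read_lineage_map
#' @param lineage_map named character vector (names = samples).
#' @export
write_lineage_map <- function(lineage_map, path) {
  write_tsv_output(data.frame(sample = names(lineage_map),
                              lineage = unname(lineage_map),
                              stringsAsFactors = FALSE),
                   path, op = "lineage_map")
}
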