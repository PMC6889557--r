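# Read-depth based chromosome/gene copy-number estimation and
# heterozygous-SNP filtering.

#' Median read depth in non-overlapping windows
#'
#' Summarises per-base depth into medians over fixed windows (default
#' 100 bases), the smoothing step ahead of copy-number estimation. The
#' trailing partial window is included; an even number of values gives the
#' mean of the two middle values, the usual median convention.
#'
#' @param depths named list of per-base depth vectors (one per contig), or
#'   a single numeric vector (treated as one contig).
#' @param w window size in bases (default 100).
#' @return A `coverage_track`: named list of data.frames with 0-based
#'   half-open `start`, `end` and `median` columns.
#' @export
window_medians <- function(depths, w = 100L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be a positive integer")
  if (!is.list(depths)) depths <- list(contig = depths)
  track <- lapply(depths, function(d) {
    n <- length(d)
    if (n == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        median = numeric(0)))
    }
    starts <- seq.int(0L, n - 1L, by = w)
    ends <- pmin(starts + w, n)
    med <- vapply(seq_along(starts), function(i)
      median(d[(starts[i] + 1L):ends[i]]), 0)
    data.frame(start = starts, end = ends, median = med)
  })
  structure(track, class = "coverage_track")
}

#' Chromosome copy number from relative coverage
#'
#' Takes the median of window medians per contig and scales it against the
#' contig with the smallest positive median, which is assumed to be present
#' at `baseline_ploidy` copies. Copy numbers are rounded to the nearest
#' integer (floored at 0), so a contig at twice the baseline coverage is
#' called at twice the baseline ploidy.
#'
#' @param track a `coverage_track` from [window_medians()].
#' @param baseline_ploidy copy number attributed to the least-covered
#'   contig (default 1).
#' @return named integer vector of per-contig copy numbers.
#' @export
chromosome_copy_number <- function(track, baseline_ploidy = 1L) {
  med <- vapply(track, function(t) median(t$median), 0)
  pos <- med[med > 0]
  if (!length(pos)) stop("no contig with positive median coverage")
  base <- min(pos)
  setNames(pmax(0L, as.integer(round(baseline_ploidy * med / base))),
           names(track))
}

#' Segment a coverage track into fixed-copy-number regions
#'
#' Assigns every window an integer copy number (window median scaled by
#' the per-copy baseline coverage) and merges runs of windows with the
#' same level into regions, reporting each region's mean and standard
#' deviation of window medians. These region statistics are the null
#' distribution that [gene_copy_deviation()] tests genes against; they can
#' equally be supplied from an external table of pre-defined regions.
#'
#' @param track a `coverage_track`.
#' @param per_copy_depth depth contributed by one chromosome copy; when
#'   `NULL` (default) it is estimated as the median of the lowest positive
#'   coverage level among windows (windows within 1.5x of the smallest
#'   positive window median) divided by `baseline_ploidy`.
#' @param baseline_ploidy copy number attributed to the lowest coverage
#'   level (default 1).
#' @return data.frame with `contig`, `start`, `end`, `copy_number`,
#'   `mean`, `sd` (sd is `NA` for single-window regions).
#' @export
region_stats_from_track <- function(track, per_copy_depth = NULL,
                                    baseline_ploidy = 1L) {
  if (is.null(per_copy_depth)) {
    meds <- unlist(lapply(track, function(t) t$median), use.names = FALSE)
    pos <- meds[meds > 0]
    if (!length(pos)) stop("no window with positive median coverage")
    per_copy_depth <- median(pos[pos <= 1.5 * min(pos)]) / baseline_ploidy
  }
  per_copy <- per_copy_depth
  out <- lapply(names(track), function(ctg) {
    t <- track[[ctg]]
    if (!nrow(t)) return(NULL)
    cn <- pmax(0L, as.integer(round(t$median / per_copy)))
    r <- rle(cn)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    data.frame(
      contig = ctg,
      start = t$start[idx_start],
      end = t$end[idx_end],
      copy_number = r$values,
      mean = vapply(seq_along(r$values), function(i)
        mean(t$median[idx_start[i]:idx_end[i]]), 0),
      sd = vapply(seq_along(r$values), function(i)
        stats::sd(t$median[idx_start[i]:idx_end[i]]), 0),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Z-test for gene copy-number deviation
#'
#' Compares a gene's mean coverage against the mean and standard deviation
#' of the surrounding fixed-copy-number region with an uncorrected Z-test:
#' `z = (gene_mean - region_mean) / region_sd`, two-sided normal p-value.
#' Genes in zero-variance regions cannot be tested and are flagged. Both
#' coverage gains and losses are of interest, hence the two-sided test.
#'
#' @param gene_mean numeric vector of gene mean coverages.
#' @param region_mean,region_sd region statistics (recycled against
#'   `gene_mean`), e.g. from [region_stats_from_track()].
#' @param alpha significance level for the `deviating` flag (default 0.05,
#'   uncorrected).
#' @return data.frame with `z`, `p`, `deviating` and `testable` columns.
#' @examples
#' gene_copy_deviation(30, 20, 5)  # z = 2, p ~ 0.0455
#' @export
gene_copy_deviation <- function(gene_mean, region_mean, region_sd,
                                alpha = 0.05) {
  n <- max(length(gene_mean), length(region_mean), length(region_sd))
  gene_mean <- rep_len(gene_mean, n)
  region_mean <- rep_len(region_mean, n)
  region_sd <- rep_len(region_sd, n)
  testable <- !is.na(region_sd) & region_sd > 0
  z <- ifelse(testable, (gene_mean - region_mean) / region_sd, NA_real_)
  p <- 2 * pnorm(-abs(z))
  data.frame(z = z, p = p,
             deviating = !is.na(p) & p < alpha,
             testable = testable)
}

#' Filter heterozygous SNP calls
#'
#' Removes the classic false-positive classes from a heterozygous SNP
#' list: calls within `end_excl` bases of either chromosome end, calls
#' whose minor-allele frequency is below `min_maf`, and calls with read
#' depth below `min_depth`. Thresholds are exclusive ("below" removes),
#' so a SNP exactly at the MAF or depth floor is retained.
#'
#' @param snps data.frame with columns `contig`, `pos` (1-based), `maf`
#'   (minor-allele frequency in `[0, 0.5]`) and `depth`; extra columns are
#'   carried through.
#' @param contig_lengths named integer vector of contig lengths.
#' @param end_excl exclusion zone at each chromosome end in bases
#'   (default 10000).
#' @param min_maf minimum minor-allele frequency (default 0.15).
#' @param min_depth minimum read depth (default 3).
#' @return the retained rows of `snps`.
#' @export
filter_het_snps <- function(snps, contig_lengths, end_excl = 10000L,
                            min_maf = 0.15, min_depth = 3L) {
  need <- c("contig", "pos", "maf", "depth")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns: ", paste(need, collapse = ", "))
  }
  len <- unlist(contig_lengths)[snps$contig]
  if (anyNA(len)) stop("SNP on contig with unknown length")
  keep <- snps$pos > end_excl &
    snps$pos <= len - end_excl &
    snps$maf >= min_maf &
    snps$depth >= min_depth
  snps[keep, , drop = FALSE]
}

#' Read a per-base depth TSV
#'
#' Three columns (contig, 1-based position, depth), the layout produced by
#' standard depth tools. Positions absent from the file get depth 0 up to
#' the last observed position (or the supplied contig length).
#'
#' @param path file path.
#' @param contig_lengths optional named lengths to pad to.
#' @return named list of per-base depth vectors.
#' @export
read_depth_tsv <- function(path, contig_lengths = NULL) {
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("contig", "pos", "depth"))
  out <- lapply(split(df, df$contig), function(x) {
    n <- if (!is.null(contig_lengths)) contig_lengths[[x$contig[1]]]
         else max(x$pos)
    d <- numeric(n)
    d[x$pos] <- x$depth
    d
  })
  if (!is.null(contig_lengths)) {
    for (ctg in setdiff(names(contig_lengths), names(out))) {
      out[[ctg]] <- numeric(contig_lengths[[ctg]])
    }
    out <- out[names(contig_lengths)]
  }
  out
}

#' Write a coverage track as BEDGRAPH
#'
#' @param track a `coverage_track`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s", .format_header("window_medians")), con)
  for (ctg in names(track)) {
    t <- track[[ctg]]
    if (nrow(t)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ctg, t$start, t$end,
                         format(t$median, trim = TRUE)), con)
    }
  }
  invisible(path)
}
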