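# Intragenic tandem-repeat copy-number estimation (flocculin-type genes):
# local alignment of repeat units against a gene, chaining of hits into
# clusters, and copies = cluster span / unit length.

#' Construct a repeat unit
#'
#' @param unit_id short label (e.g. "A").
#' @param sequence nucleotide string of one repeat copy.
#' @return list of class `repeat_unit` with `unit_id`, `sequence`,
#'   `length`.
#' @export
repeat_unit <- function(unit_id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("repeat unit sequence must be non-empty")
  structure(list(unit_id = unit_id, sequence = sequence,
                 length = nchar(sequence)),
            class = "repeat_unit")
}

# One best local alignment of unit vs a gene window; returns NULL when the
# score drops below min_score. match +1 / mismatch -1 / gap -2 (linear).
.best_local_hit <- function(gene_seq, unit_seq, min_score) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(unit_seq),
    subject = Biostrings::DNAString(gene_seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  if (Biostrings::score(aln) < min_score) return(NULL)
  sub <- Biostrings::subject(aln)
  pat <- Biostrings::pattern(aln)
  aln_len <- nchar(as.character(pat))
  list(start = Biostrings::start(sub) - 1L,   # to 0-based half-open
       end = Biostrings::end(sub),
       unit_cov = (Biostrings::end(pat) - Biostrings::start(pat) + 1L) /
         nchar(unit_seq),
       identity = Biostrings::nmatch(aln) / aln_len,
       score = Biostrings::score(aln))
}

# Recursively harvest non-overlapping local hits: take the best hit, then
# recurse into the flanks on either side of it.
.harvest_hits <- function(gene_seq, unit_seq, min_score, offset = 0L,
                          min_flank = 4L) {
  if (nchar(gene_seq) < min_flank) return(NULL)
  hit <- .best_local_hit(gene_seq, unit_seq, min_score)
  if (is.null(hit)) return(NULL)
  left <- substr(gene_seq, 1L, hit$start)
  right <- substr(gene_seq, hit$end + 1L, nchar(gene_seq))
  rbind(
    .harvest_hits(left, unit_seq, min_score, offset),
    data.frame(start = offset + hit$start, end = offset + hit$end,
               unit_coverage = hit$unit_cov, identity = hit$identity,
               score = hit$score, stringsAsFactors = FALSE),
    .harvest_hits(right, unit_seq, min_score, offset + hit$end)
  )
}

#' Local alignments of a repeat unit against a gene
#'
#' Finds all non-overlapping local alignments of `unit` (both strands)
#' against `gene`, by iterated best-local-alignment with match +1,
#' mismatch -1, gap -2: the best hit is recorded and the search recurses
#' into the unaligned flanks until scores fall below a floor tied to
#' `min_identity`. Hits below `min_identity` are dropped. Coordinates are
#' 0-based half-open on the gene.
#'
#' @param gene nucleotide string of the gene.
#' @param unit a `repeat_unit` (or a plain string, labelled "unit").
#' @param min_identity minimum alignment identity for a reported hit
#'   (default 0.7).
#' @return data.frame sorted by `start` with columns `unit_id`, `start`,
#'   `end`, `unit_coverage`, `identity`, `score`, `strand`; zero rows when
#'   nothing aligns.
#' @export
align_units <- function(gene, unit, min_identity = 0.7) {
  if (!inherits(unit, "repeat_unit")) unit <- repeat_unit("unit", unit)
  gene <- toupper(as.character(gene))
  if (!nzchar(gene)) stop("gene sequence must be non-empty")
  # score floor: a full-length hit at the identity floor scores about
  # (2*min_identity - 1) * L; anything below that is noise for chaining
  min_score <- max(5, floor((2 * min_identity - 1) * unit$length))
  out <- NULL
  for (strand in c("+", "-")) {
    useq <- if (strand == "+") unit$sequence else
      reverse_complement(unit$sequence)
    hits <- .harvest_hits(gene, useq, min_score)
    if (!is.null(hits) && nrow(hits)) {
      hits$strand <- strand
      out <- rbind(out, hits)
    }
  }
  if (is.null(out) || !nrow(out)) {
    return(data.frame(unit_id = character(0), start = integer(0),
                      end = integer(0), unit_coverage = numeric(0),
                      identity = numeric(0), score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- out[out$identity >= min_identity, , drop = FALSE]
  # a palindromic-ish unit can hit the same span on both strands: keep the
  # higher-scoring of duplicated spans
  out <- out[order(out$start, out$end, -out$score), , drop = FALSE]
  dup <- duplicated(out[, c("start", "end")])
  out <- out[!dup, , drop = FALSE]
  data.frame(unit_id = unit$unit_id, out[, c("start", "end", "unit_coverage",
                                             "identity", "score", "strand")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chain repeat-unit hits into tandem clusters
#'
#' Discards hits covering less than `min_cov` of the unit, sorts the rest
#' by start, and chains consecutive hits while the gap between them is at
#' most `gap_factor` times the unit length (a strictly larger gap starts a
#' new cluster). Each cluster's copy number is its genomic span (first hit
#' start to last hit end) divided by the unit length — which is what makes
#' fractional copy numbers possible when copies are truncated or spaced.
#'
#' @param hits data.frame from [align_units()] (any row order; sorted
#'   internally).
#' @param unit the `repeat_unit` the hits refer to.
#' @param min_cov minimum `unit_coverage` of a hit (default 0.5).
#' @param gap_factor maximum gap between consecutive hits, in units of the
#'   repeat length (default 3).
#' @return data.frame with one row per cluster: `unit_id`, `span_start`,
#'   `span_end`, `n_hits`, `copies`.
#' @examples
#' u <- repeat_unit("U", strrep("A", 100))
#' h <- data.frame(start = c(0, 100, 250), end = c(100, 200, 350),
#'                 unit_coverage = 1, identity = 1)
#' cluster_repeats(h, u)  # one cluster, copies 3.5
#' @export
cluster_repeats <- function(hits, unit, min_cov = 0.5, gap_factor = 3.0) {
  if (!inherits(unit, "repeat_unit")) stop("unit must be a repeat_unit")
  empty <- data.frame(unit_id = character(0), span_start = integer(0),
                      span_end = integer(0), n_hits = integer(0),
                      copies = numeric(0), stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits <- hits[hits$unit_coverage >= min_cov, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  max_gap <- gap_factor * unit$length
  # gap is measured from the running end of the current cluster so nested
  # or overlapping hits cannot shrink it
  cluster_id <- integer(nrow(hits))
  cluster_id[1] <- 1L
  cur_end <- hits$end[1]
  for (i in seq_len(nrow(hits))[-1]) {
    if (hits$start[i] - cur_end > max_gap) {
      cluster_id[i] <- cluster_id[i - 1L] + 1L
      cur_end <- hits$end[i]
    } else {
      cluster_id[i] <- cluster_id[i - 1L]
      cur_end <- max(cur_end, hits$end[i])
    }
  }
  do.call(rbind, lapply(split(seq_len(nrow(hits)), cluster_id), function(i) {
    s <- min(hits$start[i]); e <- max(hits$end[i])
    data.frame(unit_id = unit$unit_id, span_start = s, span_end = e,
               n_hits = length(i), copies = (e - s) / unit$length,
               stringsAsFactors = FALSE)
  }))
}

#' Tandem-repeat copy-number report for genes vs repeat units
#'
#' Runs [align_units()] and [cluster_repeats()] for every gene x unit
#' combination and reports, per combination, the copy number of the
#' largest cluster (rounded to one decimal), with the gene length
#' alongside. All clusters are retained in the `clusters` attribute for
#' detailed inspection.
#'
#' @param genes named character vector of gene sequences (or FASTA path).
#' @param units named character vector of repeat unit sequences (or FASTA
#'   path), names used as unit ids.
#' @param min_identity,min_cov,gap_factor passed through to the alignment
#'   and clustering steps.
#' @return data.frame with columns `gene`, `gene_size`, then one numeric
#'   column per unit (`NA` when the unit forms no cluster in that gene);
#'   attribute `"clusters"` holds the full per-cluster table.
#' @export
repeat_report <- function(genes, units, min_identity = 0.7, min_cov = 0.5,
                          gap_factor = 3.0) {
  if (is.character(genes) && length(genes) == 1L && file.exists(genes)) {
    genes <- read_genome(genes)
  }
  if (is.character(units) && length(units) == 1L && file.exists(units)) {
    units <- read_genome(units)
  }
  if (is.null(names(genes)) || is.null(names(units))) {
    stop("genes and units must be named")
  }
  unit_objs <- lapply(names(units), function(u) repeat_unit(u, units[[u]]))
  names(unit_objs) <- names(units)
  all_clusters <- NULL
  tab <- matrix(NA_real_, length(genes), length(units),
                dimnames = list(names(genes), names(units)))
  for (g in names(genes)) {
    for (u in names(units)) {
      hits <- align_units(genes[[g]], unit_objs[[u]],
                          min_identity = min_identity)
      cl <- cluster_repeats(hits, unit_objs[[u]], min_cov = min_cov,
                            gap_factor = gap_factor)
      if (nrow(cl)) {
        cl$gene <- g
        all_clusters <- rbind(all_clusters, cl)
        tab[g, u] <- round(max(cl$copies), 1)
      }
    }
  }
  out <- data.frame(gene = names(genes),
                    gene_size = unname(nchar(genes)),
                    tab, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "clusters") <- all_clusters
  out
}

#' Write a repeat report as TSV
#'
#' Mirrors the gene x unit table with "-" for absent clusters.
#'
#' @param report data.frame from [repeat_report()].
#' @param path file path.
#' @param params header parameters.
#' @return `path`, invisibly.
#' @export
write_repeat_report <- function(report, path, params = list()) {
  df <- report
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && names(df)[j] != "gene_size") {
      df[[j]] <- ifelse(is.na(df[[j]]), "-", format(df[[j]], trim = TRUE))
    }
  }
  write_tsv_output(df, path, op = "repeats", params = params)
}
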