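# Sub-region k-mer set construction and similarity scoring.

.new_sample_region_sets <- function(sample_id, k, sets, read_support = NULL) {
  if (is.null(read_support)) {
    read_support <- setNames(rep(NA_integer_, length(sets)), names(sets))
  }
  structure(list(sample_id = sample_id, k = as.integer(k), sets = sets,
                 read_support = read_support),
            class = "sample_region_sets")
}

#' @export
print.sample_region_sets <- function(x, ...) {
  cat(sprintf("sample_region_sets '%s': %d regions, k=%d\n",
              x$sample_id, length(x$sets), x$k))
  invisible(x)
}

#' Per-region k-mer sets of a genome
#'
#' Cuts each sub-region's sequence directly out of a genome and reduces it
#' to canonical k-mers. Applied to the reference assembly itself this yields
#' the reference sub-region sets that containment scoring is anchored on.
#' Applied to another genome it assumes that genome is coordinate-colinear
#' with the reference (no indels/rearrangements); that holds for the
#' substitution-only genomes produced by [simulate_panel()], which is the
#' intended use — panel strains from real data should go through
#' [region_sets_from_alignments()].
#'
#' @param genome named character vector of contig sequences (or a
#'   `DNAStringSet`).
#' @param regions sub-region data.frame from [partition_reference()].
#' @param k k-mer length (default 21).
#' @param sample_id label stored in the result (default: "genome").
#' @return A `sample_region_sets` object: per-region canonical k-mer sets
#'   keyed by region id.
#' @export
region_sets_from_genome <- function(genome, regions, k = 21L,
                                    sample_id = "genome") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  genome <- toupper(genome)
  missing_ctg <- setdiff(unique(regions$contig), names(genome))
  if (length(missing_ctg)) {
    stop("regions reference contigs absent from genome: ",
         paste(missing_ctg, collapse = ", "))
  }
  too_long <- regions$end > nchar(genome)[regions$contig]
  if (any(too_long)) {
    stop("region(s) extend beyond contig end: ",
         paste(regions$id[too_long], collapse = ", "))
  }
  seqs <- substring(genome[regions$contig], regions$start + 1L, regions$end)
  sets <- lapply(seqs, canonical_kmers, k = k)
  names(sets) <- regions$id
  .new_sample_region_sets(sample_id, k, sets)
}

#' Per-region k-mer sets of a sample from its read alignments
#'
#' Builds one canonical k-mer set per sub-region from reads aligned to the
#' partitioned reference. For every primary mapped read, the aligned
#' (match/mismatch) CIGAR blocks are projected onto reference coordinates;
#' the read bases whose projected positions fall inside a sub-region are
#' extracted and their canonical k-mers added to that region's set. A read
#' spanning a region boundary therefore contributes to both regions, but
#' no k-mer straddles a boundary — exactly mirroring how the reference sets
#' are built, so containment compares like with like. Unmapped, secondary
#' and supplementary records are ignored; records on contigs not covered by
#' `regions` are skipped and counted in a warning.
#'
#' With `min_freq = 2` (recommended at depths of 20x and above), k-mers
#' seen only once in a region are dropped. Almost every k-mer touched by a
#' sequencing error is a singleton, while true k-mers recur with the
#' coverage, so the floor removes error noise that would otherwise inflate
#' the set and depress containment scores; at very low coverage keep the
#' default `min_freq = 1`.
#'
#' @param alignments path to a SAM or BAM file, or a
#'   `GenomicAlignments::GAlignments` object carrying sequences.
#' @param regions sub-region data.frame from [partition_reference()].
#' @param k k-mer length (default 21).
#' @param sample_id sample label (default: file basename).
#' @param min_freq minimum per-region k-mer multiplicity (default 1, keep
#'   everything).
#' @return A `sample_region_sets` object; `read_support` holds the number
#'   of aligned bases falling in each region.
#' @export
region_sets_from_alignments <- function(alignments, regions, k = 21L,
                                        sample_id = NULL, min_freq = 1L) {
  if (is.character(alignments)) {
    if (is.null(sample_id)) {
      sample_id <- sub("\\.(sam|bam)$", "", basename(alignments),
                       ignore.case = TRUE)
    }
    alignments <- .read_alignments(alignments)
  }
  if (is.null(sample_id)) sample_id <- "sample"
  empty_sets <- setNames(rep(list(character(0)), nrow(regions)), regions$id)
  zero_support <- setNames(integer(nrow(regions)), regions$id)

  known <- unique(regions$contig)
  ctg <- as.character(GenomicAlignments::seqnames(alignments))
  off_panel <- !(ctg %in% known)
  if (any(off_panel)) {
    warning(sum(off_panel), " alignment(s) on contigs without sub-regions",
            " were skipped")
    alignments <- alignments[!off_panel]
    ctg <- ctg[!off_panel]
  }
  if (!length(alignments)) {
    return(.new_sample_region_sets(sample_id, k, empty_sets, zero_support))
  }

  cig <- GenomicAlignments::cigar(alignments)
  ops <- c("M", "=", "X")
  ref_blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, ops = ops, pos = GenomicAlignments::start(alignments))
  qry_blocks <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = ops)

  n_per <- S4Vectors::elementNROWS(ref_blocks)
  ref_flat <- unlist(ref_blocks, use.names = FALSE)
  qry_flat <- unlist(qry_blocks, use.names = FALSE)
  aln_idx <- rep(seq_along(alignments), n_per)

  block_gr <- GenomicRanges::GRanges(ctg[aln_idx], ref_flat)
  region_gr <- GenomicRanges::GRanges(
    regions$contig, IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(block_gr, region_gr)
  if (!length(hits)) {
    return(.new_sample_region_sets(sample_id, k, empty_sets, zero_support))
  }
  bi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)

  # clip each block to the region it overlaps, then map back to read coords
  ov_start <- pmax(IRanges::start(ref_flat)[bi], regions$start[ri] + 1L)
  ov_end <- pmin(IRanges::end(ref_flat)[bi], regions$end[ri])
  q_from <- IRanges::start(qry_flat)[bi] +
    (ov_start - IRanges::start(ref_flat)[bi])
  q_to <- q_from + (ov_end - ov_start)

  read_seq <- as.character(S4Vectors::mcols(alignments)$seq)
  pieces <- substring(read_seq[aln_idx[bi]], q_from, q_to)

  region_of <- regions$id[ri]
  sets <- empty_sets
  support <- zero_support
  piece_by_region <- split(pieces, region_of)
  for (rid in names(piece_by_region)) {
    if (min_freq > 1L) {
      cnt <- cpp_kmer_counts(piece_by_region[[rid]], as.integer(k))
      sets[[rid]] <- sort(names(cnt)[cnt >= min_freq])
    } else {
      sets[[rid]] <- sort(cpp_canonical_kmers(piece_by_region[[rid]],
                                              as.integer(k), TRUE))
    }
  }
  base_counts <- vapply(split(ov_end - ov_start + 1L, region_of), sum, 0L)
  support[names(base_counts)] <- base_counts
  .new_sample_region_sets(sample_id, k, sets, support)
}

#' Score a panel of samples against reference sub-region sets
#'
#' For every sub-region and sample computes the containment of the
#' reference region set in the sample's region set (or the Jaccard index
#' with `metric = "jaccard"`). Cells where the sample has no k-mers for a
#' region, or where the reference set is empty, get status `"missing"`
#' instead of a score.
#'
#' @param ref_sets a `sample_region_sets` for the reference (from
#'   [region_sets_from_genome()] or [region_sets_from_alignments()]), or a
#'   named list of k-mer vectors keyed by region id.
#' @param panel list of `sample_region_sets`, one per panel strain.
#' @param metric `"containment"` (default) or `"jaccard"`.
#' @return A `similarity_matrix`: list with `score` (region x sample
#'   numeric matrix, `NA` where missing), `status` (character matrix,
#'   `"scored"`/`"missing"`), `k` and `metric`.
#' @export
score_matrix <- function(ref_sets, panel, metric = c("containment", "jaccard")) {
  metric <- match.arg(metric)
  if (inherits(panel, "sample_region_sets")) panel <- list(panel)
  if (!length(panel)) stop("panel must contain at least one sample")
  if (inherits(ref_sets, "sample_region_sets")) {
    k <- ref_sets$k
    ref_sets <- ref_sets$sets
  } else {
    k <- if (length(ref_sets) && length(ref_sets[[1]]))
      nchar(ref_sets[[1]][1]) else NA_integer_
  }
  ks <- vapply(panel, function(p) p$k, 0L)
  if (!is.na(k) && any(ks != k)) stop("k differs between reference and panel")
  sim_fun <- if (metric == "containment") containment else kmer_jaccard
  samples <- vapply(panel, function(p) p$sample_id, "")
  if (anyDuplicated(samples)) stop("duplicate sample ids in panel")
  rids <- names(ref_sets)
  score <- matrix(NA_real_, length(rids), length(samples),
                  dimnames = list(rids, samples))
  for (j in seq_along(panel)) {
    sets_j <- panel[[j]]$sets
    for (i in seq_along(rids)) {
      ref <- ref_sets[[i]]
      tgt <- sets_j[[rids[i]]]
      if (length(ref) && !is.null(tgt) && length(tgt)) {
        score[i, j] <- sim_fun(ref, tgt)
      }
    }
  }
  status <- ifelse(is.na(score), "missing", "scored")
  structure(list(score = score, status = status, k = k, metric = metric),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d regions x %d samples (%s, k=%d)\n",
              nrow(x$score), ncol(x$score), x$metric, x$k))
  invisible(x)
}

#' Call the top-scoring sample(s) for every sub-region
#'
#' For each sub-region, the samples within `tie_delta` of the maximal
#' similarity are the top-scoring set (with the default `tie_delta = 0`,
#' exact ties). A region whose maximal similarity falls below
#' `min_similarity` is called `low_similarity` and gets no winners; a
#' region whose winners span more than one lineage is `ambiguous_lineage`
#' (its winners are still reported and traced); otherwise `assigned`.
#' Regions with no scored cell at all are `missing`.
#'
#' @param matrix a `similarity_matrix` from [score_matrix()].
#' @param lineage_map named character vector mapping every sample to a
#'   lineage.
#' @param min_similarity similarity floor below which a region is called
#'   `low_similarity` (default 0.75).
#' @param tie_delta samples scoring within this margin of the maximum count
#'   as tied winners (default 0, exact ties only).
#' @return data.frame with one row per region: `region_id`, `status`,
#'   `max_score`, `top_samples` (list column), `lineages` (list column),
#'   `lineage` (the single winning lineage, `NA` when not `assigned`).
#' @export
assign_top <- function(matrix, lineage_map, min_similarity = 0.75,
                       tie_delta = 0) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  samples <- colnames(matrix$score)
  absent <- setdiff(samples, names(lineage_map))
  if (length(absent)) {
    stop("samples without lineage: ", paste(absent, collapse = ", "))
  }
  rids <- rownames(matrix$score)
  res <- lapply(seq_along(rids), function(i) {
    sc <- matrix$score[i, ]
    if (all(is.na(sc))) {
      return(list(status = "missing", max_score = NA_real_,
                  top = character(0), lin = character(0)))
    }
    mx <- max(sc, na.rm = TRUE)
    if (mx < min_similarity) {
      return(list(status = "low_similarity", max_score = mx,
                  top = character(0), lin = character(0)))
    }
    top <- samples[!is.na(sc) & sc >= mx - tie_delta]
    lin <- unique(unname(lineage_map[top]))
    status <- if (length(lin) > 1L) "ambiguous_lineage" else "assigned"
    list(status = status, max_score = mx, top = top, lin = lin)
  })
  data.frame(
    region_id = rids,
    status = vapply(res, `[[`, "", "status"),
    max_score = vapply(res, `[[`, 0, "max_score"),
    top_samples = I(lapply(res, `[[`, "top")),
    lineages = I(lapply(res, `[[`, "lin")),
    lineage = vapply(res, function(r)
      if (r$status == "assigned") r$lin else NA_character_, ""),
    stringsAsFactors = FALSE
  )
}

#' Write / read a similarity matrix as TSV
#'
#' Region ids in the first column, one score column per sample, `NA` for
#' missing cells; the usual comment header records k and the metric.
#'
#' @param matrix a `similarity_matrix`.
#' @param path file path.
#' @return `write_similarity_matrix` returns `path` invisibly;
#'   `read_similarity_matrix` a `similarity_matrix`.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(region_id = rownames(matrix$score), matrix$score,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_output(df, path, op = "score",
                   params = list(k = matrix$k, metric = matrix$metric))
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  kv <- regmatches(hdr, regexpr("k=[0-9]+", hdr))
  metric <- if (any(grepl("metric=jaccard", hdr))) "jaccard" else "containment"
  df <- read_tsv_output(path)
  score <- as.matrix(df[, -1, drop = FALSE])
  rownames(score) <- df[[1]]
  structure(list(score = score,
                 status = ifelse(is.na(score), "missing", "scored"),
                 k = if (length(kv)) as.integer(sub("k=", "", kv[1]))
                     else NA_integer_,
                 metric = metric),
            class = "similarity_matrix")
}

#' Write / read per-region k-mer sets
#'
#' Plain-text exchange format for `sample_region_sets`: header lines
#' recording sample and k, then two tab-separated columns (region id,
#' k-mer), regions in input order and k-mers sorted.
#'
#' @param x a `sample_region_sets`.
#' @param path file path.
#' @return `write_region_sets` returns `path` invisibly;
#'   `read_region_sets` a `sample_region_sets`.
#' @export
write_region_sets <- function(x, path) {
  stopifnot(inherits(x, "sample_region_sets"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#%s", .format_header("region_sets",
                                             list(sample_id = x$sample_id,
                                                  k = x$k))),
               sprintf("#regions=%s", paste(names(x$sets), collapse = ","))),
             con)
  for (rid in names(x$sets)) {
    if (length(x$sets[[rid]])) {
      writeLines(paste(rid, x$sets[[rid]], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_region_sets
#' @export
read_region_sets <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  sid <- sub(".*sample_id=([^ ]+).*", "\\1", grep("sample_id=", hdr,
                                                  value = TRUE)[1])
  k <- as.integer(sub(".*k=([0-9]+).*", "\\1", grep(" k=", hdr,
                                                    value = TRUE)[1]))
  rids <- strsplit(sub("^#regions=", "", grep("^#regions=", hdr,
                                              value = TRUE)[1]), ",")[[1]]
  sets <- setNames(rep(list(character(0)), length(rids)), rids)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    rid <- vapply(parts, `[[`, "", 1L)
    km <- vapply(parts, `[[`, "", 2L)
    filled <- split(km, rid)
    sets[names(filled)] <- lapply(filled, sort)
  }
  .new_sample_region_sets(sid, k, sets)
}

#' Write assignments as TSV
#'
#' @param assignments data.frame from [assign_top()].
#' @param path file path.
#' @param params named list recorded in the header (e.g. thresholds).
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path, params = list()) {
  df <- data.frame(
    region_id = assignments$region_id,
    status = assignments$status,
    max_score = assignments$max_score,
    top_samples = vapply(assignments$top_samples, paste, "", collapse = ","),
    lineages = vapply(assignments$lineages, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  write_tsv_output(df, path, op = "assign", params = params)
}

#' Read assignments written by [write_assignments()]
#'
#' @param path file path.
#' @return data.frame in the shape produced by [assign_top()].
#' @export
read_assignments <- function(path) {
  df <- read_tsv_output(path)
  split_or_empty <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character(0)
           else strsplit(s, ",", fixed = TRUE)[[1]])
  }
  data.frame(
    region_id = df$region_id,
    status = df$status,
    max_score = df$max_score,
    top_samples = I(split_or_empty(as.character(df$top_samples))),
    lineages = I(split_or_empty(as.character(df$lineages))),
    lineage = vapply(seq_len(nrow(df)), function(i) {
      lin <- if (is.na(df$lineages[i])) "" else as.character(df$lineages[i])
      if (df$status[i] == "assigned") lin else NA_character_
    }, ""),
    stringsAsFactors = FALSE
  )
}
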