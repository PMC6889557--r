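#' End-to-end admixture recovery benchmark on synthetic data
#'
#' Runs the complete workflow on a simulated study: a hierarchical strain
#' panel (5 lineages x 3 strains on a 200 kb, two-contig genome;
#' within-lineage divergence 0.003, between-lineage 0.02), an admixed
#' query copying 60% of its genome from one donor strain and 40% from a
#' donor in another lineage, and 30x error-prone reads (rate 0.002) from
#' the query. The query's own read-derived sub-region k-mer sets are
#' scored by containment against panel region sets, top-scoring strains
#' are called per 2 kb sub-region, and winners are traced onto the UPGMA
#' tree of panel Mash distances.
#'
#' The defaults define the benchmark conditions; change them only to
#' explore, not to compare against the reported recovery rates.
#'
#' @param seed integer seed driving every random step.
#' @param n_lineages,strains_per_lineage panel shape (default 5 x 3).
#' @param contig_lengths genome shape (default two 100 kb contigs).
#' @param within_div,between_div panel divergences (defaults 0.003, 0.02).
#' @param coverage,read_len,err read simulation (defaults 30x, 150 bp,
#'   0.002).
#' @param region_size,k partition parameters (defaults 2000, 21).
#' @param min_similarity assignment floor (default 0.75).
#' @param donor_fracs fractions of the genome copied from the two donors
#'   (default `c(0.6, 0.4)`); donors are the first strains of the first
#'   two lineages.
#' @return list with `donor_accuracy` (fraction of non-breakpoint regions
#'   whose single top-scoring sample is the true donor), `lineage_fracs`
#'   (traced lineage counts / N), `truth_fracs` (region-truth donor
#'   fractions), `monophyletic` (per-lineage clade recovery of the Mash +
#'   UPGMA tree), `n_regions`, `N`, plus the intermediate objects
#'   (`assignments`, `trace`, `tree`).
#' @export
admixture_benchmark <- function(seed = 1L,
                                n_lineages = 5L, strains_per_lineage = 3L,
                                contig_lengths = c(chrI = 100000L,
                                                   chrII = 100000L),
                                within_div = 0.003, between_div = 0.02,
                                coverage = 30, read_len = 150L, err = 0.002,
                                region_size = 2000L, k = 21L,
                                min_similarity = 0.75,
                                donor_fracs = c(0.6, 0.4)) {
  seed <- as.integer(seed)
  panel <- simulate_panel(n_lineages, strains_per_lineage, contig_lengths,
                          within_div, between_div, seed = seed)
  donors <- c("L1_S1", "L2_S1")

  # 60/40 mosaic: donor 1 owns contig I plus the head of contig II; the
  # single breakpoint deliberately falls inside a sub-region
  total <- sum(contig_lengths)
  want1 <- round(donor_fracs[1] * total)
  bp <- want1 - contig_lengths[[1]] + 337L  # off-grid breakpoint
  segments <- data.frame(
    contig = c(names(contig_lengths)[1], names(contig_lengths)[2],
               names(contig_lengths)[2]),
    start = c(0L, 0L, bp),
    end = c(contig_lengths[[1]], bp, contig_lengths[[2]]),
    donor_id = c(donors[1], donors[1], donors[2]),
    stringsAsFactors = FALSE)
  query <- simulate_admixed_query(panel, segments, extra_div = 0,
                                  seed = seed + 1L)

  regions <- partition_reference(contig_lengths, region_size = region_size,
                                 k = k)
  truth <- region_truth(segments, regions)

  # query sub-region sets from its own reads (SAM round-trip included)
  reads <- simulate_reads(query$genome, coverage = coverage,
                          read_len = read_len, err = err, seed = seed + 2L,
                          sample_id = "query")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  write_sam(reads, contig_lengths, sam)
  query_sets <- region_sets_from_alignments(sam, regions, k = k,
                                            sample_id = "query",
                                            min_freq = 2L)

  # panel sub-region sets straight from the colinear genomes
  panel_sets <- lapply(names(panel$genomes), function(s)
    region_sets_from_genome(panel$genomes[[s]], regions, k = k,
                            sample_id = s))

  mat <- score_matrix(query_sets, panel_sets)
  assignments <- assign_top(mat, panel$lineage_map,
                            min_similarity = min_similarity)

  # population tree from Mash distances of the panel assemblies
  sketches <- lapply(names(panel$genomes), function(s)
    sketch_sequences(panel$genomes[[s]], k = k, min_freq = 1L,
                     sample_id = s))
  names(sketches) <- names(panel$genomes)
  tree <- upgma(mash_distance_matrix(sketches))
  tr <- trace_tree(assignments, tree, panel$lineage_map)

  nb <- !truth$breakpoint
  single_winner <- lengths(assignments$top_samples) == 1L
  hit <- vapply(seq_len(nrow(assignments)), function(i)
    single_winner[i] && assignments$top_samples[[i]][1] == truth$donor_id[i],
    logical(1))
  donor_accuracy <- mean(hit[nb])

  truth_fracs <- table(factor(panel$lineage_map[truth$donor_id[nb]],
                              levels = sort(unique(panel$lineage_map))))
  truth_fracs <- as.numeric(truth_fracs) / sum(truth_fracs)
  names(truth_fracs) <- sort(unique(panel$lineage_map))

  lineage_fracs <- if (tr$N > 0) tr$lineage_counts / tr$N else
    tr$lineage_counts * NA_real_

  list(donor_accuracy = donor_accuracy,
       lineage_fracs = lineage_fracs,
       truth_fracs = truth_fracs,
       monophyletic = lineage_monophyly(tree, panel$lineage_map),
       n_regions = nrow(regions),
       N = tr$N,
       assignments = assignments,
       trace = tr,
       tree = tree,
       truth = truth,
       panel = panel)
}
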