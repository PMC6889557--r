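make_sam <- function(reads, lens) {
  path <- tempfile(fileext = ".sam")
  write_sam(reads, lens, path)
  path
}

test_that("genome-derived region sets give containment 1 for the genome itself", {
  withr::with_seed(5, {
    genome <- c(c1 = random_dna(5000), c2 = random_dna(2300))
    regions <- partition_reference(contig_lengths(genome), 2000L)
    rs <- region_sets_from_genome(genome, regions, k = 21)
    for (rid in regions$id) {
      expect_equal(containment(rs$sets[[rid]], rs$sets[[rid]]), 1)
    }
    expect_error(region_sets_from_genome(genome["c1"], regions), "absent")
    bad <- regions; bad$end[1] <- 99999L
    expect_error(region_sets_from_genome(genome, bad), "beyond")
  })
})

test_that("divergent genomes score below 1 in mutated regions", {
  withr::with_seed(6, {
    panel <- simulate_panel(1, 2, c(c1 = 20000L), within_div = 0.01,
                            between_div = 0, seed = 60)
    regions <- partition_reference(c(c1 = 20000L), 2000L)
    a <- region_sets_from_genome(panel$genomes$L1_S1, regions, k = 21,
                                 sample_id = "a")
    b <- region_sets_from_genome(panel$genomes$L1_S2, regions, k = 21,
                                 sample_id = "b")
    sc <- score_matrix(a, list(b))$score
    # ~2% pairwise divergence: every 2 kb region should carry mutations,
    # and expected k-mer survival (1-0.02)^21 ~ 0.65 is well below 1
    expect_true(all(sc < 1))
    expect_true(mean(sc) > 0.4 && mean(sc) < 0.9)
  })
})

test_that("read alignments are projected onto regions through CIGAR blocks", {
  lens <- c(c1 = 20L)
  regions <- partition_reference(lens, region_size = 10L, k = 3L)
  # perfect-match 10-base read starting at 0-based reference position 4:
  # overlap with [0,10) is read bases 0..5 -> 4 three-mer windows
  reads <- data.frame(qname = "r1", flag = 0L, rname = "c1", pos = 5L,
                      mapq = 60L, cigar = "10M", seq = "ACGTACGTAC",
                      stringsAsFactors = FALSE)
  rs <- region_sets_from_alignments(make_sam(reads, lens), regions, k = 3)
  # windows ACG CGT GTA TAC canonicalise to {ACG, GTA}
  expect_equal(rs$sets[["c1:0-10"]], c("ACG", "GTA"))
  # spanning read contributes to the second region too (read bases 6..9)
  expect_equal(rs$sets[["c1:10-20"]], sort(canonical_kmers("GTAC", 3)))
  expect_equal(unname(rs$read_support), c(6L, 4L))
})

test_that("unmapped and secondary records contribute nothing", {
  lens <- c(c1 = 40L)
  regions <- partition_reference(lens, region_size = 40L, k = 3L)
  reads <- data.frame(
    qname = c("u", "sec", "ok"), flag = c(4L, 256L, 0L), rname = "c1",
    pos = c(1L, 1L, 11L), mapq = 60L, cigar = "8M",
    seq = c("ACGTACGT", "ACGTACGT", "TTTTTTTT"), stringsAsFactors = FALSE)
  rs <- region_sets_from_alignments(make_sam(reads, lens), regions, k = 3)
  expect_equal(rs$sets[["c1:0-40"]], "AAA")  # only the primary mapped read
})

test_that("alignments on contigs without regions are skipped with a warning", {
  lens <- c(c1 = 40L, c2 = 40L)
  regions <- partition_reference(lens["c1"], region_size = 40L, k = 3L)
  reads <- data.frame(qname = c("a", "b"), flag = 0L, rname = c("c2", "c1"),
                      pos = 1L, mapq = 60L, cigar = "8M", seq = "ACGTACGT",
                      stringsAsFactors = FALSE)
  expect_warning(
    rs <- region_sets_from_alignments(make_sam(reads, lens), regions, k = 3),
    "skipped")
  expect_equal(length(rs$sets), 1L)
})

test_that("min_freq floor drops k-mers seen once in a region", {
  lens <- c(c1 = 30L)
  regions <- partition_reference(lens, region_size = 30L, k = 3L)
  # r2's windows AAG and AGT canonicalise to the singletons AAG and ACT;
  # its AAA windows recur across both reads
  reads <- data.frame(
    qname = c("r1", "r2"), flag = 0L, rname = "c1", pos = c(1L, 1L),
    mapq = 60L, cigar = "6M", seq = c("AAAAAA", "AAAAGT"),
    stringsAsFactors = FALSE)
  sam <- make_sam(reads, lens)
  all_k <- region_sets_from_alignments(sam, regions, k = 3)
  flt <- region_sets_from_alignments(sam, regions, k = 3, min_freq = 2L)
  expect_true(all(c("AAG", "ACT") %in% all_k$sets[["c1:0-30"]]))
  expect_false(any(c("AAG", "ACT") %in% flt$sets[["c1:0-30"]]))
  expect_true("AAA" %in% flt$sets[["c1:0-30"]])
})

test_that("score_matrix equals brute-force set arithmetic on toy sets", {
  ref <- list(r1 = c("AAA", "ACA", "AGA"), r2 = c("CCC", "CCG"),
              r3 = character(0))
  s1 <- list(r1 = c("AAA", "ACA", "TTT"), r2 = c("CCC", "CCG"),
             r3 = c("GGG"))
  s2 <- list(r1 = c("TTT"), r2 = character(0), r3 = character(0))
  mat <- toy_matrix(ref, list(s1 = s1, s2 = s2))
  expect_equal(mat$score["r1", "s1"], 2 / 3)
  expect_equal(mat$score["r2", "s1"], 1)
  expect_equal(mat$score["r1", "s2"], 0)
  expect_equal(mat$status["r2", "s2"], "missing")   # sample set empty
  expect_equal(mat$status["r3", "s1"], "missing")   # reference set empty
  expect_error(score_matrix(ref_sets_as_srs(ref), list()), "at least one")
})

test_that("adding reads never decreases containment (monotonicity)", {
  withr::with_seed(21, {
    genome <- c(c1 = random_dna(4000))
    regions <- partition_reference(contig_lengths(genome), 2000L)
    ref <- region_sets_from_genome(genome, regions, k = 21)
    reads <- simulate_reads(genome, coverage = 4, read_len = 100,
                            err = 0.01, seed = 1)
    half <- reads[seq_len(nrow(reads) %/% 2), ]
    s_half <- region_sets_from_alignments(
      make_sam(half, contig_lengths(genome)), regions, k = 21,
      sample_id = "s")
    s_full <- region_sets_from_alignments(
      make_sam(reads, contig_lengths(genome)), regions, k = 21,
      sample_id = "s")
    sc_half <- score_matrix(ref, list(s_half))$score
    sc_full <- score_matrix(ref, list(s_full))$score
    ok <- !is.na(sc_half)
    expect_true(all(sc_full[ok] >= sc_half[ok]))
  })
})

test_that("assign_top applies tie, floor and lineage rules", {
  sc <- rbind(r1 = c(s1 = 0.9, s2 = 0.9, s3 = 0.5),
              r2 = c(s1 = 0.4, s2 = 0.3, s3 = 0.2),
              r3 = c(s1 = 0.8, s2 = 0.95, s3 = 0.95),
              r4 = c(s1 = NA, s2 = NA, s3 = NA))
  mat <- structure(list(score = sc,
                        status = ifelse(is.na(sc), "missing", "scored"),
                        k = 21L, metric = "containment"),
                   class = "similarity_matrix")
  lmap <- c(s1 = "L1", s2 = "L1", s3 = "L2")
  asg <- assign_top(mat, lmap)
  expect_equal(asg$status, c("assigned", "low_similarity",
                             "ambiguous_lineage", "missing"))
  expect_equal(asg$top_samples[[1]], c("s1", "s2"))  # exact tie, one lineage
  expect_equal(asg$lineage[1], "L1")
  expect_equal(asg$top_samples[[2]], character(0))
  expect_equal(sort(asg$top_samples[[3]]), c("s2", "s3"))
  # tie_delta widens the winner set
  asg2 <- assign_top(mat, lmap, tie_delta = 0.15)
  expect_equal(sort(asg2$top_samples[[3]]), c("s1", "s2", "s3"))
  expect_error(assign_top(mat, c(s1 = "L1")), "without lineage")
})

test_that("matrices, assignments and region sets round-trip through files", {
  withr::with_seed(31, {
    genome <- c(c1 = random_dna(4500))
    regions <- partition_reference(contig_lengths(genome), 2000L)
    ref <- region_sets_from_genome(genome, regions, k = 21, sample_id = "ref")
    p1 <- region_sets_from_genome(genome, regions, k = 21, sample_id = "p1")
    mat <- score_matrix(ref, list(p1))

    f1 <- withr::local_tempfile(fileext = ".tsv")
    write_similarity_matrix(mat, f1)
    back <- read_similarity_matrix(f1)
    expect_equal(back$score, mat$score)
    expect_equal(back$k, mat$k)

    asg <- assign_top(mat, c(p1 = "L1"))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_assignments(asg, f2)
    asg2 <- read_assignments(f2)
    expect_equal(asg2$status, asg$status)
    expect_equal(asg2$top_samples, asg$top_samples)

    f3 <- withr::local_tempfile(fileext = ".sets")
    write_region_sets(ref, f3)
    ref2 <- read_region_sets(f3)
    expect_identical(ref2$sets, ref$sets)
    expect_identical(ref2$k, ref$k)
  })
})
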