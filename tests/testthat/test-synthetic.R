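test_that("panel simulation is seed-deterministic", {
  a <- simulate_panel(2, 2, c(c1 = 5000L), 0.003, 0.02, seed = 3)
  b <- simulate_panel(2, 2, c(c1 = 5000L), 0.003, 0.02, seed = 3)
  c <- simulate_panel(2, 2, c(c1 = 5000L), 0.003, 0.02, seed = 4)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$ancestor, b$ancestor)
  expect_false(identical(a$genomes, c$genomes))
  expect_equal(names(a$genomes), c("L1_S1", "L1_S2", "L2_S1", "L2_S2"))
  expect_equal(unname(a$lineage_map["L2_S1"]), "L2")
})

test_that("pairwise divergence matches the substitution rates", {
  L <- 50000L
  p <- simulate_panel(2, 2, c(c1 = L), within_div = 0.004,
                      between_div = 0.03, seed = 11)
  diff_frac <- function(x, y) {
    mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  # within a lineage: two strains each at 0.004 from the founder; a site
  # differs if exactly one mutated (and picked different bases when both).
  d_within <- diff_frac(p$genomes$L1_S1[["c1"]], p$genomes$L1_S2[["c1"]])
  expected <- 2 * 0.004
  tol <- 3 * sqrt(expected / L)   # 3 binomial standard deviations
  expect_lt(abs(d_within - expected), tol + 0.004^2)
  # across lineages divergence is roughly 2*(between+within)
  d_between <- diff_frac(p$genomes$L1_S1[["c1"]], p$genomes$L2_S1[["c1"]])
  expect_gt(d_between, 3 * d_within)
  # zero rate copies the founder exactly
  p0 <- simulate_panel(1, 2, c(c1 = 2000L), within_div = 0,
                       between_div = 0.01, seed = 12)
  expect_identical(p0$genomes$L1_S1, p0$genomes$L1_S2)
})

test_that("admixed query copies donors segment by segment", {
  p <- simulate_panel(2, 1, c(c1 = 6000L), 0.001, 0.02, seed = 21)
  # whole-genome single segment with no extra divergence == the donor
  seg_all <- data.frame(contig = "c1", start = 0L, end = 6000L,
                        donor_id = "L1_S1")
  q <- simulate_admixed_query(p, seg_all, extra_div = 0, seed = 1)
  expect_identical(q$genome[["c1"]], p$genomes$L1_S1[["c1"]])
  # two-donor mosaic: each side matches its donor
  segs <- data.frame(contig = "c1", start = c(0L, 3600L),
                     end = c(3600L, 6000L),
                     donor_id = c("L1_S1", "L2_S1"))
  q2 <- simulate_admixed_query(p, segs, extra_div = 0, seed = 1)
  expect_identical(substr(q2$genome[["c1"]], 1, 3600),
                   substr(p$genomes$L1_S1[["c1"]], 1, 3600))
  expect_identical(substr(q2$genome[["c1"]], 3601, 6000),
                   substr(p$genomes$L2_S1[["c1"]], 3601, 6000))
  expect_error(simulate_admixed_query(p, segs[0, ]), "at least one")
  expect_error(simulate_admixed_query(
    p, data.frame(contig = "c1", start = 0L, end = 6000L,
                  donor_id = "ghost")), "ghost")
  gap <- data.frame(contig = "c1", start = c(0L, 4000L),
                    end = c(3600L, 6000L), donor_id = "L1_S1")
  expect_error(simulate_admixed_query(p, gap), "tile")
})

test_that("region_truth labels breakpoint regions as mixed", {
  regions <- partition_reference(c(c1 = 6000L), 2000L)
  segs <- data.frame(contig = "c1", start = c(0L, 3600L),
                     end = c(3600L, 6000L), donor_id = c("d1", "d2"))
  tr <- region_truth(segs, regions)
  expect_equal(tr$donor_id, c("d1", NA, "d2"))
  expect_equal(tr$breakpoint, c(FALSE, TRUE, FALSE))
})

test_that("simulated reads hit the requested count, depth and determinism", {
  withr::with_seed(31, {
    genome <- c(c1 = random_dna(100000))
    reads <- simulate_reads(genome, coverage = 30, read_len = 150, err = 0,
                            seed = 7)
    expect_equal(nrow(reads), round(30 * 100000 / 150))
    # mean depth within 10% of target
    depth <- numeric(100000)
    for (i in seq_len(nrow(reads))) {
      idx <- reads$pos[i]:(reads$pos[i] + 149)
      depth[idx] <- depth[idx] + 1
    }
    expect_lt(abs(mean(depth) - 30) / 30, 0.1)
    # error-free reads match the genome at their stated positions
    expect_identical(reads$seq[1],
                     substr(genome[["c1"]], reads$pos[1], reads$pos[1] + 149))
    expect_identical(reads, simulate_reads(genome, coverage = 30,
                                           read_len = 150, err = 0, seed = 7))
    # with errors, sequences diverge at roughly the error rate
    re <- simulate_reads(genome, coverage = 2, read_len = 150, err = 0.01,
                         seed = 8)
    mm <- mapply(function(s, p) {
      sum(strsplit(s, "")[[1]] !=
            strsplit(substr(genome[["c1"]], p, p + 149), "")[[1]])
    }, re$seq, re$pos)
    expect_equal(mean(mm) / 150, 0.01, tolerance = 0.3)
  })
})

test_that("aneuploid depth simulation matches Poisson expectations", {
  lens <- c(a = 30000L, b = 30000L, z = 5000L)
  sim <- simulate_aneuploid_depth(lens, c(a = 3L, b = 1L, z = 0L),
                                  per_copy_depth = 30, seed = 5)
  expect_equal(mean(sim$depths$a), 90, tolerance = 0.02)
  expect_equal(mean(sim$depths$b), 30, tolerance = 0.02)
  expect_true(all(sim$depths$z == 0))
  sim2 <- simulate_aneuploid_depth(lens, c(a = 3L, b = 1L, z = 0L),
                                   per_copy_depth = 30, seed = 5)
  expect_identical(sim$depths, sim2$depths)
})

test_that("repeat gene simulation records block truth", {
  withr::with_seed(61, {
    units <- c(A = random_dna(50), B = random_dna(20))
    sim <- simulate_repeat_gene(units,
                                data.frame(unit_id = c("A", "B"),
                                           copies = c(5L, 3L),
                                           gap = c(151L, 0L)), seed = 9)
    expect_equal(nchar(sim$gene), 5 * 50 + 151 + 3 * 20)
    expect_equal(sim$truth$copies, c(5, 3))
    expect_equal(sim$truth$start, c(0L, 5 * 50 + 151))
    sim2 <- simulate_repeat_gene(units,
                                 data.frame(unit_id = c("A", "B"),
                                            copies = c(5L, 3L),
                                            gap = c(151L, 0L)), seed = 9)
    expect_identical(sim$gene, sim2$gene)
  })
})

test_that("SAM output round-trips through the alignment reader", {
  withr::with_seed(71, {
    genome <- c(c1 = random_dna(3000))
    reads <- simulate_reads(genome, coverage = 5, read_len = 100, err = 0,
                            seed = 3)
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(reads, contig_lengths(genome), sam)
    regions <- partition_reference(contig_lengths(genome), 1500L)
    rs <- region_sets_from_alignments(sam, regions, k = 21)
    ref <- region_sets_from_genome(genome, regions, k = 21)
    sc <- score_matrix(ref, list(rs))$score
    # 5x error-free coverage: nearly all reference k-mers observed
    expect_true(all(sc > 0.9))
  })
})
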