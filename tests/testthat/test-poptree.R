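test_that("minhash sketches are deterministic and respect min_freq", {
  counts <- c(AAA = 3L, ACG = 1L, CCC = 2L, GGG = 1L)
  sk <- minhash_sketch(counts, sketch_size = 10, min_freq = 2L,
                       sample_id = "s")
  expect_equal(length(sk$hashes), 2L)  # singletons dropped
  sk2 <- minhash_sketch(counts, sketch_size = 10, min_freq = 2L)
  expect_identical(sk$hashes, sk2$hashes)
  expect_false(is.unsorted(sk$hashes))
  # fewer distinct k-mers than sketch_size: all kept
  sk3 <- minhash_sketch(counts, sketch_size = 10, min_freq = 1L)
  expect_equal(length(sk3$hashes), 4L)
  # sketch truncates to the smallest hashes
  sk4 <- minhash_sketch(counts, sketch_size = 2, min_freq = 1L)
  expect_identical(sk4$hashes, sk3$hashes[1:2])
  expect_warning(minhash_sketch(c(AAA = 1L), min_freq = 2L), "empty")
})

test_that("sketch_jaccard on full sketches equals exact Jaccard", {
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- unique(replicate(60, random_dna(21)))
      b <- c(sample(a, 25), unique(replicate(30, random_dna(21))))
      exact <- length(intersect(a, b)) / length(union(a, b))
      ja <- sketch_jaccard(
        minhash_sketch(a, sketch_size = 1e6, min_freq = 1L, sample_id = "a"),
        minhash_sketch(b, sketch_size = 1e6, min_freq = 1L, sample_id = "b"))
      expect_equal(ja, exact)
    }
  })
})

test_that("bottom-sketch estimate is close to exact Jaccard on genomes", {
  withr::with_seed(14, {
    panel <- simulate_panel(1, 2, c(c1 = 100000L), within_div = 0.005,
                            between_div = 0, seed = 140)
    ka <- canonical_kmers(panel$genomes$L1_S1, 21)
    kb <- canonical_kmers(panel$genomes$L1_S2, 21)
    exact <- length(intersect(ka, kb)) / length(union(ka, kb))
    est <- sketch_jaccard(
      minhash_sketch(ka, sketch_size = 1000, min_freq = 1L, sample_id = "a"),
      minhash_sketch(kb, sketch_size = 1000, min_freq = 1L, sample_id = "b"))
    expect_lt(abs(est - exact), 0.05)
  })
})

test_that("mash_distance matches its closed form and conventions", {
  expect_equal(mash_distance(1, 21), 0)
  expect_equal(mash_distance(0, 21), 1)   # capped
  expect_equal(mash_distance(0.9, 21), -(1 / 21) * log(2 * 0.9 / 1.9))
  expect_equal(mash_distance(0.9, 21), 0.0025746, tolerance = 1e-4)
  expect_error(mash_distance(1.2, 21), "\\[0, 1\\]")
})

test_that("upgma reproduces the hand-worked 3-taxon example exactly", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(ape::write.tree(upgma(d)), "((A:0.1,B:0.1):0.2,C:0.3);")
  # two taxa split the distance evenly
  d2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("X", "Y"),
                                                      c("X", "Y")))
  expect_equal(ape::write.tree(upgma(d2)), "(X:0.2,Y:0.2);")
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("upgma agrees with an independent average-linkage implementation", {
  skip_if_not_installed("phangorn")
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(4:8, 1)
      labs <- paste0("t", seq_len(n))
      x <- matrix(runif(n * 3), n)
      d <- as.matrix(dist(x))
      dimnames(d) <- list(labs, labs)
      mine <- upgma(d)
      ref <- phangorn::upgma(as.dist(d))
      # same topology ...
      expect_equal(phangorn::RF.dist(mine, ref), 0)
      # ... and same ultrametric heights (cophenetic distances)
      expect_equal(ape::cophenetic.phylo(mine)[labs, labs],
                   ape::cophenetic.phylo(ref)[labs, labs],
                   tolerance = 1e-10)
    }
  })
})

test_that("ultrametric input is reproduced exactly", {
  d <- matrix(c(0, .2, .6, .6,
                .2, 0, .6, .6,
                .6, .6, 0, .1,
                .6, .6, .1, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- upgma(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)
})

test_that("trace_tree counts winners, aggregates nodes and lineages", {
  tree <- ape::read.tree(text = "((s1:1,s2:1):1,(s3:1,s4:1):1);")
  lmap <- c(s1 = "L1", s2 = "L1", s3 = "L2", s4 = "L2")
  asg <- data.frame(
    region_id = c("r1", "r2", "r3", "r4", "r5"),
    status = c("assigned", "assigned", "assigned", "low_similarity",
               "ambiguous_lineage"),
    max_score = c(.9, .9, .8, .3, .85),
    top_samples = I(list("s1", "s1", "s3", character(0), c("s2", "s3"))),
    lineages = I(list("L1", "L1", "L2", character(0), c("L1", "L2"))),
    lineage = c("L1", "L1", "L2", NA, NA),
    stringsAsFactors = FALSE)
  tr <- trace_tree(asg, tree, lmap)
  expect_equal(unname(tr$leaf_counts[c("s1", "s2", "s3", "s4")]),
               c(2L, 1L, 2L, 0L))
  # N counts every tied winner once
  expect_equal(tr$N, 5L)
  expect_equal(unname(tr$lineage_counts), c(3L, 2L))
  # root count equals N; internal clade counts equal leaf sums
  root <- as.character(length(tree$tip.label) + 1L)
  expect_equal(unname(tr$node_counts[root]), 5L)
  expect_equal(sort(unname(tr$node_counts)), c(2L, 3L, 5L))
  expect_equal(unname(tr$summary["n_low_similarity"]), 1L)
  # unknown winner is an error naming the sample
  bad <- asg; bad$top_samples[[1]] <- "nope"
  expect_error(trace_tree(bad, tree, lmap), "nope")
})

test_that("all-low-similarity assignments give N = 0", {
  tree <- ape::read.tree(text = "(s1:1,s2:1);")
  asg <- data.frame(region_id = c("r1", "r2"),
                    status = "low_similarity", max_score = 0.1,
                    top_samples = I(list(character(0), character(0))),
                    lineages = I(list(character(0), character(0))),
                    lineage = NA_character_, stringsAsFactors = FALSE)
  tr <- trace_tree(asg, tree, c(s1 = "L1", s2 = "L1"))
  expect_equal(tr$N, 0L)
  expect_equal(unname(tr$summary["n_traced"]), 0L)
})

test_that("trace output and annotated newick are well-formed", {
  tree <- ape::read.tree(text = "((s1:1,s2:1):1,s3:2);")
  lmap <- c(s1 = "L1", s2 = "L1", s3 = "L2")
  asg <- data.frame(region_id = c("r1", "r2"), status = "assigned",
                    max_score = .9,
                    top_samples = I(list("s1", "s3")),
                    lineages = I(list("L1", "L2")),
                    lineage = c("L1", "L2"), stringsAsFactors = FALSE)
  tr <- trace_tree(asg, tree, lmap)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  df <- read_tsv_output(path)
  expect_equal(sum(df$count[df$level == "leaf"]), tr$N)
  expect_true(grepl("s1\\[1\\]", trace_newick(tr, tree)))
})

test_that("lineage_monophyly detects clade recovery and its failure", {
  tree <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  good <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  bad <- c(a1 = "A", a2 = "B", b1 = "B", b2 = "A")
  expect_true(all(lineage_monophyly(tree, good)))
  expect_false(all(lineage_monophyly(tree, bad)))
})
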