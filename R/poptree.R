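# Population tree construction (MinHash/Mash + UPGMA) and tree tracing of
# sub-region winners.

#' MinHash bottom sketch of a k-mer multiset
#'
#' Discards k-mers below a multiplicity floor (the usual noise filter for
#' read data; use `min_freq = 1` for assemblies, where every k-mer occurs
#' once), hashes the remaining distinct canonical k-mers with a fixed
#' 64-bit hash, and keeps the `sketch_size` smallest hash values. Fixing
#' the hash makes sketches reproducible and comparable across runs.
#'
#' @param kmer_counts named integer vector: canonical k-mer -> multiplicity
#'   (e.g. from [kmer_counts()]); a bare character vector of k-mers is
#'   treated as having multiplicity 1 each.
#' @param sketch_size maximum number of hashes retained (default 1e6).
#' @param min_freq minimum k-mer multiplicity (default 2).
#' @param sample_id label stored in the sketch.
#' @param k k-mer length; inferred from the k-mers when missing.
#' @return A `minhash_sketch`: list with `sample_id`, `k`, `sketch_size`,
#'   `min_freq` and `hashes` (sorted ascending). Empty after filtering ->
#'   empty sketch with a warning.
#' @export
minhash_sketch <- function(kmer_counts, sketch_size = 1e6, min_freq = 2L,
                           sample_id = NA_character_, k = NULL) {
  if (sketch_size < 1) stop("sketch_size must be >= 1")
  if (is.character(kmer_counts) && is.null(names(kmer_counts))) {
    kmer_counts <- setNames(rep(1L, length(kmer_counts)), kmer_counts)
  }
  keep <- names(kmer_counts)[kmer_counts >= min_freq]
  if (is.null(k)) {
    k <- if (length(keep)) nchar(keep[[1]]) else
      if (length(kmer_counts)) nchar(names(kmer_counts)[[1]]) else NA_integer_
  }
  if (!length(keep)) {
    warning("no k-mers pass min_freq = ", min_freq, "; sketch is empty")
    hashes <- numeric(0)
  } else {
    hashes <- sort(unique(cpp_hash53(keep)))
    if (length(hashes) > sketch_size) hashes <- hashes[seq_len(sketch_size)]
  }
  structure(list(sample_id = sample_id, k = as.integer(k),
                 sketch_size = as.integer(sketch_size),
                 min_freq = as.integer(min_freq), hashes = hashes),
            class = "minhash_sketch")
}

#' Canonical k-mer multiplicities of sequences
#'
#' @param sequences character vector of sequences (contigs or reads).
#' @param k k-mer length (default 21).
#' @return named integer vector: canonical k-mer -> count.
#' @export
kmer_counts <- function(sequences, k = 21L) {
  cpp_kmer_counts(as.character(sequences), as.integer(k))
}

#' Sketch a genome or read set directly
#'
#' Convenience wrapper: [kmer_counts()] then [minhash_sketch()].
#'
#' @inheritParams kmer_counts
#' @inheritParams minhash_sketch
#' @export
sketch_sequences <- function(sequences, k = 21L, sketch_size = 1e6,
                             min_freq = 2L, sample_id = NA_character_) {
  minhash_sketch(kmer_counts(sequences, k), sketch_size = sketch_size,
                 min_freq = min_freq, sample_id = sample_id, k = k)
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch '%s': %d hashes (k=%d, size=%d, min_freq=%d)\n",
              x$sample_id, length(x$hashes), x$k, x$sketch_size, x$min_freq))
  invisible(x)
}

#' Jaccard index estimated from two bottom sketches
#'
#' Standard merged bottom-sketch estimator: let X be the `s` smallest
#' hashes of the union of both sketches (s = the smaller sketch size, or
#' fewer if the union is smaller); the estimate is
#' `|X (intersect) A (intersect) B| / |X|`. When the sketches hold the complete hash
#' sets (inputs smaller than the sketch size) this equals the exact
#' Jaccard index.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return Jaccard estimate in `[0, 1]`; `NA` if either sketch is empty.
#' @export
sketch_jaccard <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k) stop("sketches have different k")
  if (!length(a$hashes) || !length(b$hashes)) return(NA_real_)
  s <- min(a$sketch_size, b$sketch_size)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  if (length(merged) > s) merged <- merged[seq_len(s)]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  shared / length(merged)
}

#' Mash distance from a Jaccard estimate
#'
#' Converts a (MinHash-estimated) Jaccard index into the Mash distance, an
#' estimate of the per-base mutation rate between two sequences under a
#' Poisson model of k-mer survival: `d = -(1/k) * ln(2j / (1 + j))`.
#' `j = 1` gives 0; `j = 0` would be infinite and is capped at 1, as is any
#' value exceeding 1.
#'
#' @param j Jaccard index in `[0, 1]` (vectorised).
#' @param k k-mer length.
#' @return distance(s) in `[0, 1]`.
#' @examples
#' mash_distance(0.9, 21)  # ~0.0025746
#' @export
mash_distance <- function(j, k) {
  if (any(j < 0 | j > 1, na.rm = TRUE)) stop("j must be in [0, 1]")
  d <- ifelse(j <= 0, 1, -(1 / k) * log(2 * j / (1 + j)))
  pmin(pmax(d, 0), 1)
}

#' Pairwise Mash distance matrix of sketches
#'
#' @param sketches list of `minhash_sketch` objects (named by sample, or
#'   labelled from their `sample_id`s).
#' @return symmetric matrix of Mash distances with zero diagonal.
#' @export
mash_distance_matrix <- function(sketches) {
  ids <- names(sketches)
  if (is.null(ids)) ids <- vapply(sketches, function(s) s$sample_id, "")
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  k <- sketches[[1]]$k
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        mash_distance(sketch_jaccard(sketches[[i]], sketches[[j]]), k)
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric,
#' rooted tree: two clusters merging at distance `d` sit at height `d/2`,
#' and each child branch has length `d/2` minus the child's own height.
#' Tied merge candidates are resolved by the lexicographic order of the
#' clusters' smallest leaf labels, and children of every node are written
#' smallest-leaf first, so the output is fully deterministic.
#'
#' @param dist symmetric numeric matrix with zero diagonal and labelled
#'   rows/columns (or a `dist` object).
#' @return an `ape::phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(d))  # ((A:0.1,B:0.1):0.2,C:0.3);
#' @export
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(dist)
  if (is.null(labels)) stop("distance matrix must be labelled")
  n <- length(labels)
  if (n == 1L) return(ape::read.tree(text = sprintf("(%s:0);", labels)))

  # active clusters: newick fragment, height, size, smallest leaf label
  nwk <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  minleaf <- labels
  D <- dist
  active <- rep(TRUE, n)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    for (a in idx) for (b in idx) {
      if (a >= b) next
      cand <- sort(c(minleaf[a], minleaf[b]))
      if (is.null(best) || D[a, b] < best$d - 1e-15 ||
          (abs(D[a, b] - best$d) <= 1e-15 &&
           (cand[1] < best$key[1] ||
            (cand[1] == best$key[1] && cand[2] < best$key[2])))) {
        best <- list(a = a, b = b, d = D[a, b], key = cand)
      }
    }
    a <- best$a; b <- best$b
    if (minleaf[b] < minleaf[a]) { tmp <- a; a <- b; b <- tmp }
    h <- best$d / 2
    nwk_new <- sprintf("(%s:%s,%s:%s)",
                       nwk[a], format(h - height[a], digits = 15,
                                      scientific = FALSE),
                       nwk[b], format(h - height[b], digits = 15,
                                      scientific = FALSE))
    # size-weighted average linkage update, stored in slot a
    others <- setdiff(idx, c(a, b))
    if (length(others)) {
      D[a, others] <- D[others, a] <-
        (size[a] * D[a, others] + size[b] * D[b, others]) / (size[a] + size[b])
    }
    nwk[a] <- nwk_new
    height[a] <- h
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
  }
  ape::read.tree(text = paste0(nwk[which(active)], ";"))
}

#' Neighbor-joining tree (alternative to UPGMA)
#'
#' Thin wrapper over `ape::nj` for users preferring an additive rather
#' than ultrametric reference tree.
#'
#' @inheritParams upgma
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!inherits(dist, "dist")) dist <- as.dist(dist)
  ape::nj(dist)
}

#' Trace sub-region winners onto a population tree
#'
#' Every sub-region whose status is `assigned` or `ambiguous_lineage`
#' increments the count of each of its top-scoring samples by one (tied
#' samples all count). Counts are aggregated up the tree (each internal
#' node gets the sum over its descendant leaves) and over lineages. `N` is
#' the grand total over leaves — the number a tree-tracing display
#' normalises its edge thicknesses by. `low_similarity` and `missing`
#' regions are tallied separately in `summary`.
#'
#' @param assignments data.frame from [assign_top()].
#' @param tree `ape::phylo` whose tip labels include every winning sample.
#' @param lineage_map optional named character vector mapping samples to
#'   lineages (for `lineage_counts`).
#' @return A `trace_result`: list with `leaf_counts`, `node_counts` (named
#'   by internal node number), `lineage_counts`, `N` and `summary`.
#' @export
trace_tree <- function(assignments, tree, lineage_map = NULL) {
  stopifnot(inherits(tree, "phylo"))
  traced <- assignments$status %in% c("assigned", "ambiguous_lineage")
  winners <- unlist(assignments$top_samples[traced], use.names = FALSE)
  unknown <- setdiff(unique(winners), tree$tip.label)
  if (length(unknown)) {
    stop("top-scoring sample(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  leaf_counts <- setNames(integer(length(tree$tip.label)), tree$tip.label)
  if (length(winners)) {
    tab <- table(winners)
    leaf_counts[names(tab)] <- as.integer(tab)
  }
  N <- sum(leaf_counts)

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  node_counts <- setNames(integer(n_node), as.character(n_tip + seq_len(n_node)))
  if (n_node > 0) {
    # accumulate leaf counts up the tree in postorder
    total <- c(unname(leaf_counts), integer(n_node))
    ord <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in seq_len(nrow(ord))) {
      total[ord[e, 1]] <- total[ord[e, 1]] + total[ord[e, 2]]
    }
    node_counts[] <- total[n_tip + seq_len(n_node)]
  }

  lineage_counts <- NULL
  if (!is.null(lineage_map)) {
    lin <- lineage_map[names(leaf_counts)]
    lineage_counts <- vapply(split(leaf_counts, lin), sum, 0L)
  }
  summary <- c(n_regions = nrow(assignments),
               n_traced = sum(traced),
               n_low_similarity = sum(assignments$status == "low_similarity"),
               n_missing = sum(assignments$status == "missing"))
  structure(list(leaf_counts = leaf_counts, node_counts = node_counts,
                 lineage_counts = lineage_counts, N = N, summary = summary),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("trace_result: N = %d over %d leaves (%d regions traced)\n",
              x$N, length(x$leaf_counts), x$summary[["n_traced"]]))
  if (!is.null(x$lineage_counts)) {
    frac <- if (x$N > 0) x$lineage_counts / x$N else x$lineage_counts * NA
    for (l in names(x$lineage_counts)) {
      cat(sprintf("  %s: %d (%.1f%%)\n", l, x$lineage_counts[[l]],
                  100 * frac[[l]]))
    }
  }
  invisible(x)
}

#' Write a trace result as TSV
#'
#' One row per leaf and per lineage with its count and fraction of N; the
#' summary tallies are recorded in the header.
#'
#' @param x a `trace_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  rows <- data.frame(level = "leaf", name = names(x$leaf_counts),
                     count = unname(x$leaf_counts), stringsAsFactors = FALSE)
  if (!is.null(x$lineage_counts)) {
    rows <- rbind(rows, data.frame(level = "lineage",
                                   name = names(x$lineage_counts),
                                   count = unname(x$lineage_counts),
                                   stringsAsFactors = FALSE))
  }
  rows$fraction <- if (x$N > 0) rows$count / x$N else NA_real_
  write_tsv_output(rows, path, op = "trace",
                   params = as.list(c(N = x$N, x$summary)))
}

#' Annotated newick with per-node trace counts
#'
#' Returns the tree in newick form with each leaf and internal node
#' labelled by `[count]` comments, a compact exchange format for
#' tree-tracing displays.
#'
#' @param x a `trace_result`.
#' @param tree the `ape::phylo` the result was traced on.
#' @return single newick string.
#' @export
trace_newick <- function(x, tree) {
  t2 <- tree
  t2$tip.label <- sprintf("%s[%d]", tree$tip.label,
                          unname(x$leaf_counts[tree$tip.label]))
  t2$node.label <- sprintf("[%d]", unname(x$node_counts))
  ape::write.tree(t2)
}

#' Do lineages form monophyletic clades of a tree?
#'
#' Checks whether every lineage's samples form a clade of the (unrooted)
#' tree — the natural notion of recovering a generating topology whose
#' within-lineage structure is unresolved. The count of non-recovered
#' lineage clades equals the Robinson-Foulds distance between the tree and
#' the multifurcating lineage tree, restricted to the splits the latter
#' resolves.
#'
#' @param tree `ape::phylo`.
#' @param lineage_map named character vector sample -> lineage covering all
#'   tips.
#' @return named logical vector, one element per lineage.
#' @export
lineage_monophyly <- function(tree, lineage_map) {
  lins <- unique(unname(lineage_map[tree$tip.label]))
  vapply(setNames(lins, lins), function(l) {
    tips <- tree$tip.label[lineage_map[tree$tip.label] == l]
    if (length(tips) <= 1) return(TRUE)
    ape::is.monophyletic(tree, tips, reroot = TRUE)
  }, logical(1))
}
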