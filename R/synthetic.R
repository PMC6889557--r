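# Synthetic data generation: strain panels with lineage structure, admixed
# mosaic queries, aligned reads, aneuploid depth tracks and tandem-repeat
# genes. The mutation model is substitution-only, keeping all genomes
# coordinate-colinear with the ancestor so truth can be projected exactly
# onto reference sub-regions.

.random_genome <- function(lengths) {
  setNames(vapply(lengths, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    ""), names(lengths))
}

# Substitute each site independently with probability `rate`; the new base
# is uniform over the three alternatives (transitions and transversions
# equiprobable).
.mutate_genome <- function(genome, rate) {
  if (rate <= 0) return(genome)
  vapply(genome, function(seq) {
    n <- nchar(seq)
    n_mut <- rbinom(1L, n, rate)
    if (n_mut == 0L) return(seq)
    pos <- sample.int(n, n_mut)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                    "A", "C", "T",  "A", "C", "G"), nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, n_mut, replace = TRUE)
    chars[pos] <- alt[cbind(pick, match(chars[pos], colnames(alt)))]
    paste(chars, collapse = "")
  }, "")
}

#' Simulate a strain panel with lineage structure
#'
#' Generates a random ancestor genome, derives one founder per lineage by
#' substituting sites at rate `between_div`, and each strain from its
#' founder at rate `within_div`. Strains of one lineage are therefore about
#' `2 * within_div` apart and strains of different lineages about
#' `2 * (between_div + within_div)` apart — a clean hierarchical population
#' for testing lineage recovery. Strain ids are `L<lineage>_S<strain>`.
#'
#' @param n_lineages number of lineages.
#' @param strains_per_lineage strains per lineage.
#' @param genome named integer vector of contig lengths.
#' @param within_div substitution rate founder -> strain.
#' @param between_div substitution rate ancestor -> founder.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `ancestor` (named character vector), `genomes` (named
#'   list of panel genomes), `lineage_map` (strain -> lineage), and `truth`
#'   (list recording the generating parameters, seed and the lineage tree
#'   in newick form, with within-lineage structure unresolved).
#' @export
simulate_panel <- function(n_lineages, strains_per_lineage, genome,
                           within_div, between_div, seed) {
  stopifnot(n_lineages >= 1, strains_per_lineage >= 1)
  withr::with_seed(as.integer(seed), {
    ancestor <- .random_genome(genome)
    lineages <- sprintf("L%d", seq_len(n_lineages))
    genomes <- list()
    lineage_map <- character(0)
    clades <- character(n_lineages)
    for (li in seq_len(n_lineages)) {
      founder <- .mutate_genome(ancestor, between_div)
      ids <- sprintf("%s_S%d", lineages[li], seq_len(strains_per_lineage))
      for (si in seq_len(strains_per_lineage)) {
        genomes[[ids[si]]] <- .mutate_genome(founder, within_div)
      }
      lineage_map[ids] <- lineages[li]
      clades[li] <- if (strains_per_lineage == 1L) ids else
        sprintf("(%s)", paste(ids, collapse = ","))
    }
    truth <- list(kind = "panel", seed = as.integer(seed),
                  n_lineages = n_lineages,
                  strains_per_lineage = strains_per_lineage,
                  within_div = within_div, between_div = between_div,
                  contig_lengths = as.list(genome),
                  tree_newick = sprintf("(%s);", paste(clades, collapse = ",")))
    list(ancestor = ancestor, genomes = genomes, lineage_map = lineage_map,
         truth = truth)
  })
}

#' Simulate an admixed (mosaic) query genome
#'
#' Builds a query genome by copying donor sequence segment-by-segment from
#' panel strains — the synthetic analogue of an admixed genome whose
#' chromosomes are mosaics of different population lineages. Segments are
#' 0-based half-open, must tile each query contig without gaps or
#' overlaps, and every donor must be a panel member. `extra_div` adds
#' private substitutions on top of the mosaic.
#'
#' @param panel result of [simulate_panel()] (or a named list of genomes).
#' @param segments data.frame with columns `contig`, `start`, `end`,
#'   `donor_id`.
#' @param extra_div private substitution rate of the query (default 0).
#' @param seed integer seed.
#' @return list with `genome` (named character vector) and `truth`
#'   (segments, extra_div, seed).
#' @export
simulate_admixed_query <- function(panel, segments, extra_div = 0, seed = 1L) {
  genomes <- if (!is.null(panel$genomes)) panel$genomes else panel
  if (is.null(segments) || !nrow(segments)) {
    stop("segments must contain at least one row")
  }
  bad <- setdiff(unique(segments$donor_id), names(genomes))
  if (length(bad)) stop("donor(s) not in panel: ", paste(bad, collapse = ", "))
  withr::with_seed(as.integer(seed), {
    query <- character(0)
    for (ctg in unique(segments$contig)) {
      seg <- segments[segments$contig == ctg, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      ctg_len <- nchar(genomes[[seg$donor_id[1]]][[ctg]])
      if (seg$start[1] != 0L || seg$end[nrow(seg)] != ctg_len ||
          (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)]))) {
        stop("segments must tile contig ", ctg, " without gaps or overlaps")
      }
      query[[ctg]] <- paste(vapply(seq_len(nrow(seg)), function(i)
        substring(genomes[[seg$donor_id[i]]][[ctg]],
                  seg$start[i] + 1L, seg$end[i]), ""), collapse = "")
    }
    query <- .mutate_genome(query, extra_div)
    list(genome = query,
         truth = list(kind = "admixed_query", seed = as.integer(seed),
                      segments = segments, extra_div = extra_div))
  })
}

#' True donor of each sub-region
#'
#' Projects the segment truth of an admixed query onto a sub-region
#' partition: regions lying entirely inside one donor segment get that
#' donor; regions containing a segment boundary are flagged as breakpoint
#' regions (their truth is mixed).
#'
#' @param segments truth segments from [simulate_admixed_query()].
#' @param regions sub-region data.frame from [partition_reference()].
#' @return data.frame with `id`, `donor_id` (`NA` at breakpoints),
#'   `breakpoint` (logical).
#' @export
region_truth <- function(segments, regions) {
  donor <- rep(NA_character_, nrow(regions))
  brk <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    seg <- segments[segments$contig == regions$contig[i] &
                    segments$start < regions$end[i] &
                    segments$end > regions$start[i], , drop = FALSE]
    if (nrow(seg) == 1L) donor[i] <- seg$donor_id else brk[i] <- TRUE
  }
  data.frame(id = regions$id, donor_id = donor, breakpoint = brk,
             stringsAsFactors = FALSE)
}

#' Simulate aligned short reads from a genome
#'
#' Draws reads of fixed length with uniform start positions to an expected
#' depth of `coverage`, applies a uniform per-base substitution error rate,
#' and reports each read as an alignment at its true position with a
#' full-match CIGAR — the alignment is known by construction, no aligner
#' runs. Read count per contig is `round(coverage * contig_len / read_len)`.
#'
#' @param genome named character vector of contig sequences.
#' @param coverage target mean depth (default 30).
#' @param read_len read length in bases (default 150).
#' @param err per-base error (substitution) rate (default 0).
#' @param seed integer seed.
#' @param sample_id prefix for read names.
#' @return data.frame of SAM-style records (`qname`, `flag`, `rname`,
#'   `pos` 1-based, `mapq`, `cigar`, `seq`), writable with [write_sam()].
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 150L, err = 0,
                           seed = 1L, sample_id = "sim") {
  read_len <- as.integer(read_len)
  withr::with_seed(as.integer(seed), {
    recs <- lapply(names(genome), function(ctg) {
      len <- nchar(genome[[ctg]])
      if (len < read_len) return(NULL)
      n <- as.integer(round(coverage * len / read_len))
      if (n == 0L) return(NULL)
      starts <- sample.int(len - read_len + 1L, n, replace = TRUE)
      seqs <- substring(genome[[ctg]], starts, starts + read_len - 1L)
      if (err > 0) {
        n_err <- rbinom(1L, n * read_len, err)
        if (n_err > 0L) {
          at_read <- sample.int(n, n_err, replace = TRUE)
          at_pos <- sample.int(read_len, n_err, replace = TRUE)
          alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                          "A", "C", "T",  "A", "C", "G"), nrow = 3,
                        dimnames = list(NULL, c("A", "C", "G", "T")))
          pick <- sample.int(3L, n_err, replace = TRUE)
          for (e in seq_len(n_err)) {
            old <- substr(seqs[at_read[e]], at_pos[e], at_pos[e])
            substr(seqs[at_read[e]], at_pos[e], at_pos[e]) <-
              alt[pick[e], old]
          }
        }
      }
      data.frame(qname = sprintf("%s_%s_r%06d", sample_id, ctg, seq_len(n)),
                 flag = 0L, rname = ctg, pos = starts, mapq = 60L,
                 cigar = sprintf("%dM", read_len), seq = seqs,
                 stringsAsFactors = FALSE)
    })
    recs <- Filter(Negate(is.null), recs)
    if (!length(recs)) {
      stop("no reads simulated: every contig is shorter than read_len")
    }
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  })
}

#' Simulate a per-base depth track with aneuploid chromosomes
#'
#' Per-base depth is Poisson with mean `ploidy * per_copy_depth` for each
#' contig, emulating the read-depth signal that chromosome copy-number
#' estimation consumes.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param ploidies named integer vector of true copy numbers (same names).
#' @param per_copy_depth expected depth contributed by one chromosome copy
#'   (default 30).
#' @param seed integer seed.
#' @return list with `depths` (named list of per-base vectors) and `truth`
#'   (ploidies, per_copy_depth, seed).
#' @export
simulate_aneuploid_depth <- function(contig_lengths, ploidies,
                                     per_copy_depth = 30, seed = 1L) {
  stopifnot(all(names(contig_lengths) %in% names(ploidies)))
  withr::with_seed(as.integer(seed), {
    depths <- lapply(setNames(names(contig_lengths), names(contig_lengths)),
                     function(ctg) {
      rpois(contig_lengths[[ctg]], ploidies[[ctg]] * per_copy_depth)
    })
    list(depths = depths,
         truth = list(kind = "aneuploid_depth", seed = as.integer(seed),
                      ploidies = as.list(ploidies),
                      per_copy_depth = per_copy_depth))
  })
}

#' Write per-base depths as TSV
#'
#' @param depths named list of per-base depth vectors.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(depths)) {
    d <- depths[[ctg]]
    writeLines(sprintf("%s\t%d\t%d", ctg, seq_along(d), as.integer(d)), con)
  }
  invisible(path)
}

#' Simulate a gene built from tandem repeat blocks
#'
#' Concatenates blocks of exact repeat-unit copies separated by random
#' spacer sequence of the requested gap lengths, recording the true copy
#' number of each block — the ground truth for the repeat clustering and
#' copy-number estimator.
#'
#' @param units named character vector of repeat unit sequences.
#' @param layout data.frame with columns `unit_id`, `copies` (integer) and
#'   `gap` (spacer length after the block, 0 for adjacent blocks).
#' @param seed integer seed (spacers are random).
#' @return list with `gene` (string) and `truth` (per-block data.frame
#'   with unit, copies, start, end on the gene).
#' @export
simulate_repeat_gene <- function(units, layout, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    parts <- character(0)
    truth <- NULL
    pos <- 0L
    for (i in seq_len(nrow(layout))) {
      u <- layout$unit_id[i]
      if (!u %in% names(units)) stop("unknown unit: ", u)
      block <- strrep(units[[u]], layout$copies[i])
      truth <- rbind(truth, data.frame(
        unit_id = u, copies = as.numeric(layout$copies[i]),
        start = pos, end = pos + nchar(block), stringsAsFactors = FALSE))
      parts <- c(parts, block)
      pos <- pos + nchar(block)
      if (layout$gap[i] > 0) {
        spacer <- paste(sample(c("A", "C", "G", "T"), layout$gap[i],
                               replace = TRUE), collapse = "")
        parts <- c(parts, spacer)
        pos <- pos + layout$gap[i]
      }
    }
    list(gene = paste(parts, collapse = ""), truth = truth)
  })
}

#' Write a simulation truth object as JSON
#'
#' @param truth truth list from any `simulate_*` function.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
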