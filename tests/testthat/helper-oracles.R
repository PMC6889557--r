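# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles deliberately avoid the package's fast paths.

# reverse complement, one character at a time
rc_brute <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
  paste(comp[chars], collapse = "")
}

# canonical k-mer set by explicit window enumeration and per-window
# reverse-complement comparison
canonical_kmers_brute <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in 1:(n - k + 1)) {
    w <- substr(s, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    r <- rc_brute(w)
    out <- c(out, if (w <= r) w else r)
  }
  sort(unique(out))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# chain sorted hits into clusters by explicit scanning (gap rule oracle)
cluster_brute <- function(starts, ends, covs, unit_len, min_cov = 0.5,
                          gap_factor = 3.0) {
  keep <- covs >= min_cov
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(span_start = integer(0), span_end = integer(0),
                      copies = numeric(0)))
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out <- NULL
  cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - ce > gap_factor * unit_len) {
      out <- rbind(out, data.frame(span_start = cs, span_end = ce,
                                   copies = (ce - cs) / unit_len))
      cs <- starts[i]
      ce <- ends[i]
    } else {
      ce <- max(ce, ends[i])
    }
  }
  rbind(out, data.frame(span_start = cs, span_end = ce,
                        copies = (ce - cs) / unit_len))
}

# small similarity matrix built directly from named k-mer vectors
toy_matrix <- function(ref_sets, sample_sets_list, k = 3L) {
  panel <- lapply(names(sample_sets_list), function(s)
    structure(list(sample_id = s, k = k, sets = sample_sets_list[[s]],
                   read_support = NULL), class = "sample_region_sets"))
  score_matrix(ref_sets_as_srs(ref_sets, k), panel)
}

ref_sets_as_srs <- function(sets, k = 3L) {
  structure(list(sample_id = "ref", k = k, sets = sets, read_support = NULL),
            class = "sample_region_sets")
}
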