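#' Canonical k-mers of a nucleotide sequence
#'
#' Extracts all length-`k` windows of `sequence`, replaces each by the
#' lexicographic minimum of itself and its reverse complement (its canonical
#' form), and returns the distinct canonical k-mers. Canonicalisation makes
#' the set strand-invariant, so read orientation never matters downstream.
#' Windows containing any symbol other than A/C/G/T (case-insensitive) are
#' skipped rather than guessed at.
#'
#' @param sequence character vector of nucleotide sequences; k-mers are pooled
#'   over all elements.
#' @param k k-mer length (default 21).
#' @return Sorted character vector of distinct canonical k-mers. Sequences
#'   shorter than `k` contribute nothing; an empty input yields an empty set.
#' @examples
#' canonical_kmers("ACGTACGT", k = 4)
#' @export
canonical_kmers <- function(sequence, k = 21L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (length(sequence) == 0L) return(character(0))
  sort(cpp_canonical_kmers(as.character(sequence), k, TRUE))
}

#' Construct a k-mer set object
#'
#' Light container pairing a canonical k-mer collection with its k and a
#' source label. Most functions accept either a `kmer_set` or a bare
#' character vector of k-mers.
#'
#' @param members character vector of canonical k-mers (deduplicated here).
#' @param k k-mer length; inferred from `members` when missing.
#' @param source_id label of the sequence or sample of origin.
#' @return An object of class `kmer_set` with fields `k`, `members`,
#'   `source_id`.
#' @export
kmer_set <- function(members, k = NULL, source_id = NA_character_) {
  members <- sort(unique(as.character(members)))
  if (is.null(k)) {
    k <- if (length(members)) nchar(members[[1]]) else NA_integer_
  }
  k <- as.integer(k)
  if (length(members) && any(nchar(members) != k)) {
    stop("all members must have length k = ", k)
  }
  structure(list(k = k, members = members, source_id = source_id),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d canonical %d-mers (source: %s)\n",
              length(x$members), x$k, x$source_id))
  invisible(x)
}

.kmer_members <- function(x) {
  if (inherits(x, "kmer_set")) x$members else as.character(x)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences (A/C/G/T and IUPAC ambiguity codes).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtRYKMry km", "TGCAtgcaYRMKyr mk", x))
}

#' Containment of one k-mer set in another
#'
#' The fraction of the reference set's k-mers found in the target set,
#' `|ref / target| / |ref|`. Containment (rather than Jaccard) is the default
#' sub-region similarity because it is robust to the target sample carrying
#' extra k-mers, e.g. from sequencing errors or deeper coverage.
#'
#' @param ref_set,target_set `kmer_set` objects or character vectors of
#'   canonical k-mers.
#' @return Similarity in `[0, 1]`; `NA` if the reference set is empty (no
#'   score can be defined).
#' @examples
#' containment(c("AAA", "CCC"), c("AAA", "GGG"))  # 0.5
#' @export
containment <- function(ref_set, target_set) {
  ref <- .kmer_members(ref_set)
  if (length(ref) == 0L) return(NA_real_)
  tgt <- .kmer_members(target_set)
  sum(ref %in% tgt) / length(ref)
}

#' Jaccard index of two k-mer sets
#'
#' `|A intersect B| / |A union B|`; offered as an alternative sub-region
#' similarity to [containment()].
#'
#' @inheritParams containment
#' @return Jaccard index in `[0, 1]`; `NA` when both sets are empty.
#' @export
kmer_jaccard <- function(ref_set, target_set) {
  a <- .kmer_members(ref_set)
  b <- .kmer_members(target_set)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Write / read a k-mer set as sorted plain text
#'
#' One k-mer per line after `#`-prefixed header lines recording k and the
#' source label.
#'
#' @param x a `kmer_set`.
#' @param path file path.
#' @return `write_kmer_set` returns `path` invisibly; `read_kmer_set`
#'   returns a `kmer_set`.
#' @export
write_kmer_set <- function(x, path) {
  stopifnot(inherits(x, "kmer_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#kpaint kmer_set v%s", utils::packageVersion("kpaint")),
               sprintf("#k=%d", x$k),
               sprintf("#source_id=%s", x$source_id),
               x$members), con)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  k <- as.integer(sub("^#k=", "", grep("^#k=", lines, value = TRUE)[1]))
  src <- sub("^#source_id=", "", grep("^#source_id=", lines, value = TRUE)[1])
  kmer_set(lines[!hdr & nzchar(lines)], k = k, source_id = src)
}
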