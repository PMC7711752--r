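#' Exact canonical k-mer set of a genome
#'
#' Extracts the set of distinct canonical k-mers from one or more DNA
#' sequences. A canonical k-mer is the lexicographically smaller of a k-mer
#' and its reverse complement, which makes the set independent of the strand
#' an assembly happens to report. Windows containing any non-ACGT character
#' (ambiguity codes, gaps) are skipped, and k-mers never span record
#' boundaries. Input case is ignored, so soft-masked assemblies work as-is.
#'
#' This is the exact, full-set representation: it supports exact Jaccard
#' indices and the corrected overlap share, but for large collections the
#' sketch-based summaries ([minhash_sketch()], [hll_sketch()]) are the
#' practical choice; the full set is kept as the slow reference path.
#'
#' @param x Genome sequence(s): a character vector of DNA strings, a
#'   `Biostrings::DNAStringSet`, or the path of a FASTA file (optionally
#'   gzip-compressed).
#' @param k k-mer length in bases, between 1 and 26. Defaults to 16, the
#'   length at which the distance thresholds shipped with this package were
#'   characterised.
#' @return An object of class `kmer_set`: a list with elements `k` and
#'   `codes` (sorted 2-bit integer encodings of the canonical k-mers, stored
#'   as doubles). `length()` gives the cardinality and `as.character()`
#'   decodes back to k-mer strings in lexicographic order.
#' @examples
#' ks <- kmer_set("ACGTACGT", k = 4)
#' length(ks)
#' as.character(ks)
#' @export
kmer_set <- function(x, k = 16L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop("k must be a single integer >= 1")
  if (k > 26L)
    stop("k must be <= 26 (2-bit codes are stored exactly in doubles)")
  seqs <- as_dna_character(x)
  codes <- kmer_codes_cpp(seqs, k)
  structure(list(k = k, codes = codes), class = "kmer_set")
}

# Normalise the accepted genome inputs to a plain character vector.
as_dna_character <- function(x) {
  if (inherits(x, "kmer_set"))
    stop("input is already a kmer_set")
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    return(as.character(x))
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fna|fasta)(\\.gz)?$", x, ignore.case = TRUE))
    return(read_genome(x))
  if (!is.character(x))
    stop("genome input must be a character vector, DNAStringSet or FASTA path")
  x
}

#' Read a genome assembly from FASTA
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file and returns the
#' sequences as a character vector. Record IDs are kept as names but play no
#' role in k-mer extraction.
#'
#' @param path FASTA file path, plain or `.gz`.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  as.character(Biostrings::readDNAStringSet(path))
}

#' @export
length.kmer_set <- function(x) length(x$codes)

#' @export
as.character.kmer_set <- function(x, ...) decode_kmers_cpp(x$codes, x$k)

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d distinct canonical %d-mers\n", length(x$codes), x$k))
  invisible(x)
}

#' Write a canonical k-mer list to disk
#'
#' Dumps one canonical k-mer per line, unique and lexicographically sorted —
#' the plain-text exchange format produced by sorting a k-mer counter's dump.
#'
#' @param x A [kmer_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_list <- function(x, path) {
  stopifnot(inherits(x, "kmer_set"))
  writeLines(as.character(x), path)
  invisible(path)
}

check_kmer_pair <- function(a, b) {
  if (!inherits(a, "kmer_set") || !inherits(b, "kmer_set"))
    stop("both arguments must be kmer_set objects")
  if (a$k != b$k)
    stop("k-mer lengths differ (", a$k, " vs ", b$k, ")")
}

#' Exact Jaccard index of two k-mer sets
#'
#' The fraction of shared k-mers, |A intersect B| / |A union B|, computed on
#' the exact canonical k-mer sets.
#'
#' @param a,b [kmer_set()] objects with equal `k`.
#' @return Jaccard index in \[0, 1\].
#' @export
exact_jaccard <- function(a, b) {
  check_kmer_pair(a, b)
  na <- as.numeric(length(a$codes)); nb <- as.numeric(length(b$codes))
  if (na == 0 && nb == 0)
    stop("Jaccard index undefined for two empty k-mer sets")
  ni <- intersect_size_cpp(a$codes, b$codes)
  ni / (na + nb - ni)
}

#' Capture-recapture corrected k-mer overlap share
#'
#' The number of shared k-mers between two genomes, minus the overlap two
#' unrelated k-mer sets of the same sizes would show by chance
#' (|A|·|B| / 4^k, the capture-recapture expectation under uniform sampling
#' of the k-mer space), expressed as a share of the smaller set:
#'
#' \deqn{ (|A \cap B| - |A||B|/4^k) / \min(|A|, |B|) }
#'
#' The statistic is close to 1 for identical genomes, close to 0 (and may be
#' slightly negative) for unrelated ones, and is oriented as a similarity.
#'
#' @param a,b Non-empty [kmer_set()] objects with equal `k`.
#' @return Corrected overlap share, at most 1.
#' @examples
#' x <- kmer_set(paste(sample(c("A","C","G","T"), 200, TRUE), collapse = ""), k = 8)
#' corrected_overlap_share(x, x)  # 1 - |x| / 4^8
#' @export
corrected_overlap_share <- function(a, b) {
  check_kmer_pair(a, b)
  na <- as.numeric(length(a$codes)); nb <- as.numeric(length(b$codes))
  if (na == 0 || nb == 0)
    stop("corrected overlap share undefined for an empty k-mer set")
  ni <- intersect_size_cpp(a$codes, b$codes)
  (ni - na * nb / 4^a$k) / min(na, nb)
}
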