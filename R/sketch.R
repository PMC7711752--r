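#' Bottom-s MinHash sketch of a genome
#'
#' Summarises a genome's canonical k-mer set by the `s` smallest distinct
#' values of a seedable 64-bit hash over the k-mers. Two such sketches allow
#' an unbiased estimate of the Jaccard index of the underlying full sets via
#' the merged-sketch estimator ([sketch_jaccard()]), which in turn feeds the
#' ANI-proxy distance transform ([mash_distance()]).
#'
#' @param x Genome input accepted by [kmer_set()], or an existing `kmer_set`.
#' @param k k-mer length; ignored (taken from `x`) when `x` is a `kmer_set`.
#' @param s Sketch capacity: number of retained hash values. Default 100000,
#'   deliberately large so that distance estimates stay accurate for
#'   divergent genome pairs. Genomes with fewer than `s` distinct k-mers
#'   yield shorter (exact) sketches.
#' @param hash_seed Seed of the k-mer hash. Sketches are only comparable
#'   when built with the same seed.
#' @return Object of class `minhash_sketch`: list with `k`, `s`, `hash_seed`
#'   and `hashes` (strictly increasing hash values).
#' @export
minhash_sketch <- function(x, k = 16L, s = 100000L, hash_seed = 42L) {
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L) stop("sketch size s must be >= 1")
  ks <- if (inherits(x, "kmer_set")) x else kmer_set(x, k)
  structure(
    list(k = ks$k, s = s, hash_seed = as.integer(hash_seed),
         hashes = minhash_cpp(ks$codes, s, as.integer(hash_seed))),
    class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("minhash_sketch: k=%d, s=%d (%d hashes), seed=%d\n",
              x$k, x$s, length(x$hashes), x$hash_seed))
  invisible(x)
}

check_minhash_pair <- function(a, b) {
  if (!inherits(a, "minhash_sketch") || !inherits(b, "minhash_sketch"))
    stop("both arguments must be minhash_sketch objects")
  if (a$k != b$k || a$s != b$s || a$hash_seed != b$hash_seed)
    stop("incompatible sketches: k, s and hash_seed must match")
}

#' Jaccard estimate from two MinHash sketches
#'
#' Merged-sketch (bottom-s of the union) estimator: take the smallest
#' `min(s, |union|)` values of the merged hash lists and count the fraction
#' present in both sketches. Unbiased for the Jaccard index of the two full
#' k-mer sets, with standard error about `sqrt(j(1-j)/s)`.
#'
#' @param a,b Compatible [minhash_sketch()] objects.
#' @return Estimated Jaccard index in \[0, 1\].
#' @export
sketch_jaccard <- function(a, b) {
  check_minhash_pair(a, b)
  if (length(a$hashes) == 0L && length(b$hashes) == 0L)
    stop("Jaccard estimate undefined for two empty sketches")
  u <- sort(unique(c(a$hashes, b$hashes)))
  u <- u[seq_len(min(a$s, length(u)))]
  sum(u %in% a$hashes & u %in% b$hashes) / length(u)
}

#' Mash distance transform of a Jaccard index
#'
#' Converts a Jaccard index `j` of two k-mer sets into a per-site distance
#' under a Poisson model of random site substitution,
#' \deqn{D = -\frac{1}{k}\,\ln\frac{2j}{1+j},}
#' a proxy for one minus the average nucleotide identity. `j = 0` maps to
#' the maximal distance 1 (rather than infinity), and values are capped at 1.
#'
#' @param j Jaccard index in \[0, 1\] (vectorised).
#' @param k k-mer length used to compute `j`.
#' @return Distance in \[0, 1\]; 0 for identical genomes.
#' @examples
#' mash_distance(0.5, 16)
#' @export
mash_distance <- function(j, k = 16L) {
  if (any(!is.finite(j)) || any(j < 0) || any(j > 1))
    stop("j must lie in [0, 1]")
  if (k < 1) stop("k must be >= 1")
  d <- ifelse(j > 0, -(1 / k) * log(2 * j / (1 + j)), 1)
  pmin(d, 1)
}

# ---- HyperLogLog ----------------------------------------------------------

#' HyperLogLog sketch of a genome's k-mer set
#'
#' Fixed-memory cardinality summary: each canonical k-mer is hashed, the top
#' `p` bits select one of `2^p` registers, and the register keeps the maximal
#' 1-based position of the first set bit in the remaining hash bits.
#' Registers of two genomes can be combined position-wise by `max` to sketch
#' the union, which yields a Jaccard similarity by inclusion-exclusion
#' ([hll_similarity()]).
#'
#' @param x Genome input accepted by [kmer_set()], or an existing `kmer_set`.
#' @param k k-mer length; taken from `x` when it is a `kmer_set`.
#' @param p log2 of the register count, between 4 and 24. Default 20
#'   (about one million registers), giving a relative cardinality error of
#'   roughly 0.1%; reduce for speed when many pairs are compared.
#' @param hash_seed Seed of the k-mer hash.
#' @return Object of class `hll_sketch`: list with `k`, `p`, `hash_seed`,
#'   `registers` (integer vector of length `2^p`).
#' @export
hll_sketch <- function(x, k = 16L, p = 20L, hash_seed = 42L) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 4L || p > 24L)
    stop("p must be an integer in [4, 24]")
  ks <- if (inherits(x, "kmer_set")) x else kmer_set(x, k)
  structure(
    list(k = ks$k, p = p, hash_seed = as.integer(hash_seed),
         registers = hll_registers_cpp(ks$codes, p, as.integer(hash_seed))),
    class = "hll_sketch")
}

#' @export
print.hll_sketch <- function(x, ...) {
  cat(sprintf("hll_sketch: k=%d, p=%d (%d registers), seed=%d, est. cardinality %.0f\n",
              x$k, x$p, length(x$registers), x$hash_seed, hll_cardinality(x)))
  invisible(x)
}

#' Cardinality estimate of an HLL sketch
#'
#' Classic harmonic-mean estimator with the small-range linear-counting
#' correction (applied when the raw estimate is below `2.5 * 2^p` and empty
#' registers remain). No large-range correction is needed since the hash is
#' effectively collision-free at genomic cardinalities.
#'
#' @param x An [hll_sketch()], or a raw integer register vector.
#' @return Estimated number of distinct k-mers.
#' @export
hll_cardinality <- function(x) {
  reg <- if (inherits(x, "hll_sketch")) x$registers else x
  m <- length(reg)
  alpha <- if (m == 16) 0.673 else if (m == 32) 0.697 else if (m == 64) 0.709
           else 0.7213 / (1 + 1.079 / m)
  est <- alpha * m^2 / sum(2^(-reg))
  v <- sum(reg == 0L)
  if (est <= 2.5 * m && v > 0L) est <- m * log(m / v)
  est
}

check_hll_pair <- function(a, b) {
  if (!inherits(a, "hll_sketch") || !inherits(b, "hll_sketch"))
    stop("both arguments must be hll_sketch objects")
  if (a$k != b$k || a$p != b$p || a$hash_seed != b$hash_seed)
    stop("incompatible sketches: k, p and hash_seed must match")
}

#' Jaccard similarity from two HLL sketches
#'
#' Estimates |A|, |B| and |A union B| (union sketch = register-wise maximum)
#' with the HLL cardinality estimator and returns the inclusion-exclusion
#' Jaccard index, clamped at 0:
#' \deqn{\hat J = \max\!\big(0, (\hat C_A + \hat C_B - \hat C_{A\cup B}) / \hat C_{A\cup B}\big).}
#' Identical sketches give exactly 1. Oriented as a similarity: larger means
#' more alike.
#'
#' @param a,b Compatible [hll_sketch()] objects.
#' @return Estimated Jaccard similarity.
#' @export
hll_similarity <- function(a, b) {
  check_hll_pair(a, b)
  cu <- hll_cardinality(pmax(a$registers, b$registers))
  if (cu == 0) stop("similarity undefined for two empty sketches")
  max(0, (hll_cardinality(a) + hll_cardinality(b) - cu) / cu)
}

# ---- serialization --------------------------------------------------------

#' Save / load a sketch
#'
#' Sketches are written as versioned JSON so they can be computed once per
#' genome and reused across runs and methods. Hash values survive the
#' round-trip exactly.
#'
#' @param x A [minhash_sketch()] or [hll_sketch()].
#' @param path File path (conventionally `.json`).
#' @return `write_sketch()` returns `path` invisibly; `read_sketch()` returns
#'   the restored sketch object.
#' @export
write_sketch <- function(x, path) {
  if (inherits(x, "minhash_sketch")) {
    obj <- list(format = "fungidist_sketch", version = 1L, method = "minhash",
                k = x$k, s = x$s, hash_seed = x$hash_seed, payload = x$hashes)
  } else if (inherits(x, "hll_sketch")) {
    obj <- list(format = "fungidist_sketch", version = 1L, method = "hll",
                k = x$k, p = x$p, hash_seed = x$hash_seed, payload = x$registers)
  } else stop("not a sketch object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fungidist_sketch"))
    stop("not a fungidist sketch file: ", path)
  if (obj$method == "minhash") {
    structure(list(k = as.integer(obj$k), s = as.integer(obj$s),
                   hash_seed = as.integer(obj$hash_seed),
                   hashes = as.numeric(obj$payload)),
              class = "minhash_sketch")
  } else if (obj$method == "hll") {
    structure(list(k = as.integer(obj$k), p = as.integer(obj$p),
                   hash_seed = as.integer(obj$hash_seed),
                   registers = as.integer(obj$payload)),
              class = "hll_sketch")
  } else stop("unknown sketch method: ", obj$method)
}
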