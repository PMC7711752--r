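# Independent oracles: deliberately naive implementations that share no code
# with the package internals (string enumeration + Biostrings for reverse
# complements, grid scans, exhaustive pair classification).

# Canonical k-mer set by brute substring enumeration.
naive_kmer_set <- function(seqs, k) {
  kmers <- unlist(lapply(toupper(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(character())
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  sort(unique(pmin(kmers, rc)))
}

naive_jaccard <- function(A, B) {
  length(intersect(A, B)) / length(union(A, B))
}

naive_overlap_share <- function(A, B, k) {
  (length(intersect(A, B)) - length(A) * length(B) / 4^k) /
    min(length(A), length(B))
}

# Reverse complement of a whole sequence.
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Equal-error threshold by scanning a dense grid of candidate cuts.
grid_eer <- function(lower, higher, orientation = "distance", n_grid = 1e6) {
  rng <- range(c(lower, higher))
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  slo <- sort(lower); shi <- sort(higher)
  if (orientation == "distance") {
    wl <- 1 - findInterval(grid, slo) / length(slo)   # lower > t
    wh <- findInterval(grid, shi) / length(shi)       # higher <= t
  } else {
    wl <- findInterval(grid, slo, left.open = TRUE) / length(slo)  # lower < t
    wh <- 1 - findInterval(grid, shi, left.open = TRUE) / length(shi) # higher >= t
  }
  dd <- wl - wh
  ties <- which(abs(dd) == min(abs(dd)))
  # the share difference is a step function of t; pick the tie-plateau edge
  # that borders its sign change (the equal-error crossing)
  decreasing <- orientation == "distance" # d falls with t for distances
  i <- if (xor(decreasing, dd[ties[1]] < 0)) max(ties) else min(ties)
  list(threshold = grid[i],
       pooled = (wl[i] * length(slo) + wh[i] * length(shi)) /
         (length(slo) + length(shi)))
}

# Most specific shared rank of two lineage rows; pairs differing at phylum
# (or with a missing rank at the decision point) return NA.
naive_pair_level <- function(ra, rb) {
  lv <- c("species", "genus", "family", "order", "class", "phylum")
  for (i in seq_along(lv)) {
    l <- lv[i]
    if (is.na(ra[[l]]) || is.na(rb[[l]])) return(NA_character_)
    if (ra[[l]] == rb[[l]]) {
      if (l == "species") return("species")
      below <- lv[i - 1]
      if (is.na(ra[[below]]) || is.na(rb[[below]])) return(NA_character_)
      return(l)
    }
  }
  NA_character_
}

# Exhaustive stratum assignment over all C(n,2) pairs.
naive_strata <- function(records) {
  n <- nrow(records)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lev <- naive_pair_level(records[i, ], records[j, ])
    a <- sort(c(records$accession[i], records$accession[j]))
    out[[length(out) + 1L]] <- data.frame(accession_a = a[1], accession_b = a[2],
                                          level = lev, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_dna <- function(n, seed = NULL) {
  fungidist::random_genome(n, 0.5, seed = seed)
}
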