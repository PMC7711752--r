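# Hierarchical clade simulator: genomes whose pairwise divergence is layered
# by taxonomic rank, for validating every pipeline stage without downloads.

#' Random genome sequence
#'
#' I.i.d. bases with a target GC content split evenly between G and C (and
#' AT evenly between A and T). Deterministic under `seed`.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc_content Target GC fraction, strictly inside (0, 1).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return A single DNA string.
#' @export
random_genome <- function(length, gc_content = 0.5, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.finite(gc_content) || gc_content <= 0 || gc_content >= 1)
    stop("gc_content must lie strictly inside (0, 1)")
  with_seed(seed, {
    at <- (1 - gc_content) / 2
    gc <- gc_content / 2
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c(at, gc, gc, at)), collapse = "")
  })
}

#' Mutate a genome
#'
#' Each site is independently substituted with probability `p_sub` to one of
#' the three other bases (uniformly). Insertions/deletions of 1-10 bp are
#' then applied at per-site rate `indel_rate` (default 0, so that
#' substitution-only divergence matches closed-form k-mer survival models
#' exactly).
#'
#' @param sequence A single DNA string.
#' @param p_sub Per-site substitution probability in \[0, 1).
#' @param indel_rate Per-site probability of starting a 1-10 bp indel.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return The mutated DNA string.
#' @export
mutate_genome <- function(sequence, p_sub, indel_rate = 0, seed = NULL) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  if (!is.finite(p_sub) || p_sub < 0 || p_sub >= 1) stop("invalid p_sub")
  if (!is.finite(indel_rate) || indel_rate < 0 || indel_rate >= 1)
    stop("invalid indel_rate")
  if (p_sub == 0 && indel_rate == 0) return(sequence)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    v <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(v)
    hit <- which(runif(n) < p_sub)
    if (length(hit)) {
      # uniform over the three other bases: shift by 1..3 in base order
      cur <- match(v[hit], bases)
      v[hit] <- bases[((cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    }
    if (indel_rate > 0) {
      pos <- which(runif(length(v)) < indel_rate)
      for (p in rev(pos)) { # right to left so positions stay valid
        len <- sample.int(10L, 1L)
        if (runif(1) < 0.5) {
          v <- v[-(p:min(p + len - 1L, length(v)))]
        } else {
          v <- append(v, sample(bases, len, replace = TRUE), after = p)
        }
      }
    }
    paste(v, collapse = "")
  })
}

#' Configuration of a simulated clade registry
#'
#' Describes a balanced taxon tree (counts of children per parent at each
#' rank) and the per-rank divergence accumulated on the branch that creates
#' a new taxon at that rank. Branch divergences are jittered by a lognormal
#' rate multiplier (`rate_dispersion` = sdlog, mean 1) to emulate the heavy
#' rate heterogeneity real clades show, where within-rank distances spread
#' over orders of magnitude; set it to 0 for strictly deterministic branch
#' lengths.
#'
#' The default divergence profile increases strictly from strain to phylum,
#' which makes distance strata at successive ranks stochastically ordered —
#' the structure the threshold analysis assumes.
#'
#' @param genome_length Genome length in bases (default 50000).
#' @param gc_content GC fraction of the root genome (default 0.5).
#' @param n_phyla,n_classes,n_orders,n_families,n_genera,n_species Children
#'   per parent at each rank (defaults 2, 1, 1, 1, 5, 3).
#' @param genomes_per_species Genomes sampled per species (default 3).
#' @param divergence Named numeric vector of per-rank branch divergences
#'   (per-site substitution probability on the branch creating a taxon at
#'   that rank), names `strain`, `species`, `genus`, `family`, `order`,
#'   `class`, `phylum`.
#' @param rate_dispersion sdlog of the lognormal branch-rate multiplier
#'   (default 0.7).
#' @param indel_rate Per-site indel rate on every branch (default 0).
#' @param seed Master seed of the registry (default 1).
#' @return Object of class `clade_config` (a validated list).
#' @export
clade_config <- function(genome_length = 50000L, gc_content = 0.5,
                         n_phyla = 2L, n_classes = 1L, n_orders = 1L,
                         n_families = 1L, n_genera = 5L, n_species = 3L,
                         genomes_per_species = 3L,
                         divergence = c(strain = 0.002, species = 0.03,
                                        genus = 0.08, family = 0.12,
                                        order = 0.16, class = 0.20,
                                        phylum = 0.25),
                         rate_dispersion = 0.7,
                         indel_rate = 0, seed = 1L) {
  need <- c("strain", "species", "genus", "family", "order", "class", "phylum")
  if (!all(need %in% names(divergence)))
    stop("divergence must name all of: ", paste(need, collapse = ", "))
  divergence <- divergence[need]
  if (any(!is.finite(divergence)) || any(divergence < 0) || any(divergence >= 1))
    stop("divergences must lie in [0, 1)")
  counts <- c(n_phyla, n_classes, n_orders, n_families, n_genera, n_species,
              genomes_per_species)
  if (any(counts < 1)) stop("all taxon counts must be >= 1")
  if (rate_dispersion < 0) stop("rate_dispersion must be >= 0")
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content,
                 n_phyla = as.integer(n_phyla), n_classes = as.integer(n_classes),
                 n_orders = as.integer(n_orders), n_families = as.integer(n_families),
                 n_genera = as.integer(n_genera), n_species = as.integer(n_species),
                 genomes_per_species = as.integer(genomes_per_species),
                 divergence = divergence, rate_dispersion = rate_dispersion,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "clade_config")
}

# One branch: lognormal rate multiplier (mean 1) truncated to [1/3, 3].
# The bounds keep the heterogeneity within an order of magnitude, so strata
# whose nominal divergences differ by more than ~9x can never cross.
branch_divergence <- function(p, sdlog) {
  if (p == 0) return(0)
  if (sdlog == 0) return(p)
  m <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  min(p * min(max(m, 1 / 3), 3), 0.95)
}

#' Generate a synthetic genome registry
#'
#' Builds the taxon tree top-down from a single root genome: each new taxon
#' at a rank is the parent ancestor mutated by that rank's (jittered) branch
#' divergence, and each genome is its species ancestor mutated by the strain
#' divergence. The result mimics a registry of assemblies: a lineage table
#' over six ranks, one sequence per accession, and a truth table giving the
#' realised divergence (sum of branch substitution loads on the connecting
#' path) for every genome pair.
#'
#' With `edge_cases = TRUE` three curation test cases are appended to the
#' first genus: a hybrid-named species and a strain-code-named species (both
#' sitting almost on top of an existing species, as their real counterparts
#' do), and an overdispersed species whose within-species divergence exceeds
#' the species-level divergence (the "unexpectedly diverse species" class of
#' outliers). For these injected species the truth table treats the branch
#' as departing at the genus level, a slight simplification.
#'
#' @param config A [clade_config()].
#' @param dir If non-`NULL`, write one gzipped FASTA per genome
#'   (`<accession>.fna.gz`), `lineages.tsv` and `truth.tsv` into this
#'   directory.
#' @param edge_cases Inject the named curation edge cases (default `FALSE`).
#' @return Object of class `synthetic_registry`: list with `records`
#'   (lineage data frame with a `flags` column), `sequences` (named list of
#'   DNA strings), `truth` (data frame `accession_a`, `accession_b`,
#'   `divergence`), `config`, and `dir`.
#' @export
generate_registry <- function(config = clade_config(), dir = NULL,
                              edge_cases = FALSE) {
  stopifnot(inherits(config, "clade_config"))
  with_seed(config$seed, {
    dv <- config$divergence
    sdlog <- config$rate_dispersion
    root <- random_genome(config$genome_length, config$gc_content)

    rows <- list()     # per-genome lineage rows
    seqs <- list()     # per-genome sequence
    paths <- list()    # per-genome taxon path (phylum..species)
    cums <- list()     # per-genome cumulative divergence from root at each
                       # ancestor: phylum, class, order, family, genus,
                       # species, strain (= the genome itself)
    acc_i <- 0L; sp_global <- 0L; gen_global <- 0L

    emit_genomes <- function(anc_sp, lineage6, cum6, strain_div, flags) {
      for (g in seq_len(config$genomes_per_species)) {
        d <- branch_divergence(strain_div, sdlog)
        acc_i <<- acc_i + 1L
        acc <- sprintf("GCA_%06d.1", acc_i)
        seqs[[acc]] <<- mutate_genome(anc_sp, d, config$indel_rate)
        rows[[acc]] <<- data.frame(accession = acc,
                                   species = lineage6[["species"]],
                                   genus = lineage6[["genus"]],
                                   family = lineage6[["family"]],
                                   order = lineage6[["order"]],
                                   class = lineage6[["class"]],
                                   phylum = lineage6[["phylum"]],
                                   flags = flags, stringsAsFactors = FALSE)
        paths[[acc]] <<- unname(lineage6[c("phylum", "class", "order",
                                           "family", "genus", "species")])
        cums[[acc]] <<- c(cum6, strain = unname(cum6[["species"]]) + d)
      }
    }

    for (ph in seq_len(config$n_phyla)) {
      phylum <- sprintf("Phylum%02d", ph)
      d_ph <- branch_divergence(dv[["phylum"]], sdlog)
      anc_ph <- mutate_genome(root, d_ph, config$indel_rate)
      for (cl in seq_len(config$n_classes)) {
        class_ <- sprintf("%s_Class%02d", phylum, cl)
        d_cl <- branch_divergence(dv[["class"]], sdlog)
        anc_cl <- mutate_genome(anc_ph, d_cl, config$indel_rate)
        for (or in seq_len(config$n_orders)) {
          order_ <- sprintf("%s_Order%02d", class_, or)
          d_or <- branch_divergence(dv[["order"]], sdlog)
          anc_or <- mutate_genome(anc_cl, d_or, config$indel_rate)
          for (fa in seq_len(config$n_families)) {
            family_ <- sprintf("%s_Family%02d", order_, fa)
            d_fa <- branch_divergence(dv[["family"]], sdlog)
            anc_fa <- mutate_genome(anc_or, d_fa, config$indel_rate)
            for (ge in seq_len(config$n_genera)) {
              gen_global <- gen_global + 1L
              genus <- sprintf("Genus%03d", gen_global)
              d_ge <- branch_divergence(dv[["genus"]], sdlog)
              anc_ge <- mutate_genome(anc_fa, d_ge, config$indel_rate)
              cum_ge <- c(phylum = d_ph, class = d_ph + d_cl,
                          order = d_ph + d_cl + d_or,
                          family = d_ph + d_cl + d_or + d_fa,
                          genus = d_ph + d_cl + d_or + d_fa + d_ge)
              first_genus <- ph == 1L && cl == 1L && or == 1L &&
                fa == 1L && ge == 1L
              for (sp in seq_len(config$n_species)) {
                sp_global <- sp_global + 1L
                species <- sprintf("%s epithetum%04d", genus, sp_global)
                d_sp <- branch_divergence(dv[["species"]], sdlog)
                anc_sp <- mutate_genome(anc_ge, d_sp, config$indel_rate)
                lineage6 <- c(species = species, genus = genus,
                              family = family_, order = order_,
                              class = class_, phylum = phylum)
                cum6 <- c(cum_ge, species = unname(cum_ge[["genus"]]) + d_sp)
                emit_genomes(anc_sp, lineage6, cum6, dv[["strain"]], "")
                if (edge_cases && first_genus && sp == 1L) {
                  near <- function(nm, flag, strain_div, anc, extra) {
                    l6 <- lineage6; l6[["species"]] <- nm
                    c6 <- cum6; c6[["species"]] <- c6[["species"]] + extra
                    emit_genomes(anc, l6, c6, strain_div, flag)
                  }
                  hyb <- sprintf("%s epithetum%04d x %s epithetum%04d",
                                 genus, sp_global, genus, sp_global + 1L)
                  near(hyb, "hybrid", dv[["strain"]],
                       mutate_genome(anc_sp, dv[["strain"]], config$indel_rate),
                       dv[["strain"]])
                  strn <- sprintf("%s sp. SYN%04d", genus, sp_global)
                  near(strn, "strain_named", dv[["strain"]],
                       mutate_genome(anc_sp, dv[["strain"]], config$indel_rate),
                       dv[["strain"]])
                  wide <- sprintf("%s varia%04d", genus, sp_global)
                  near(wide, "outlier_species", 2 * dv[["species"]],
                       mutate_genome(anc_ge, d_sp, config$indel_rate), d_sp)
                }
              }
            }
          }
        }
      }
    }

    records <- do.call(rbind, rows)
    rownames(records) <- NULL

    # pairwise truth: cum_a + cum_b - 2 * cum(deepest shared ancestor)
    accs <- records$accession
    if (length(accs) >= 2L) {
      path_mat <- do.call(rbind, paths[accs])
      cum_mat <- do.call(rbind, cums[accs])
      pr <- combn(length(accs), 2L)
      lvl <- c("phylum", "class", "order", "family", "genus", "species")
      div <- vapply(seq_len(ncol(pr)), function(jj) {
        i1 <- pr[1L, jj]; i2 <- pr[2L, jj]
        shared <- which(path_mat[i1, ] == path_mat[i2, ])
        cum_anc <- if (length(shared)) cum_mat[i1, lvl[max(shared)]] else 0
        cum_mat[i1, "strain"] + cum_mat[i2, "strain"] - 2 * cum_anc
      }, numeric(1))
      truth <- data.frame(accession_a = pmin(accs[pr[1L, ]], accs[pr[2L, ]]),
                          accession_b = pmax(accs[pr[1L, ]], accs[pr[2L, ]]),
                          divergence = div, stringsAsFactors = FALSE)
    } else {
      truth <- data.frame(accession_a = character(), accession_b = character(),
                          divergence = numeric(), stringsAsFactors = FALSE)
    }

    reg <- structure(list(records = records, sequences = seqs, truth = truth,
                          config = config, dir = dir),
                     class = "synthetic_registry")
    if (!is.null(dir)) write_registry(reg, dir)
    reg
  })
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf("synthetic_registry: %d genomes, %d species, %d genera (%d bp each)\n",
              nrow(x$records), length(unique(x$records$species)),
              length(unique(x$records$genus)), x$config$genome_length))
  invisible(x)
}

#' Write a synthetic registry to disk
#'
#' One gzipped FASTA per genome (`<accession>.fna.gz`), a lineage TSV as
#' consumed by [load_lineages()], and the pairwise truth TSV.
#'
#' @param registry A `synthetic_registry`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "synthetic_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(registry$sequences)) {
    ss <- Biostrings::DNAStringSet(registry$sequences[[acc]])
    names(ss) <- acc
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(acc, ".fna.gz")),
                                compress = TRUE)
  }
  lin <- registry$records[c("accession", RANK_LEVELS)]
  write.table(lin, file.path(dir, "lineages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(registry$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
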