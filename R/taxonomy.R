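# Lineage annotation, dataset curation and rank-stratified pair enumeration.

RANK_LEVELS <- c("species", "genus", "family", "order", "class", "phylum")

# Default curation lists: genera with unexpectedly short between-species
# distances and species with unexpectedly high within-species diversity in
# public fungal genome collections. Fully user-overridable.
OUTLIER_GENERA <- c("Komagataella", "Calonectria", "Coccidioides", "Alternaria")
OUTLIER_SPECIES <- c("Rhizoctonia solani", "Debaryomyces hansenii",
                     "Blumeria graminis", "Parastagonospora avenae",
                     "Schyzophyllum commune", "Rhodotorula toruloides",
                     "Hortaea werneckii", "Microbotryum violaceum")

#' Load a lineage table
#'
#' Reads a tab-separated table mapping genome accessions to their taxonomic
#' lineage at six ranks: species, genus, family, order, class, phylum. A
#' header row with those column names (plus `accession`) is required; column
#' order is free and extra columns are ignored. Blank cells become `NA`, the
#' missing-rank sentinel; records missing a rank are skipped by the strata
#' that need it. Taxon names are compared as exact strings downstream, so the
#' only normalisation applied here is whitespace trimming.
#'
#' @param path Path of the TSV file (or a connection).
#' @return A data frame with columns `accession`, `species`, `genus`,
#'   `family`, `order`, `class`, `phylum`, one row per accession.
#' @export
load_lineages <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = c("", "NA"))
  need <- c("accession", RANK_LEVELS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("lineage table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[need]
  for (col in need) df[[col]] <- trimws(df[[col]])
  df[df == ""] <- NA
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup))
    stop("duplicate accession(s) in lineage table: ",
         paste(unique(dup), collapse = ", "))
  if (anyNA(df$accession)) stop("lineage table has rows without an accession")
  df
}

#' Convert an NCBI ranked-lineage dump to the package's lineage TSV
#'
#' Thin convenience converter for the `rankedlineage.dmp` dialect
#' (pipe-and-tab separated: tax_id, tax_name, species, genus, family, order,
#' class, phylum, kingdom, superkingdom). Rows are matched to accessions via
#' an assembly table with columns `accession` and `taxid` (or
#' `organism_name`, matched against tax_name). For leaf taxa the dump leaves
#' the species field empty and puts the binomial in tax_name; that case is
#' filled in from tax_name.
#'
#' @param dmp_path Path to `rankedlineage.dmp`.
#' @param assemblies Data frame with `accession` and `taxid` or
#'   `organism_name` columns.
#' @return Lineage data frame as returned by [load_lineages()].
#' @export
convert_rankedlineage <- function(dmp_path, assemblies) {
  raw <- readLines(dmp_path)
  parts <- strsplit(sub("\\t\\|$", "", raw), "\t\\|\t")
  mat <- do.call(rbind, lapply(parts, function(p) { length(p) <- 10L; p }))
  dmp <- data.frame(taxid = trimws(mat[, 1]), tax_name = trimws(mat[, 2]),
                    species = trimws(mat[, 3]), genus = trimws(mat[, 4]),
                    family = trimws(mat[, 5]), order = trimws(mat[, 6]),
                    class = trimws(mat[, 7]), phylum = trimws(mat[, 8]),
                    stringsAsFactors = FALSE)
  blank_species <- is.na(dmp$species) | dmp$species == ""
  dmp$species[blank_species] <- dmp$tax_name[blank_species]
  key <- if ("taxid" %in% names(assemblies)) "taxid" else "organism_name"
  if (!key %in% names(assemblies) || !"accession" %in% names(assemblies))
    stop("assemblies must have columns accession and taxid (or organism_name)")
  dmp_key <- if (key == "taxid") dmp$taxid else dmp$tax_name
  idx <- match(as.character(assemblies[[key]]), dmp_key)
  if (anyNA(idx))
    stop("no lineage found for accession(s): ",
         paste(assemblies$accession[is.na(idx)], collapse = ", "))
  out <- cbind(data.frame(accession = assemblies$accession,
                          stringsAsFactors = FALSE),
               dmp[idx, RANK_LEVELS])
  rownames(out) <- NULL
  out[out == ""] <- NA
  out
}

#' Keep species with enough genomes, cap over-represented ones
#'
#' Drops every species represented by fewer than `min_n` genomes and
#' downsamples species with more than `max_n` genomes to `max_n`, uniformly
#' at random, to limit the over-representation of intensely sequenced
#' species. Records whose species is missing are dropped (they cannot
#' satisfy the minimum). The operation is idempotent and, given `seed`,
#' reproducible.
#'
#' @param records Lineage data frame (as from [load_lineages()]), one row per
#'   genome.
#' @param min_n Minimum genomes per retained species (default 3).
#' @param max_n Maximum genomes per species before downsampling (default 10).
#' @param seed RNG seed for the downsampling; `NULL` uses the current stream.
#' @return The filtered data frame.
#' @export
filter_min_max_per_species <- function(records, min_n = 3L, max_n = 10L,
                                       seed = NULL) {
  stopifnot(min_n >= 1L, max_n >= min_n)
  records <- records[!is.na(records$species), , drop = FALSE]
  counts <- table(records$species)
  records <- records[counts[records$species] >= min_n, , drop = FALSE]
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), records$species), function(i) {
      if (length(i) > max_n) sort(sample(i, max_n)) else i
    }), use.names = FALSE)
  })
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Curate a genome set before threshold estimation
#'
#' Removes records that blur the species boundary for reasons of nomenclature
#' rather than biology: hybrid-named species (species string containing
#' `" x "` or the word "hybrid"), species named by a strain code instead of
#' an epithet (`"Genus sp. CODE"`), and user-listed outlier genera and
#' species. Detection of hybrids and strain names is by explicit, auditable
#' regular expressions since no registry flags them consistently.
#'
#' @param records Lineage data frame, one row per genome.
#' @param exclude_genera Character vector of genera to drop wholesale;
#'   defaults to genera with anomalously short between-species distances.
#' @param exclude_species Species to drop; defaults to species with
#'   anomalously high within-species diversity.
#' @param drop_hybrids Drop hybrid-named species (default `TRUE`).
#' @param drop_strain_named Drop `"Genus sp. CODE"` species (default `TRUE`).
#' @return A list with `records` (retained rows) and `audit` (data frame of
#'   `accession`, `species`, `reason` for every removal).
#' @export
curate <- function(records,
                   exclude_genera = OUTLIER_GENERA,
                   exclude_species = OUTLIER_SPECIES,
                   drop_hybrids = TRUE,
                   drop_strain_named = TRUE) {
  curate_records(records, exclude_genera, exclude_species,
                 drop_hybrids, drop_strain_named)
}

# core kept separate so pipeline code can use it while `curate` is also the
# name of delineate()'s logical switch
curate_records <- function(records, exclude_genera, exclude_species,
                           drop_hybrids, drop_strain_named) {
  sp <- records$species
  reason <- rep(NA_character_, nrow(records))
  is_hybrid <- !is.na(sp) &
    grepl("( x )|(\\bhybrid\\b)", sp, ignore.case = TRUE)
  is_strain <- !is.na(sp) &
    grepl("\\bsp\\.? +[A-Za-z0-9_-]*[0-9][A-Za-z0-9_-]*\\b", sp)
  if (drop_hybrids) reason[is_hybrid] <- "hybrid"
  if (drop_strain_named) reason[is.na(reason) & is_strain] <- "strain_named"
  reason[is.na(reason) & !is.na(records$genus) &
           records$genus %in% exclude_genera] <- "outlier_genus"
  reason[is.na(reason) & !is.na(sp) & sp %in% exclude_species] <- "outlier_species"
  drop <- !is.na(reason)
  audit <- data.frame(accession = records$accession[drop],
                      species = sp[drop],
                      reason = reason[drop],
                      stringsAsFactors = FALSE)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, audit = audit)
}

#' Enumerate genome pairs in one taxonomic rank stratum
#'
#' The species stratum contains every unordered pair of genomes of the same
#' species. The stratum of a higher level L contains every unordered pair
#' sharing the taxon at L but differing at the level immediately below
#' (genus stratum: same genus, different species; family stratum: same
#' family, different genus; and so on). A record missing either taxon is
#' skipped for that stratum, so together the six strata partition all
#' complete-lineage pairs except those that already differ at phylum.
#'
#' @param records Lineage data frame, one row per genome; accessions unique.
#' @param level One of `"species"`, `"genus"`, `"family"`, `"order"`,
#'   `"class"`, `"phylum"`.
#' @return Data frame with columns `accession_a`, `accession_b` (unordered,
#'   `a < b`), `level` and `anchor_taxon` (the shared taxon).
#' @export
enumerate_rank_pairs <- function(records, level) {
  if (!level %in% RANK_LEVELS)
    stop("unknown taxonomic level: ", level)
  if (anyDuplicated(records$accession))
    stop("duplicate accessions in records")
  empty <- data.frame(accession_a = character(), accession_b = character(),
                      level = character(), anchor_taxon = character(),
                      stringsAsFactors = FALSE)
  if (level == "species") {
    sub_level <- NULL
    ok <- !is.na(records$species)
  } else {
    sub_level <- RANK_LEVELS[match(level, RANK_LEVELS) - 1L]
    ok <- !is.na(records[[level]]) & !is.na(records[[sub_level]])
  }
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) < 2L) return(empty)
  groups <- split(seq_len(nrow(rec)), rec[[level]])
  res <- lapply(names(groups), function(tax) {
    i <- groups[[tax]]
    if (length(i) < 2L) return(NULL)
    pr <- combn(i, 2L)
    if (!is.null(sub_level)) {
      sub <- rec[[sub_level]]
      pr <- pr[, sub[pr[1L, ]] != sub[pr[2L, ]], drop = FALSE]
    }
    if (ncol(pr) == 0L) return(NULL)
    a <- rec$accession[pr[1L, ]]
    b <- rec$accession[pr[2L, ]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data.frame(accession_a = a, accession_b = b, level = level,
               anchor_taxon = tax, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  res <- res[order(res$accession_a, res$accession_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate pairs at all six rank strata
#'
#' @param records Lineage data frame.
#' @param levels Levels to enumerate (default all six).
#' @return One data frame stacking the per-level strata of
#'   [enumerate_rank_pairs()].
#' @export
enumerate_all_strata <- function(records, levels = RANK_LEVELS) {
  out <- do.call(rbind, lapply(levels, enumerate_rank_pairs, records = records))
  rownames(out) <- NULL
  out
}

#' Write / read a stratum table
#'
#' @param pairs Stratum data frame from [enumerate_rank_pairs()].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_strata <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
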