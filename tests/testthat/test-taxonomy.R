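# Lineage parsing, dataset filtering/curation, rank-stratified pairs.

lineage_row <- function(acc, sp, ge = sub(" .*", "", sp), fa = "Fam1",
                        or = "Ord1", cl = "Cls1", ph = "Phy1") {
  data.frame(accession = acc, species = sp, genus = ge, family = fa,
             order = or, class = cl, phylum = ph, stringsAsFactors = FALSE)
}

write_lineage_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  path
}

test_that("lineage TSV parsing: full rows, sentinels, duplicates, columns", {
  dir <- withr::local_tempdir()
  df <- rbind(
    lineage_row("GCA_1", "Hortaea werneckii", "Hortaea", "Teratosphaeriaceae",
                "Capnodiales", "Dothideomycetes", "Ascomycota"),
    lineage_row("GCA_2", "Hortaea thailandica", "Hortaea", NA,
                "Capnodiales", "Dothideomycetes", "Ascomycota"))
  f <- write_lineage_tsv(df, file.path(dir, "lin.tsv"))
  got <- load_lineages(f)
  expect_equal(got$species[1], "Hortaea werneckii")
  expect_equal(got$family[1], "Teratosphaeriaceae")
  expect_true(is.na(got$family[2]))    # blank cell -> missing-rank sentinel
  dup <- rbind(df, df[1, ])
  f2 <- write_lineage_tsv(dup, file.path(dir, "dup.tsv"))
  expect_error(load_lineages(f2), "GCA_1")
  f3 <- write_lineage_tsv(df[, -3], file.path(dir, "short.tsv"))
  expect_error(load_lineages(f3), "genus")
})

test_that("ranked-lineage dump converter joins accessions to lineages", {
  dir <- withr::local_tempdir()
  dmp <- c(
    "4959\t|\tDebaryomyces hansenii\t|\t\t|\tDebaryomyces\t|\tDebaryomycetaceae\t|\tSaccharomycetales\t|\tSaccharomycetes\t|\tAscomycota\t|\tFungi\t|\tEukaryota\t|",
    "5270\t|\tUstilago maydis\t|\t\t|\tUstilago\t|\tUstilaginaceae\t|\tUstilaginales\t|\tUstilaginomycetes\t|\tBasidiomycota\t|\tFungi\t|\tEukaryota\t|")
  f <- file.path(dir, "rankedlineage.dmp")
  writeLines(dmp, f)
  asm <- data.frame(accession = c("GCA_10", "GCA_11"), taxid = c(5270, 4959))
  got <- convert_rankedlineage(f, asm)
  expect_equal(got$species, c("Ustilago maydis", "Debaryomyces hansenii"))
  expect_equal(got$phylum, c("Basidiomycota", "Ascomycota"))
  expect_error(convert_rankedlineage(f, data.frame(accession = "X", taxid = 1)),
               "X")
})

test_that("species size filter drops small species and caps large ones", {
  df <- do.call(rbind, c(
    lapply(1:2, function(i) lineage_row(paste0("A", i), "Aa bb")),      # too few
    lapply(1:3, function(i) lineage_row(paste0("B", i), "Bb cc")),      # boundary
    lapply(1:15, function(i) lineage_row(paste0("C", i), "Cc dd"))))    # capped
  got <- filter_min_max_per_species(df, min_n = 3, max_n = 10, seed = 5)
  expect_equal(sum(got$species == "Aa bb"), 0L)
  expect_equal(sum(got$species == "Bb cc"), 3L)
  expect_equal(sum(got$species == "Cc dd"), 10L)
  # reproducible under the seed, idempotent on reapplication
  again <- filter_min_max_per_species(df, min_n = 3, max_n = 10, seed = 5)
  expect_identical(got, again)
  expect_identical(filter_min_max_per_species(got, 3, 10, seed = 99), got)
})

test_that("curation flags hybrids, strain names and listed outliers with audit", {
  df <- rbind(
    lineage_row("G1", "Saccharomyces cerevisiae x Saccharomyces kudriavzevii",
                "Saccharomyces"),
    lineage_row("G2", "Neurospora sp. CHS2018a", "Neurospora"),
    lineage_row("G3", "Coccidioides immitis", "Coccidioides"),
    lineage_row("G4", "Hortaea werneckii", "Hortaea"),
    lineage_row("G5", "Aspergillus niger", "Aspergillus"))
  got <- curate(df)
  expect_equal(got$records$accession, "G5")
  expect_equal(got$audit$reason[match(c("G1", "G2", "G3", "G4"),
                                      got$audit$accession)],
               c("hybrid", "strain_named", "outlier_genus", "outlier_species"))
  # switches off: hybrids and strain names retained
  kept <- curate(df, drop_hybrids = FALSE, drop_strain_named = FALSE)
  expect_true(all(c("G1", "G2") %in% kept$records$accession))
  # curation is idempotent
  expect_identical(curate(got$records)$records, got$records)
  # plain species epithets are never mistaken for strain codes
  ok <- curate(lineage_row("G6", "Fusarium sp2x unusual", "Fusarium"))
  expect_equal(nrow(ok$audit), 0L)
})

test_that("stratum sizes match closed-form combinatorics", {
  # one species, 4 genomes: C(4,2) pairs
  df <- do.call(rbind, lapply(1:4, function(i) lineage_row(paste0("S", i), "Aa bb")))
  expect_equal(nrow(enumerate_rank_pairs(df, "species")), 6L)
  # one genus, species of sizes 3 and 2: genus 3*2, species 3+1
  df2 <- rbind(do.call(rbind, lapply(1:3, function(i) lineage_row(paste0("X", i), "Gg s1", "Gg"))),
               do.call(rbind, lapply(1:2, function(i) lineage_row(paste0("Y", i), "Gg s2", "Gg"))))
  expect_equal(nrow(enumerate_rank_pairs(df2, "genus")), 6L)
  expect_equal(nrow(enumerate_rank_pairs(df2, "species")), 4L)
  # family with G1={sp(3)}, G2={sp(2),sp(2)}: family 3*4, genus 2*2
  df3 <- rbind(
    do.call(rbind, lapply(1:3, function(i) lineage_row(paste0("P", i), "G1 s1", "G1"))),
    do.call(rbind, lapply(1:2, function(i) lineage_row(paste0("Q", i), "G2 s1", "G2"))),
    do.call(rbind, lapply(1:2, function(i) lineage_row(paste0("R", i), "G2 s2", "G2"))))
  expect_equal(nrow(enumerate_rank_pairs(df3, "family")), 12L)
  expect_equal(nrow(enumerate_rank_pairs(df3, "genus")), 4L)
  expect_error(enumerate_rank_pairs(df3, "kingdom"), "unknown")
})

test_that("strata partition all complete-lineage pairs and match the oracle", {
  reg <- generate_registry(clade_config(genome_length = 60, n_phyla = 2,
                                        n_classes = 2, n_orders = 2,
                                        n_families = 1, n_genera = 2,
                                        n_species = 3, genomes_per_species = 2,
                                        seed = 3))
  reg$records <- reg$records[1:48, ] # three phyla-level subtrees suffice
  rec <- reg$records
  expect_lte(nrow(rec), 50L)
  strata <- enumerate_all_strata(rec)
  # no pair appears twice across strata
  key <- paste(strata$accession_a, strata$accession_b)
  expect_false(any(duplicated(key)))
  oracle <- naive_strata(rec)
  ok <- oracle[!is.na(oracle$level), ]
  expect_equal(nrow(strata), nrow(ok))
  m <- merge(strata[c("accession_a", "accession_b", "level")], ok,
             by = c("accession_a", "accession_b"))
  expect_equal(nrow(m), nrow(ok))
  expect_true(all(m$level.x == m$level.y))
  # partition: stratified pairs + cross-phylum pairs = C(n,2)
  expect_equal(nrow(strata) + sum(is.na(oracle$level)), choose(nrow(rec), 2))
})

test_that("records with a missing rank are skipped only where undecidable", {
  df <- rbind(lineage_row("M1", "Aa bb", "Aa", fa = NA),
              lineage_row("M2", "Aa cc", "Aa", fa = NA),
              lineage_row("M3", "Dd ee", "Dd"))
  # genus decidable without family
  expect_equal(nrow(enumerate_rank_pairs(df, "genus")), 1L)
  # family stratum needs the family taxon: M1/M2 are skipped there
  expect_equal(nrow(enumerate_rank_pairs(df, "family")), 0L)
})
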