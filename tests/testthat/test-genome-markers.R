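# Parsing annotated genome records and extracting marker gene copies by
# keyword matching.

make_fixture_record <- function(taxon = "1234") {
  set.seed(101)
  seq <- make_seq(900)
  feats <- list(
    list(type = "rRNA", start = 101, end = 160,
         product = "16S ribosomal RNA"),
    list(type = "rRNA", start = 301, end = 360,
         product = "16S ribosomal RNA"),
    list(type = "CDS", start = 401, end = 460, strand = "-",
         product = "60 kDa chaperonin", gene = "groEL"),
    list(type = "CDS", start = 601, end = 660,
         product = "hypothetical protein")
  )
  list(text = gb_text(seq, feats, taxon = taxon), seq = seq)
}

test_that("GenBank parsing captures features, strands and the taxon", {
  fx <- make_fixture_record()
  rec <- read_genbank(text = fx$text)[[1]]
  expect_s3_class(rec, "genome_record")
  expect_identical(rec$genome_id, "TESTG1")
  expect_identical(rec$taxon_id, "1234")
  expect_identical(rec$sequence, fx$seq)
  expect_equal(nrow(rec$features), 4)
  expect_equal(sum(rec$features$type == "rRNA"), 2)
  cds <- rec$features[rec$features$product %in% "60 kDa chaperonin", ]
  expect_identical(cds$strand, "-")
  # duplicate rRNA features are both retained
  expect_equal(sum(rec$features$product %in% "16S ribosomal RNA"), 2)
})

test_that("missing taxon warns, malformed locations error with the line", {
  fx <- make_fixture_record(taxon = NA)
  expect_warning(read_genbank(text = fx$text), "taxon")

  bad <- sub("101\\.\\.160", "101..xyz", make_fixture_record()$text)
  expect_error(read_genbank(text = bad), "line")
  out_of_range <- sub("601\\.\\.660", "601..5000", make_fixture_record()$text)
  expect_error(read_genbank(text = out_of_range), "outside")
})

test_that("marker extraction keeps paralogs, strands and keyword rules", {
  set.seed(102)
  seq <- make_seq(1200)
  feats <- list(
    list(type = "rRNA", start = 51, end = 110, product = "16S ribosomal RNA"),
    list(type = "rRNA", start = 301, end = 360, product = "16S ribosomal RNA"),
    list(type = "rRNA", start = 501, end = 560, product = "16S ribosomal RNA"),
    list(type = "CDS", start = 701, end = 760, product = "groEL chaperonin"),
    list(type = "CDS", start = 901, end = 960, product = "groES"),
    list(type = "CDS", start = 1001, end = 1060, strand = "-",
         product = "60 kDa chaperonin")
  )
  rec <- read_genbank(text = gb_text(seq, feats))[[1]]
  tax <- tibble::tibble(taxon_id = "1234", species = "Test species",
                        lineage = "Bacteria;Test")

  r16 <- extract_markers(rec, "16S", taxonomy = tax)
  expect_equal(nrow(r16), 3)
  expect_equal(r16$copy_index, 1:3)
  expect_true(all(r16$species == "Test species"))

  cpn <- extract_markers(rec, "cpn60", taxonomy = tax)
  # "groEL chaperonin" matches, "groES" does not (whole-token rule)
  expect_equal(nrow(cpn), 2)
  expect_false(any(grepl("groES", cpn$sequence)))
  # minus-strand feature is reported reverse-complemented
  minus <- cpn[cpn$copy_index == 2, ]
  expect_identical(minus$sequence, revcomp(substr(seq, 1001, 1060)))

  # unknown taxon falls back to "unknown"
  unk <- extract_markers(rec, "16S",
                         taxonomy = tax[tax$taxon_id == "none", ])
  expect_true(all(unk$species == "unknown"))

  # extraction is idempotent
  expect_identical(extract_markers(rec, "cpn60", taxonomy = tax), cpn)
  # no matching features is an empty table, not an error
  none <- extract_markers(rec, "cpn60", keywords = "nonexistent_kw")
  expect_equal(nrow(none), 0)
})

test_that("generated genome fixtures round-trip through the flat format", {
  fx <- generate_genome_fixture(n_species = 2, genomes_per_species = 2,
                                paralogs = 2, marker_length = 120,
                                flank = 40, seed = 7)
  reparsed <- read_genbank(text = fx$genbank)
  expect_length(reparsed, 4)
  m1 <- extract_markers(fx$records, "cpn60", taxonomy = fx$taxonomy)
  m2 <- extract_markers(reparsed, "cpn60", taxonomy = fx$taxonomy)
  expect_equal(m1, m2)
  expect_true(all(m1$copy_index %in% 1:2))
  expect_equal(nrow(m1), 8)
  expect_false(any(m1$species == "unknown"))
})
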