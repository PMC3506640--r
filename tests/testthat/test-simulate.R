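# Synthetic template panels, amplicon read sets and genome fixtures.

test_that("panels are deterministic, bounded and length-constrained", {
  p1 <- generate_panel(n = 8, seed = 5)
  p2 <- generate_panel(n = 8, seed = 5)
  expect_identical(p1$templates, p2$templates)
  expect_true(all(p1$templates$length >= 552 & p1$templates$length <= 558))

  ids <- panel_identities(p1)
  expect_equal(nrow(ids), choose(8, 2))
  # bounds hold up to the one-position quantisation of identity
  tol <- 1 / min(p1$templates$length)
  expect_true(all(ids$identity >= p1$lo - tol &
                    ids$identity <= p1$hi + tol))
})

test_that("a two-template panel hits an exact identity target", {
  p <- generate_panel(n = 2, lo = 0.9, hi = 0.9, length = 555, seed = 3,
                      divergence = c(0.05, 0.05), indel = FALSE)
  id <- panel_identities(p)$identity
  expect_equal(id, 0.9, tolerance = 1.5 / 555)
})

test_that("bounds that the adjustment budget cannot satisfy error out", {
  # a narrow high-identity envelope far from the drawn divergences
  # cannot be satisfied within one adjustment
  expect_error(
    generate_panel(n = 12, lo = 0.93, hi = 0.94, length = 555, seed = 1,
                   divergence = c(0.2, 0.3), indel = FALSE, max_tries = 1),
    "bounds"
  )
})

test_that("mutate_to_identity lands on the requested identity", {
  set.seed(501)
  parent <- make_seq(555)
  child <- mutate_to_identity(parent, 0.96, seed = 9)
  mism <- sum(strsplit(parent, "")[[1]] != strsplit(child, "")[[1]])
  expect_equal(mism, round(0.04 * 555))
})

test_that("error-free reads are exact amplicon substrings from both ends
           with complete truth labels", {
  panel <- generate_panel(n = 4, seed = 13)
  rs <- simulate_reads(panel, reads_per_template = 10,
                       median_length = 300, seed = 2)
  expect_equal(nrow(rs$reads), 40)
  expect_setequal(unique(rs$reads$direction), c("5p", "3p"))
  expect_true(all(rs$truth$template_id %in% panel$templates$template_id))
  amps <- panel_amplicons(panel)
  for (i in seq_len(nrow(rs$reads))) {
    amp <- amps[[rs$reads$template_id[i]]]
    s <- rs$reads$sequence[i]
    hit <- grepl(s, amp, fixed = TRUE) | grepl(revcomp(s), amp, fixed = TRUE)
    expect_true(hit)
  }
  # determinism
  rs2 <- simulate_reads(panel, reads_per_template = 10,
                        median_length = 300, seed = 2)
  expect_identical(rs$reads, rs2$reads)
})

test_that("read lengths reach the requested median and the error knobs
           take effect", {
  panel <- generate_panel(n = 20, seed = 42)
  rs <- simulate_reads(panel, reads_per_template = 172,
                       median_length = 394, seed = 4)
  expect_equal(nrow(rs$reads), 3440)
  expect_lt(abs(median(rs$reads$length) - 394), 5)
  expect_true(all(rs$reads$length >= 80))

  # substitution errors lower read-to-template identity by about the rate
  rs_err <- simulate_reads(panel, reads_per_template = 3,
                           median_length = 394, error_rate = 0.02,
                           seed = 5)
  ids <- vapply(seq_len(20), function(i) {
    r <- rs_err$reads[rs_err$reads$template_id ==
                        panel$templates$template_id[i], ][1, ]
    best_overlap(r$sequence,
                 panel$templates$amplicon[i])$identity
  }, numeric(1))
  expect_lt(mean(ids), 99.5)
  expect_gt(mean(ids), 96)

  # homopolymer jitter produces +-1 run lengths
  tpl <- tibble::tibble(
    template_id = "H1",
    sequence = paste0(make_seq(200, seed = 6), "AAAA", make_seq(200)),
    length = 404L
  )
  tpl$amplicon <- tpl$sequence
  hp <- structure(list(templates = tpl, lo = 0.5, hi = 1, seed = 1,
                       primer_pair = get_primer_pair("UT")),
                  class = "template_panel")
  rs_hp <- simulate_reads(hp, reads_per_template = 200,
                          median_length = 350, homopolymer_bias = 0.5,
                          seed = 7)
  runs <- regmatches(rs_hp$reads$sequence,
                     regexpr("A{3,}", rs_hp$reads$sequence))
  expect_true(any(nchar(runs) != 4))
})

test_that("genome fixtures respect the designed divergences", {
  fx <- generate_genome_fixture(n_species = 3, genomes_per_species = 2,
                                intra = 0.01, inter = 0.3,
                                marker_length = 300, flank = 50, seed = 21)
  mk <- extract_markers(fx$records, "cpn60", taxonomy = fx$taxonomy)
  expect_equal(nrow(mk), 6)
  rec <- partition_distances(mk)
  expect_lt(median(rec$distance[rec$relation == "intra"]), 0.05)
  expect_gt(median(rec$distance[rec$relation == "inter"]), 0.2)

  # paralogs produce a divergent intra-specific right tail
  fx2 <- generate_genome_fixture(n_species = 2, genomes_per_species = 1,
                                 paralogs = 2, paralog_divergence = 0.4,
                                 intra = 0.01, inter = 0.3,
                                 marker_length = 300, flank = 50, seed = 22)
  mk2 <- extract_markers(fx2$records, "cpn60", taxonomy = fx2$taxonomy)
  rec2 <- partition_distances(mk2)
  intra2 <- rec2$distance[rec2$relation == "intra"]
  expect_gt(max(intra2), 0.25)

  expect_error(generate_genome_fixture(intra = 0.3, inter = 0.2))
  fx3 <- generate_genome_fixture(n_species = 3, genomes_per_species = 2,
                                 intra = 0.01, inter = 0.3,
                                 marker_length = 300, flank = 50, seed = 21)
  expect_identical(fx$genbank, fx3$genbank)
})
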