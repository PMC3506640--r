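# Reference matching, confusion counts, the accuracy metrics and the
# post-assembly cleanup operations.

test_that("best reference matching ranks by identity with deterministic
           ties and an identity floor", {
  set.seed(701)
  refs <- setNames(replicate(3, make_seq(400)), c("R1", "R2", "R3"))
  m <- best_reference_match(c(q = refs[["R3"]]), refs)
  expect_identical(m$ref_id, "R3")
  expect_equal(m$identity, 100)

  q2 <- sub_k(refs[["R1"]], 20, seed = 2)  # 95% to R1
  m2 <- best_reference_match(c(q = q2), refs)
  expect_identical(m2$ref_id, "R1")
  expect_equal(m2$identity, 95, tolerance = 0.01)

  scrambled <- paste(sample(strsplit(refs[["R1"]], "")[[1]]), collapse = "")
  m3 <- best_reference_match(c(q = scrambled), refs)
  expect_true(is.na(m3$ref_id))

  # exact ties resolve to the lexicographically smallest reference id
  dup <- c(B = refs[["R1"]], A = refs[["R1"]])
  m4 <- best_reference_match(c(q = refs[["R1"]]), dup)
  expect_identical(m4$ref_id, "A")

  expect_error(best_reference_match(c(q = ""), refs), "empty")
  # banded and full modes agree on well-matched queries
  m5 <- best_reference_match(c(q = q2), refs, band = 24)
  expect_identical(m5$ref_id, "R1")
  expect_equal(m5$identity, m2$identity)
})

test_that("confusion counts follow the TP/FP/TN/FN definitions", {
  membership <- tibble::tibble(
    read_id = sprintf("r%02d", 1:20),
    otu_id = rep(c("OTU_001", "OTU_002"), each = 10)
  )
  otu_refs <- tibble::tibble(otu_id = c("OTU_001", "OTU_002"),
                             ref_id = c("A", "B"))
  read_refs <- tibble::tibble(read_id = membership$read_id,
                              ref_id = rep(c("A", "B"), each = 10))
  for (otu in otu_refs$otu_id) {
    cc <- confusion_counts(otu, membership, otu_refs, read_refs)
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(10, 0, 10, 0))
  }

  # one template-B read mis-assembled into OTU_001
  read_refs2 <- read_refs
  read_refs2$ref_id[5] <- "B"
  c1 <- confusion_counts("OTU_001", membership, otu_refs, read_refs2)
  expect_equal(c(c1$tp, c1$fp, c1$tn, c1$fn), c(9, 1, 10, 0))
  c2 <- confusion_counts("OTU_002", membership, otu_refs, read_refs2)
  expect_equal(c(c2$tp, c2$fp, c2$tn, c2$fn), c(10, 0, 9, 1))

  expect_error(confusion_counts("OTU_009", membership, otu_refs,
                                read_refs), "not part")
})

test_that("confusion counts equal the brute-force oracle on random
           labelled fixtures", {
  set.seed(702)
  for (i in 1:30) {
    fx <- random_label_fixture(sample(2:5, 1), sample(20:60, 1))
    for (otu in fx$otu_refs$otu_id) {
      cc <- confusion_counts(otu, fx$membership, fx$otu_refs, fx$read_refs)
      oc <- oracle_confusion(otu, fx$membership, fx$otu_refs, fx$read_refs)
      expect_equal(c(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn), oc)
    }
  }
})

test_that("residual error follows the distance-to-(1,1) form and total
           error is additive", {
  expect_equal(residual_error(1, 1), 0)
  expect_equal(residual_error(0.8, 0.9), sqrt(0.05), tolerance = 1e-12)
  expect_equal(residual_error(0.8, 0.9), 0.22360680, tolerance = 1e-7)
  expect_equal(residual_error(0, 0), sqrt(2))

  panel <- generate_panel(n = 3, seed = 41)
  rs <- simulate_reads(panel, reads_per_template = 10,
                       median_length = 350, seed = 9)
  asm <- assemble(rs, ml = 100, mi = 92)
  ev <- evaluate_assembly(asm, rs, panel)
  expect_equal(ev$summary$total_error, sum(ev$per_otu$residual_error),
               tolerance = 1e-12)
  # a perfect assembly of an error-free panel carries zero total error
  expect_equal(ev$summary$total_error, 0)
  expect_true(all(ev$per_otu$specificity >= 0 & ev$per_otu$specificity <= 1))
  expect_true(all(ev$per_otu$residual_error <= sqrt(2) + 1e-12))
})

test_that("primer trimming removes terminal footprints only", {
  pp <- get_primer_pair("UT")
  set.seed(703)
  ut <- make_seq(300)
  # concretise degenerate positions to a compatible base
  fwd <- chartr("IRYKSWM", "AACGCAA", pp$forward)
  rev_fp <- revcomp(chartr("IRYKSWM", "AACGCAA", pp$reverse))
  full <- paste0(fwd, ut, rev_fp)
  expect_identical(trim_primers(full, pp), ut)
  expect_identical(trim_primers(ut, pp), ut)
  only5 <- paste0(fwd, ut)
  expect_identical(trim_primers(only5, pp), ut)
  # an interior footprint is left untouched
  interior <- paste0(make_seq(50), fwd, make_seq(50))
  expect_identical(trim_primers(interior, pp), interior)
})

test_that("identical or contained consensus sequences collapse into the
           longer OTU", {
  set.seed(704)
  tpl <- make_seq(500)
  mk_asm <- function(consensus, members) {
    n <- vapply(members, length, integer(1))
    structure(list(
      otus = tibble::tibble(
        otu_id = names(consensus), n_members = n,
        length = nchar(consensus), consensus = unname(consensus),
        coverage = lapply(nchar(consensus), function(l) rep(1L, l))
      ),
      membership = tibble::tibble(
        read_id = unlist(members),
        otu_id = rep(names(members), n)
      ),
      params = list(ml = 100, mi = 92),
      n_reads = sum(n)
    ), class = "otu_assembly")
  }
  dup <- mk_asm(
    c(OTU_001 = tpl, OTU_002 = tpl),
    list(OTU_001 = c("r1", "r2"), OTU_002 = c("r3", "r4"))
  )
  col <- collapse_identical(dup)
  expect_equal(nrow(col$otus), 1)
  expect_setequal(col$membership$otu_id, col$otus$otu_id)
  expect_equal(col$otus$n_members, 4L)

  substr_case <- mk_asm(
    c(OTU_001 = substr(tpl, 50, 400), OTU_002 = tpl),
    list(OTU_001 = c("r1", "r2"), OTU_002 = c("r3", "r4"))
  )
  col2 <- collapse_identical(substr_case)
  expect_identical(col2$otus$otu_id, "OTU_002")
  expect_identical(col2$otus$consensus, tpl)

  disjoint <- mk_asm(
    c(OTU_001 = make_seq(300), OTU_002 = make_seq(300)),
    list(OTU_001 = c("r1", "r2"), OTU_002 = c("r3", "r4"))
  )
  expect_equal(nrow(collapse_identical(disjoint)$otus), 2)
})

test_that("chimeras are flagged when the two ends match different
           references", {
  panel <- generate_panel(n = 4, seed = 51)
  refs <- setNames(panel$templates$sequence, panel$templates$template_id)
  clean <- flag_chimera(c(x = refs[[1]]), refs)
  expect_false(clean$is_chimera)
  expect_true(clean$evaluable)

  chim <- paste0(substr(refs[[1]], 1, 270),
                 substr(refs[[2]], 271, nchar(refs[[2]])))
  fc <- flag_chimera(c(x = chim), refs)
  expect_true(fc$is_chimera)
  expect_false(identical(fc$ref_5p, fc$ref_3p))

  short <- flag_chimera(c(x = substr(chim, 1, 250)), refs)
  expect_false(short$is_chimera)
  expect_false(short$evaluable)
})

test_that("staged cleanup never increases total error on simulated
           communities", {
  panel <- generate_panel(n = 6, seed = 61)
  rs <- simulate_reads(panel, reads_per_template = 14,
                       median_length = 360, seed = 10)
  asm <- assemble(rs, ml = 100, mi = 92)
  st <- evaluate_stages(asm, rs, panel)
  err <- st$summary$total_error
  expect_true(err[2] <= err[1] + 1e-12)
  expect_true(err[3] <= err[2] + 1e-12)
  expect_identical(st$summary$stage,
                   c("raw", "trimmed_clustered", "chimera_removed"))
  # trimming strips the primer flanks, so every cleaned consensus is an
  # exact (possibly partial) copy of some template, in either orientation
  hits <- vapply(st$assembly$otus$consensus, function(s) {
    any(grepl(s, panel$templates$sequence, fixed = TRUE)) ||
      any(grepl(revcomp(s), panel$templates$sequence, fixed = TRUE))
  }, logical(1))
  expect_true(all(hits))
})

test_that("the sweep driver tabulates every stage for every setting", {
  panel <- generate_panel(n = 3, seed = 71)
  rs <- simulate_reads(panel, reads_per_template = 8,
                       median_length = 330, seed = 11)
  sw <- sweep_assembly(rs, panel, ml = c(100, 320), mi = c(92, 97))
  expect_s3_class(sw, "assembly_sweep")
  expect_equal(nrow(sw), 2 * 2 * 3)
  expect_true(all(c("total_error", "n_otus", "pct_singletons") %in%
                    names(sw)))
  wide <- tidyr::pivot_wider(sw[, c("ml", "mi", "stage", "total_error")],
                             names_from = "stage",
                             values_from = "total_error")
  expect_true(all(wide$trimmed_clustered <= wide$raw + 1e-12))
  expect_true(all(wide$chimera_removed <= wide$trimmed_clustered + 1e-12))
})
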