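# The greedy overlap-consensus assembler and its overlap primitive.

test_that("best overlaps: identity, orientation, hand-counted mismatches", {
  set.seed(601)
  a <- make_seq(400)
  r <- best_overlap(a, a)
  expect_equal(r$length, 400)
  expect_equal(r$identity, 100)
  expect_identical(r$orientation, "forward")

  rrc <- best_overlap(a, revcomp(a))
  expect_equal(rrc$length, 400)
  expect_equal(rrc$identity, 100)
  expect_identical(rrc$orientation, "reverse")

  # 150 bp shared region carrying 3 mismatches -> overlap 150, 98.0%
  shared <- make_seq(150)
  shared_mut <- sub_k(shared, 3, seed = 2)
  x <- paste0(make_seq(250), shared)
  y <- paste0(shared_mut, make_seq(250))
  o <- best_overlap(x, y)
  expect_equal(o$length, 150)
  expect_equal(o$identity, 98.0)
})

test_that("tiled error-free reads assemble into one OTU reproducing the
           template", {
  set.seed(602)
  template <- make_seq(600)
  reads <- tile_reads(template, 10, 250)
  asm <- assemble(reads, ml = 100, mi = 92)
  expect_equal(nrow(asm$otus), 1)
  expect_equal(sum(asm$membership$otu_id == "singleton"), 0)
  expect_identical(asm$otus$consensus, template)
})

test_that("templates below the identity threshold stay separate, above
           it they merge", {
  set.seed(603)
  t1 <- make_seq(400)
  t2 <- mutate_to_identity(t1, 0.80, seed = 3)
  reads <- c(tile_reads(t1, 6, 220, "a"), tile_reads(t2, 6, 220, "b"))
  asm <- assemble(reads, ml = 100, mi = 92)
  expect_equal(nrow(asm$otus), 2)
  members <- split(asm$membership$read_id, asm$membership$otu_id)
  purity <- vapply(members, function(m) {
    length(unique(substr(m, 1, 1)))
  }, integer(1))
  expect_true(all(purity == 1))

  # a 96%-identical pair is separated when mi sits between its identity
  # and 100...
  t3 <- mutate_to_identity(t1, 0.96, seed = 4)
  reads96 <- c(tile_reads(t1, 8, 220, "a"), tile_reads(t3, 8, 220, "b"))
  asm97 <- assemble(reads96, ml = 100, mi = 97)
  expect_equal(nrow(asm97$otus), 2)
  expect_true(all(asm97$otus$consensus %in% c(t1, t3)))
  # ...and merges when mi falls below it
  asm92 <- assemble(reads96, ml = 100, mi = 92)
  expect_equal(nrow(asm92$otus), 1)
})

test_that("ml beyond every read length leaves only singletons", {
  set.seed(604)
  reads <- tile_reads(make_seq(500), 8, 200)
  asm <- assemble(reads, ml = 250, mi = 92)
  expect_equal(nrow(asm$otus), 0)
  expect_true(all(asm$membership$otu_id == "singleton"))
})

test_that("every read lands exactly once (partition property) and runs
           are deterministic", {
  for (seed in 1:5) {
    set.seed(seed)
    tpls <- replicate(3, make_seq(450))
    reads <- unlist(lapply(seq_along(tpls), function(i) {
      tile_reads(tpls[i], sample(4:8, 1), sample(c(150, 200, 250), 1),
                 prefix = paste0("t", i, "_"))
    }))
    asm <- assemble(reads, ml = 120, mi = 94)
    expect_setequal(asm$membership$read_id, names(reads))
    expect_equal(anyDuplicated(asm$membership$read_id), 0)
    expect_equal(
      sum(asm$otus$n_members) + sum(asm$membership$otu_id == "singleton"),
      length(reads)
    )
    asm2 <- assemble(reads, ml = 120, mi = 94)
    expect_identical(asm$otus, asm2$otus)
    expect_identical(asm$membership, asm2$membership)
  }
})

test_that("singleton counts never decrease as ml or mi rises", {
  set.seed(605)
  t1 <- make_seq(500)
  t2 <- mutate_to_identity(t1, 0.9, seed = 6)
  reads <- c(tile_reads(t1, 8, 260, "a"), tile_reads(t2, 8, 260, "b"))
  singles <- function(asm) sum(asm$membership$otu_id == "singleton")

  by_ml <- vapply(c(50, 120, 200, 300),
                  function(ml) singles(assemble(reads, ml = ml, mi = 92)),
                  numeric(1))
  expect_true(all(diff(by_ml) >= 0))

  by_mi <- vapply(c(80, 90, 96, 99.5),
                  function(mi) singles(assemble(reads, ml = 120, mi = mi)),
                  numeric(1))
  expect_true(all(diff(by_mi) >= 0))
})

test_that("the prescreened path agrees with the exhaustive assembler on
           mid-sized inputs", {
  panel <- generate_panel(n = 4, seed = 31)
  rs <- simulate_reads(panel, reads_per_template = 12,
                       median_length = 320, seed = 8)
  a_ex <- assemble(rs, ml = 100, mi = 92, exhaustive = TRUE)
  a_ks <- assemble(rs, ml = 100, mi = 92, exhaustive = FALSE)
  expect_equal(nrow(a_ex$otus), nrow(a_ks$otus))
  expect_setequal(a_ex$otus$consensus, a_ks$otus$consensus)
  expect_identical(
    dplyr::arrange(a_ex$membership, .data$read_id),
    dplyr::arrange(a_ks$membership, .data$read_id)
  )
})

test_that("tidy and glance summarise an assembly", {
  set.seed(606)
  reads <- tile_reads(make_seq(400), 6, 200)
  asm <- assemble(reads, ml = 100, mi = 92)
  expect_identical(tidy(asm), asm$membership)
  g <- glance(asm)
  expect_equal(g$n_reads, 6)
  expect_equal(g$pct_singletons, 100 * g$n_singletons / g$n_reads)
})
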