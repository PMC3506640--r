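# Closed-form distances, the intra/inter partition, the barcode-gap
# statistic and distance histograms.

test_that("identical sequences give zero distance under every model", {
  set.seed(301)
  s <- make_seq(300)
  for (m in c("f84", "k2p", "jc")) {
    expect_equal(pairwise_distance(s, s, model = m), 0)
  }
})

test_that("Jukes-Cantor matches its closed form on a hand-counted pair", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))  # 10 transitions / 100
  expect_equal(pairwise_distance(a, b, model = "jc"),
               -0.75 * log(1 - 4 / 3 * 0.1), tolerance = 1e-12)
  expect_equal(pairwise_distance(a, b, model = "jc"), 0.1073256,
               tolerance = 1e-6)
})

test_that("F84 collapses to K2P when base frequencies are equal", {
  # balanced composition preserved by compensating substitutions
  a <- strrep("ACGT", 30)
  bch <- strsplit(a, "")[[1]]
  bch[1] <- "G"; bch[7] <- "A"    # two transitions, pooled counts even
  bch[14] <- "A"; bch[17] <- "C"  # two transversions, compensated
  b <- paste(bch, collapse = "")
  expect_equal(pairwise_distance(a, b, "f84"),
               pairwise_distance(a, b, "k2p"), tolerance = 1e-9)
})

test_that("F84 agrees with the reference distance implementation", {
  skip_if_not_installed("ape")
  set.seed(302)
  for (i in 1:25) {
    a <- make_seq(300)
    b <- sub_k(a, sample(5:150, 1))
    mine <- pairwise_distance(a, b, "f84")
    mat <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    theirs <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "F84",
                                       pairwise.deletion = TRUE))
    expect_equal(mine, theirs, tolerance = 1e-6)
  }
})

test_that("sites with gaps or ambiguity are excluded pairwise", {
  a <- "ACGTACGTAC"
  b <- "ACGT-CGTNC"
  # comparable sites: 8; all identical
  expect_equal(pairwise_distance(a, b), 0)
  expect_error(pairwise_distance("----", "ACGT"), "no comparable sites")
})

test_that("saturated pairs return infinity", {
  a <- strrep("AC", 50)
  b <- strrep("CA", 50)
  for (m in c("f84", "k2p", "jc")) {
    expect_identical(pairwise_distance(a, b, model = m), Inf)
  }
})

test_that("partitioning enumerates all unordered pairs with relations", {
  set.seed(303)
  base <- make_seq(120)
  mk <- tibble::tibble(
    id = c("x1", "x2", "y1"),
    species = c("X", "X", "Y"),
    aligned = c(base, sub_k(base, 2), sub_k(base, 40))
  )
  rec <- partition_distances(mk)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$relation == "intra"), 1)
  expect_equal(sum(rec$relation == "inter"), 2)

  # n sequences -> n(n-1)/2 records
  n <- 8
  mk2 <- tibble::tibble(
    id = paste0("s", 1:n), species = rep(c("A", "B"), each = 4),
    aligned = replicate(n, sub_k(base, sample(0:30, 1)))
  )
  expect_equal(nrow(partition_distances(mk2)), n * (n - 1) / 2)
  expect_error(partition_distances(mk2[1, ]), "at least 2")

  # divergent paralogs within one genome are a large intra distance
  mk3 <- tibble::tibble(
    id = c("g1|cpn60|1", "g1|cpn60|2"),
    species = c("Z", "Z"),
    aligned = c(base, sub_k(base, 45))
  )
  rec3 <- partition_distances(mk3)
  expect_identical(rec3$relation, "intra")
  expect_gt(rec3$distance, 0.3)
})

test_that("gap statistic is the median difference, robust to outliers,
           and reports saturation", {
  rec <- tibble::tibble(
    distance = c(0.06, 0.07, 0.08, 0.5, 0.68, 0.9),
    relation = c("intra", "intra", "intra", "inter", "inter", "inter")
  )
  g <- gap_statistic(rec)
  expect_equal(g$barcode_gap, 0.68 - 0.07, tolerance = 1e-12)
  expect_equal(g$n_intra, 3)
  expect_equal(g$n_inter, 3)

  # identical distributions -> zero gap
  sym <- tibble::tibble(distance = rep(c(0.1, 0.2, 0.3), 2),
                        relation = rep(c("intra", "inter"), each = 3))
  expect_equal(gap_statistic(sym)$barcode_gap, 0)

  # a median-based gap ignores extreme right-tail outliers
  spiked <- dplyr::bind_rows(
    rec,
    tibble::tibble(distance = c(5.9, Inf), relation = "intra")
  )
  expect_equal(gap_statistic(spiked)$median_intra, median(c(0.06, 0.07, 0.08, 5.9)))
  expect_equal(gap_statistic(spiked)$n_saturated_intra, 1)
  expect_true(is.finite(gap_statistic(spiked)$max_intra))

  expect_error(
    gap_statistic(rec[rec$relation == "inter", ]),
    "intra"
  )
})

test_that("histograms normalise per relation and the cap is display-only", {
  ten <- tibble::tibble(distance = rep(0.005, 10), relation = "intra")
  h <- distance_histogram(ten)
  expect_equal(h$percent, 100)
  expect_equal(h$bin_lo, 0)

  two <- tibble::tibble(distance = c(0.005, 0.015), relation = "inter")
  h2 <- distance_histogram(two)
  expect_equal(h2$percent, c(50, 50))

  capped <- tibble::tibble(distance = c(0.5, 1.2), relation = "inter")
  h3 <- distance_histogram(capped, cap = 1.0)
  # normalisation unchanged: all bins still sum to 100
  expect_equal(sum(h3$percent), 100)
  # plotted mass under the cap is 50% of the records
  expect_equal(sum(h3$percent[h3$bin_lo < 1.0]), 50)

  set.seed(304)
  big <- tibble::tibble(
    distance = c(runif(200, 0, 1.5), rexp(100, 5)),
    relation = sample(c("intra", "inter"), 300, replace = TRUE)
  )
  hb <- distance_histogram(big)
  sums <- as.numeric(tapply(hb$percent, hb$relation, sum))
  expect_equal(sums, c(100, 100), tolerance = 1e-9)
})

test_that("the distance matrix writer emits a square PHYLIP matrix", {
  set.seed(305)
  base <- make_seq(60)
  mk <- tibble::tibble(
    id = c("a", "b", "c"), species = c("A", "A", "B"),
    aligned = c(base, sub_k(base, 3), sub_k(base, 20))
  )
  d <- distance_matrix(mk)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  path <- tempfile(fileext = ".dist")
  write_phylip_dist(d, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_length(lines, 4)
})
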