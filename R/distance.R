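# Pairwise evolutionary distances on aligned barcode regions, the
# intra-/inter-specific partition, the median-based barcode-gap
# statistic, and distance histograms.
#
# The F84 distance follows the closed form used by PHYLIP's DNADIST:
# with base frequencies estimated from the two sequences being compared
# (pairwise), purine/pyrimidine sums piR/piY, and
#   A = piC*piT/piY + piA*piG/piR,  B = piC*piT + piA*piG,  C = piR*piY,
# the distance is
#   d = -2A * ln(1 - P/(2A) - (A-B)*Q/(2AC)) + 2(A-B-C) * ln(1 - Q/(2C))
# where P and Q are the observed transition and transversion proportions.
# Sites with a gap or ambiguity in either sequence are excluded pairwise.

#' Pairwise evolutionary distance between two aligned sequences
#'
#' Computes substitutions/site under the F84 (default), Kimura
#' two-parameter or Jukes-Cantor model from two equal-length gapped
#' sequences. Sites where either sequence has a non-ACGT symbol are
#' excluded (pairwise deletion); base frequencies for F84 are empirical
#' frequencies of the compared pair. A saturated pair (logarithm argument
#' <= 0) yields `Inf`, which downstream summaries exclude from medians
#' but count.
#'
#' @param a,b Aligned sequences of equal length (single strings).
#' @param model `"f84"`, `"k2p"` or `"jc"` (case-insensitive).
#' @return Distance in substitutions/site (scalar; may be `Inf`).
#' @export
#' @examples
#' pairwise_distance("ACGTACGTAC", "ACGTACGTAC")            # 0
#' pairwise_distance("AAAAAAAAAA", "AAAAAGAAAA", model = "jc")
pairwise_distance <- function(a, b, model = c("f84", "k2p", "jc")) {
  model <- match.arg(tolower(model[1]), c("f84", "k2p", "jc"))
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  use <- ca %in% acgt & cb %in% acgt
  n <- sum(use)
  if (n == 0) {
    stop("no comparable sites: every site has a gap or ambiguity",
         call. = FALSE)
  }
  ca <- ca[use]
  cb <- cb[use]
  diff <- ca != cb
  purine <- function(x) x %in% c("A", "G")
  transition <- diff & (purine(ca) == purine(cb))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n

  dist_from_pq(P, Q, model, freqs = table(factor(c(ca, cb), levels = acgt)) /
                 (2 * n))
}

# Shared closed forms. `freqs` is the length-4 ACGT frequency vector
# (only used by F84).
dist_from_pq <- function(P, Q, model, freqs = rep(0.25, 4)) {
  if (model == "jc") {
    arg <- 1 - 4 * (P + Q) / 3
    return(if (arg <= 0) Inf else -0.75 * log(arg))
  }
  if (model == "k2p") {
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    return(if (a1 <= 0 || a2 <= 0) Inf else -0.5 * log(a1) - 0.25 * log(a2))
  }
  # F84
  pA <- freqs[[1]]; pC <- freqs[[2]]; pG <- freqs[[3]]; pT <- freqs[[4]]
  piR <- pA + pG
  piY <- pC + pT
  if (piR <= 0 || piY <= 0) {
    # One base class is absent from the pair; the transversion correction
    # degenerates. With no transversions observed fall back to the
    # transition-only term, otherwise the distance is undefined/saturated.
    if (Q > 0) return(Inf)
    A_ <- if (piR > 0) pA * pG / piR else pC * pT / piY
    if (A_ <= 0) return(if (P > 0) Inf else 0)
    a1 <- 1 - P / (2 * A_)
    return(if (a1 <= 0) Inf else -2 * A_ * log(a1))
  }
  A_ <- pC * pT / piY + pA * pG / piR
  B_ <- pC * pT + pA * pG
  C_ <- piR * piY
  if (A_ <= 0) {
    # no within-class pair of distinct bases exists; transitions are
    # impossible under the model
    if (P > 0) return(Inf)
    a2 <- 1 - Q / (2 * C_)
    return(if (a2 <= 0) Inf else -2 * C_ * log(a2))
  }
  a1 <- 1 - P / (2 * A_) - (A_ - B_) * Q / (2 * A_ * C_)
  a2 <- 1 - Q / (2 * C_)
  if (a1 <= 0 || a2 <= 0) return(Inf)
  -2 * A_ * log(a1) + 2 * (A_ - B_ - C_) * log(a2)
}

# Normalise a marker table for distance work: ensure an `id` column and
# an `aligned` column of equal-length gapped sequences.
prepare_aligned_markers <- function(markers) {
  m <- tibble::as_tibble(markers)
  if (!"id" %in% names(m)) {
    if (all(c("genome_id", "gene", "copy_index") %in% names(m))) {
      m$id <- paste(m$genome_id, m$gene, m$copy_index, sep = "|")
    } else {
      stop("markers need an 'id' column (or genome_id/gene/copy_index)",
           call. = FALSE)
    }
  }
  if (!"aligned" %in% names(m)) {
    if (!"sequence" %in% names(m)) {
      stop("markers need an 'aligned' (or equal-length 'sequence') column",
           call. = FALSE)
    }
    if (length(unique(nchar(m$sequence))) != 1) {
      stop("'sequence' column has unequal lengths; supply an 'aligned' ",
           "column (e.g. from star_align() or an external aligner)",
           call. = FALSE)
    }
    m$aligned <- m$sequence
  }
  if (length(unique(nchar(m$aligned))) != 1) {
    stop("'aligned' sequences must all have equal length", call. = FALSE)
  }
  if (anyDuplicated(m$id)) stop("marker ids must be unique", call. = FALSE)
  m
}

#' All pairwise distances, partitioned intra-/inter-specific
#'
#' Computes the distance for every unordered pair of aligned markers and
#' labels each pair `intra` when the two species labels agree (paralog
#' pairs within one genome are intra-specific) and `inter` otherwise.
#'
#' @param markers Tibble with columns `species`, `aligned` (equal-length
#'   gapped sequences) and `id` (or `genome_id`/`gene`/`copy_index` from
#'   which ids are built). An equal-length `sequence` column may stand in
#'   for `aligned`.
#' @param model Distance model, see [pairwise_distance()].
#' @return A tibble of distance records: `id_a`, `id_b`, `distance`,
#'   `relation` (`"intra"`/`"inter"`).
#' @export
partition_distances <- function(markers, model = "f84") {
  m <- prepare_aligned_markers(markers)
  if (!"species" %in% names(m)) {
    stop("markers need a 'species' column", call. = FALSE)
  }
  n <- nrow(m)
  if (n < 2) stop("need at least 2 markers", call. = FALSE)
  pairs <- utils::combn(n, 2)
  tibble::tibble(
    id_a = m$id[pairs[1, ]],
    id_b = m$id[pairs[2, ]],
    distance = vapply(
      seq_len(ncol(pairs)),
      function(k) {
        pairwise_distance(m$aligned[pairs[1, k]], m$aligned[pairs[2, k]],
                          model = model)
      },
      numeric(1)
    ),
    relation = ifelse(
      m$species[pairs[1, ]] == m$species[pairs[2, ]], "intra", "inter"
    )
  )
}

#' Barcode-gap summary of a distance partition
#'
#' Summarises the intra- and inter-specific distance distributions and
#' computes the barcode gap: the difference between the median
#' inter-specific and median intra-specific distance. Saturated pairs
#' (infinite distances) are excluded from the medians and extrema but
#' counted in `n_saturated_*`.
#'
#' @param records Distance records from [partition_distances()].
#' @param region Optional region label carried into the summary.
#' @param target_length Optional average target length (bp) carried into
#'   the summary, mirroring the usual report layout.
#' @return A one-row tibble: `region`, `target_length`, `n_intra`,
#'   `n_inter`, `n_saturated_intra`, `n_saturated_inter`, `min_intra`,
#'   `max_intra`, `median_intra`, `min_inter`, `max_inter`,
#'   `median_inter`, `barcode_gap`.
#' @export
gap_statistic <- function(records, region = NA_character_,
                          target_length = NA_real_) {
  stopifnot(all(c("distance", "relation") %in% names(records)))
  intra <- records$distance[records$relation == "intra"]
  inter <- records$distance[records$relation == "inter"]
  if (length(intra) == 0) {
    stop("no intra-specific records: cannot compute a barcode gap",
         call. = FALSE)
  }
  if (length(inter) == 0) {
    stop("no inter-specific records: cannot compute a barcode gap",
         call. = FALSE)
  }
  fin_intra <- intra[is.finite(intra)]
  fin_inter <- inter[is.finite(inter)]
  tibble::tibble(
    region = region,
    target_length = target_length,
    n_intra = length(intra),
    n_inter = length(inter),
    n_saturated_intra = sum(!is.finite(intra)),
    n_saturated_inter = sum(!is.finite(inter)),
    min_intra = min(fin_intra),
    max_intra = max(fin_intra),
    median_intra = median(fin_intra),
    min_inter = min(fin_inter),
    max_inter = max(fin_inter),
    median_inter = median(fin_inter),
    barcode_gap = median(fin_inter) - median(fin_intra)
  )
}

#' Distance histogram (percent of comparisons per bin)
#'
#' Bins the intra- and inter-specific distances into left-closed,
#' right-open bins from 0 and expresses each bin as percent of the total
#' comparisons of that relation. A display cap (distances beyond which
#' are not plotted) affects [autoplot()] only, never the normalisation.
#' Saturated (infinite) distances are excluded.
#'
#' @param records Distance records from [partition_distances()].
#' @param bin_width Bin width in substitutions/site.
#' @param cap Optional display cap (e.g. `1.0`).
#' @return A tibble of class `distance_histogram`: `relation`, `bin_lo`,
#'   `bin_hi`, `n`, `percent`. Percents of each relation sum to 100 over
#'   all bins.
#' @export
distance_histogram <- function(records, bin_width = 0.01, cap = NULL) {
  stopifnot(bin_width > 0)
  fin <- records[is.finite(records$distance), , drop = FALSE]
  out <- fin |>
    dplyr::mutate(bin = floor(.data$distance / bin_width)) |>
    dplyr::count(.data$relation, .data$bin) |>
    dplyr::group_by(.data$relation) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      bin_lo = .data$bin * bin_width,
      bin_hi = (.data$bin + 1) * bin_width
    ) |>
    dplyr::select("relation", "bin_lo", "bin_hi", "n", "percent")
  attr(out, "bin_width") <- bin_width
  attr(out, "cap") <- cap
  class(out) <- c("distance_histogram", class(out))
  out
}

#' Full pairwise distance matrix
#'
#' @param markers Marker tibble (see [partition_distances()]).
#' @param model Distance model.
#' @return A symmetric numeric matrix with marker ids as dimnames.
#' @export
distance_matrix <- function(markers, model = "f84") {
  m <- prepare_aligned_markers(markers)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(m$id, m$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <-
          pairwise_distance(m$aligned[i], m$aligned[j], model = model)
      }
    }
  }
  d
}

#' Write a square PHYLIP distance matrix
#'
#' @param d Symmetric matrix from [distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  lines <- c(
    sprintf("%5d", nrow(d)),
    vapply(seq_len(nrow(d)), function(i) {
      paste0(
        formatC(substr(rownames(d)[i], 1, 10), width = -10),
        paste(sprintf("%9.6f", d[i, ]), collapse = " ")
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
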