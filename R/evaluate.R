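# OTU assembly evaluation against a reference template panel:
# best-reference matching, per-OTU confusion counts and the
# sensitivity/specificity/residual-error metrics, post-assembly cleanup
# (primer trimming, 100% clustering, chimera flagging), and the
# (ml, mi) parameter-sweep driver.
#
#' Residual error of an OTU from its specificity and sensitivity
#'
#' Euclidean distance from the point (specificity, sensitivity) to the
#' perfect corner (1, 1); a perfectly assembled OTU has residual error 0
#' and the worst case is sqrt(2).
#'
#' @param specificity,sensitivity Values in `[0, 1]` (vectorised).
#' @return Residual error in `[0, sqrt(2)]`.
#' @export
#' @examples
#' residual_error(0.8, 0.9)
residual_error <- function(specificity, sensitivity) {
  sqrt((1 - specificity)^2 + (1 - sensitivity)^2)
}

# Large read-by-reference matching jobs use the k-mer-seeded banded
# alignment (with per-query full-DP fallback); small jobs stay exact.
auto_band <- function(nq, nr) {
  if (nq * nr > 20000) 24L else NULL
}

# Per OTU with counts TP/FP/TN/FN:
#   Sp = TN / (TN + FP)          specificity
#   Sn = TP / (TP + FN)          sensitivity
#   E  = sqrt((1-Sp)^2 + (1-Sn)^2)  residual error (distance to (1,1))
# and the total error of an assembly is the sum of E over its OTUs.

#' Best reference match by semiglobal percent identity
#'
#' Aligns every query against every reference (both orientations) with a
#' free end-gap alignment and reports the reference with the highest
#' percent identity over the aligned overlap; ties go to the
#' lexicographically smallest reference id. Overlaps covering less than
#' `min_cover` of the shorter sequence are ignored (guards against
#' trivial high-identity dovetails), and matches below `min_identity`
#' are reported as no match.
#'
#' @param queries,references Sequences (named character vector, tibble
#'   with `id`/`sequence`, or DNAStringSet).
#' @param min_identity Identity floor in percent (default 55).
#' @param min_cover Minimum fraction of the shorter sequence the overlap
#'   must span (default 0.5).
#' @param band Optional half-width of a k-mer-seeded alignment band; the
#'   default (`NULL`) performs the exact full dynamic program for every
#'   pair. Banding accelerates large read sets; queries the prescreen
#'   cannot place at all fall back to the full alignment.
#' @return A tibble with one row per query: `query_id`, `ref_id` (`NA`
#'   when nothing qualifies), `identity`, `q_start`, `q_end`,
#'   `orientation`.
#' @export
best_reference_match <- function(queries, references, min_identity = 55,
                                 min_cover = 0.5, band = NULL) {
  q <- as_named_seqs(queries)
  r <- as_named_seqs(references)
  if (length(r) == 0) stop("references must be non-empty", call. = FALSE)
  if (any(nchar(q) == 0)) stop("empty query sequence", call. = FALSE)
  r <- r[order(names(r), method = "radix")]
  hits <- cpp_best_reference(toupper(unname(q)), toupper(unname(r)),
                             min_cover = min_cover,
                             band = if (is.null(band)) -1L else
                               as.integer(band))
  keep <- !is.na(hits$identity) & hits$identity + 1e-9 >= min_identity
  tibble::tibble(
    query_id = names(q),
    ref_id = ifelse(keep, names(r)[hits$ref_index], NA_character_),
    identity = ifelse(keep, hits$identity, NA_real_),
    q_start = ifelse(keep, hits$q_start, NA_integer_),
    q_end = ifelse(keep, hits$q_end, NA_integer_),
    orientation = ifelse(keep, hits$orientation, NA_character_)
  )
}

#' Confusion counts for one OTU
#'
#' Given per-read and per-consensus best-reference labels: true positives
#' are reads in the target OTU whose best reference equals the OTU
#' consensus's best reference; false positives are reads in the target
#' OTU matching a different reference; false negatives are reads in
#' other OTUs that match the target consensus's reference; true
#' negatives are reads in other OTUs that match their own OTU's
#' consensus reference when that reference differs from the target's.
#' Singletons and reads without a reference match are excluded (the
#' latter counted in `n_unmatched`).
#'
#' @param otu Target OTU id.
#' @param membership Tibble `read_id`, `otu_id` (singletons carry
#'   `"singleton"`).
#' @param otu_refs Tibble `otu_id`, `ref_id`: best reference of each OTU
#'   consensus.
#' @param read_refs Tibble `read_id`, `ref_id`: best reference of each
#'   read.
#' @return A one-row tibble: `otu_id`, `ref_id`, `tp`, `fp`, `tn`, `fn`,
#'   `n_unmatched`.
#' @export
confusion_counts <- function(otu, membership, otu_refs, read_refs) {
  if (!otu %in% otu_refs$otu_id) {
    stop("OTU '", otu, "' is not part of the assembly", call. = FALSE)
  }
  df <- membership |>
    dplyr::filter(.data$otu_id != "singleton",
                  .data$otu_id %in% otu_refs$otu_id) |>
    dplyr::left_join(read_refs, by = "read_id") |>
    dplyr::left_join(
      dplyr::rename(otu_refs, own_ref = "ref_id"), by = "otu_id"
    )
  n_unmatched <- sum(is.na(df$ref_id))
  df <- df[!is.na(df$ref_id), , drop = FALSE]
  # an unmatched consensus gets a sentinel label so no read can equal it
  df$own_ref[is.na(df$own_ref)] <- paste0("<unmatched:", df$otu_id[is.na(df$own_ref)], ">")
  target_ref <- otu_refs$ref_id[otu_refs$otu_id == otu][1]
  if (is.na(target_ref)) target_ref <- paste0("<unmatched:", otu, ">")

  in_target <- df$otu_id == otu
  tp <- sum(in_target & df$ref_id == target_ref)
  fp <- sum(in_target & df$ref_id != target_ref)
  fn <- sum(!in_target & df$ref_id == target_ref)
  tn <- sum(!in_target & df$ref_id == df$own_ref & df$own_ref != target_ref)
  tibble::tibble(
    otu_id = otu, ref_id = otu_refs$ref_id[otu_refs$otu_id == otu][1],
    tp = tp, fp = fp, tn = tn, fn = fn, n_unmatched = n_unmatched
  )
}

#' Evaluate an assembly against reference templates
#'
#' Matches every assembled read and every OTU consensus to its best
#' reference, computes per-OTU confusion counts, specificity,
#' sensitivity and residual error, and sums the residual errors into the
#' assembly's total error. Singleton reads are excluded from the
#' confusion counts and reported as the singleton percentage. Degenerate
#' denominators (e.g. a single-OTU assembly, where TN + FP = 0) define
#' the affected ratio as 1.0 and are flagged.
#'
#' @param assembly An `otu_assembly` (possibly after cleanup).
#' @param reads Read sequences (a `read_set`, tibble, or named vector);
#'   must cover every read id in the assembly's membership.
#' @param references Reference templates (a `template_panel`, tibble, or
#'   named vector).
#' @param min_identity Reference-match identity floor (percent).
#' @param read_refs Optional precomputed [best_reference_match()] table
#'   for the reads (reused across sweep stages).
#' @param stage Stage label carried into the summary.
#' @return An object of class `assembly_evaluation`: list with `per_otu`
#'   (tibble `otu_id`, `ref_id`, `tp`, `fp`, `tn`, `fn`, `specificity`,
#'   `sensitivity`, `residual_error`, `sp_degenerate`, `sn_degenerate`,
#'   `n_unmatched`), `summary` (one-row tibble with `stage`,
#'   `total_error`, `n_otus`, `pct_singletons`, ...), and `read_refs`.
#' @export
evaluate_assembly <- function(assembly, reads, references,
                              min_identity = 55, read_refs = NULL,
                              stage = "raw") {
  stopifnot(inherits(assembly, "otu_assembly"))
  refs <- if (inherits(references, "template_panel")) {
    setNames(references$templates$sequence, references$templates$template_id)
  } else {
    as_named_seqs(references)
  }
  seqs <- if (inherits(reads, "read_set")) {
    setNames(reads$reads$sequence, reads$reads$read_id)
  } else {
    as_named_seqs(reads, id_col = "read_id", seq_col = "sequence")
  }
  membership <- assembly$membership
  assembled_ids <- membership$read_id[
    membership$otu_id %in% assembly$otus$otu_id
  ]
  if (!all(assembled_ids %in% names(seqs))) {
    stop("reads are missing sequences for some assembled read ids",
         call. = FALSE)
  }
  if (is.null(read_refs)) {
    read_refs <- best_reference_match(
      seqs[assembled_ids], refs, min_identity = min_identity,
      band = auto_band(length(assembled_ids), length(refs))
    ) |>
      dplyr::rename(read_id = "query_id")
  }
  otu_refs <- best_reference_match(
    setNames(assembly$otus$consensus, assembly$otus$otu_id), refs,
    min_identity = min_identity
  ) |>
    dplyr::rename(otu_id = "query_id") |>
    dplyr::select("otu_id", "ref_id", consensus_identity = "identity")

  per_otu <- purrr::map(
    assembly$otus$otu_id,
    ~ confusion_counts(.x, membership, otu_refs[, c("otu_id", "ref_id")],
                       read_refs[, c("read_id", "ref_id")])
  ) |>
    dplyr::bind_rows() |>
    dplyr::left_join(
      otu_refs[, c("otu_id", "consensus_identity")], by = "otu_id"
    ) |>
    dplyr::mutate(
      sp_degenerate = (.data$tn + .data$fp) == 0,
      sn_degenerate = (.data$tp + .data$fn) == 0,
      specificity = ifelse(.data$sp_degenerate, 1,
                           .data$tn / (.data$tn + .data$fp)),
      sensitivity = ifelse(.data$sn_degenerate, 1,
                           .data$tp / (.data$tp + .data$fn)),
      residual_error = residual_error(.data$specificity,
                                      .data$sensitivity)
    )

  n_reads <- assembly$n_reads
  n_singletons <- sum(membership$otu_id == "singleton")
  n_excluded <- sum(!membership$otu_id %in%
                      c("singleton", assembly$otus$otu_id))
  summary <- tibble::tibble(
    stage = stage,
    total_error = sum(per_otu$residual_error),
    n_otus = nrow(assembly$otus),
    n_reads = n_reads,
    n_assembled = length(assembled_ids),
    n_singletons = n_singletons,
    pct_singletons = 100 * n_singletons / n_reads,
    n_excluded = n_excluded,
    n_unmatched = sum(per_otu$n_unmatched[1], na.rm = TRUE),
    ml = assembly$params$ml,
    mi = assembly$params$mi
  )
  structure(
    list(per_otu = per_otu, summary = summary, read_refs = read_refs),
    class = "assembly_evaluation"
  )
}

#' @export
print.assembly_evaluation <- function(x, ...) {
  s <- x$summary
  cat("<assembly_evaluation> stage ", s$stage, ": total error ",
      sprintf("%.4f", s$total_error), " over ", s$n_otus, " OTUs; ",
      sprintf("%.1f", s$pct_singletons), "% singletons\n", sep = "")
  invisible(x)
}

#' @describeIn evaluate_assembly Per-OTU evaluation table.
#' @param x An `assembly_evaluation`.
#' @param ... Unused.
#' @export
tidy.assembly_evaluation <- function(x, ...) {
  x$per_otu
}

#' @describeIn evaluate_assembly One-row evaluation summary.
#' @export
glance.assembly_evaluation <- function(x, ...) {
  x$summary
}

#' Trim primer sequences from consensus ends
#'
#' Removes degenerate-aware primer matches sitting within `end_window`
#' bases of either end of each sequence, in either orientation, leaving
#' the interior untouched. Mirrors post-assembly primer clean-up of OTU
#' consensus sequences.
#'
#' @param x Character vector of sequences.
#' @param primer_pair One-row tibble with `forward`/`reverse` columns.
#' @param max_mismatches Per-primer mismatch tolerance (default 3).
#' @param end_window How far from an end a primer match may start/stop
#'   (default 5 bp).
#' @return Character vector of trimmed sequences.
#' @export
trim_primers <- function(x, primer_pair, max_mismatches = 3,
                         end_window = 5) {
  pats <- unique(c(primer_pair$forward[1], primer_pair$reverse[1]))
  trim_one <- function(s) {
    # 5' end: a primer (as written) at the start, sense or antisense
    repeat {
      L <- nchar(s)
      cut <- 0L
      best_mm <- Inf
      for (p in pats) {
        sites <- match_primer(s, p, max_mismatches)
        sites <- sites[sites$strand == "+" &
                         sites$start <= end_window + 1L, , drop = FALSE]
        if (nrow(sites) > 0 && sites$mismatches[1] < best_mm) {
          best_mm <- sites$mismatches[1]
          cut <- sites$end[1]
        }
      }
      if (cut == 0L) break
      s <- substr(s, cut + 1L, L)
    }
    # 3' end: a primer's reverse complement at the end
    repeat {
      L <- nchar(s)
      cut <- 0L
      best_mm <- Inf
      for (p in pats) {
        sites <- match_primer(s, revcomp(p), max_mismatches)
        sites <- sites[sites$strand == "+" &
                         sites$end >= L - end_window, , drop = FALSE]
        if (nrow(sites) > 0) {
          sites <- sites[order(sites$mismatches, -sites$start), ,
                         drop = FALSE]
          if (sites$mismatches[1] < best_mm) {
            best_mm <- sites$mismatches[1]
            cut <- sites$start[1]
          }
        }
      }
      if (cut == 0L) break
      s <- substr(s, 1L, cut - 1L)
    }
    s
  }
  vapply(x, trim_one, character(1), USE.NAMES = FALSE)
}

#' Collapse OTUs with identical (or contained) consensus sequences
#'
#' Merges OTUs whose consensus sequences are identical, or where one is
#' an exact substring of another, into the OTU with the longer
#' consensus; members are unioned. Intended to follow [trim_primers()],
#' combining OTUs that were identical once primer sequences were
#' removed.
#'
#' @param assembly An `otu_assembly` (its `otus$consensus` should already
#'   be trimmed).
#' @return A new `otu_assembly` with merged OTUs.
#' @export
collapse_identical <- function(assembly) {
  otus <- assembly$otus
  if (nrow(otus) <= 1) return(assembly)
  ord <- order(-otus$length, otus$otu_id, method = "radix")
  otus <- otus[ord, ]
  keeper_of <- setNames(otus$otu_id, otus$otu_id)
  kept <- character(0)
  for (i in seq_len(nrow(otus))) {
    merged <- FALSE
    for (kid in kept) {
      if (grepl(otus$consensus[i],
                otus$consensus[otus$otu_id == kid],
                fixed = TRUE)) {
        keeper_of[otus$otu_id[i]] <- kid
        merged <- TRUE
        break
      }
    }
    if (!merged) kept <- c(kept, otus$otu_id[i])
  }
  membership <- assembly$membership
  assigned <- membership$otu_id %in% names(keeper_of)
  membership$otu_id[assigned] <-
    unname(keeper_of[membership$otu_id[assigned]])
  new_otus <- otus[otus$otu_id %in% kept, ]
  counts <- table(membership$otu_id)
  new_otus$n_members <-
    as.integer(counts[new_otus$otu_id])
  new_otus <- new_otus[order(new_otus$otu_id, method = "radix"), ]
  structure(
    list(
      otus = new_otus,
      membership = membership,
      params = assembly$params,
      n_reads = assembly$n_reads
    ),
    class = "otu_assembly"
  )
}

#' Flag chimeric consensus sequences
#'
#' A consensus is flagged chimeric when its 5'-most and 3'-most
#' `probe_length` bases best-match different references. Sequences
#' shorter than `min_length` are not evaluable and are reported
#' unflagged.
#'
#' @param x Named character vector (or tibble) of consensus sequences.
#' @param references Reference templates.
#' @param probe_length Length of each terminal probe (default 150).
#' @param min_length Minimum evaluable consensus length (default 300).
#' @param min_identity Identity floor for the probe matches.
#' @return A tibble: `id`, `is_chimera`, `evaluable`, `ref_5p`, `ref_3p`.
#' @export
flag_chimera <- function(x, references, probe_length = 150,
                         min_length = 300, min_identity = 55) {
  seqs <- as_named_seqs(x)
  refs <- if (inherits(references, "template_panel")) {
    setNames(references$templates$sequence, references$templates$template_id)
  } else {
    as_named_seqs(references)
  }
  out <- tibble::tibble(
    id = names(seqs),
    is_chimera = FALSE,
    evaluable = nchar(seqs) >= min_length,
    ref_5p = NA_character_,
    ref_3p = NA_character_
  )
  ev <- which(out$evaluable)
  if (length(ev) > 0) {
    head5 <- substr(seqs[ev], 1, probe_length)
    tail3 <- substr(seqs[ev], nchar(seqs[ev]) - probe_length + 1,
                    nchar(seqs[ev]))
    m5 <- best_reference_match(setNames(head5, names(seqs)[ev]), refs,
                               min_identity = min_identity)
    m3 <- best_reference_match(setNames(tail3, names(seqs)[ev]), refs,
                               min_identity = min_identity)
    out$ref_5p[ev] <- m5$ref_id
    out$ref_3p[ev] <- m3$ref_id
    out$is_chimera[ev] <- !is.na(m5$ref_id) & !is.na(m3$ref_id) &
      m5$ref_id != m3$ref_id
  }
  out
}

#' Evaluate an assembly through the post-assembly cleanup stages
#'
#' Runs the three-stage evaluation: the raw assembly; after primer
#' trimming and 100% clustering; and after removal of chimeric OTUs
#' (whose reads are excluded from further evaluation, not re-assigned).
#'
#' @inheritParams evaluate_assembly
#' @param primer_pair Primer pair used for trimming (default: the UT
#'   pair).
#' @return A list of class `assembly_stages` with elements `raw`,
#'   `trimmed_clustered`, `chimera_removed` (each an
#'   `assembly_evaluation`), the final cleaned `assembly`, and a
#'   combined `summary` tibble (one row per stage).
#' @export
evaluate_stages <- function(assembly, reads, references,
                            primer_pair = get_primer_pair("UT"),
                            min_identity = 55, read_refs = NULL) {
  ev_raw <- evaluate_assembly(assembly, reads, references,
                              min_identity = min_identity,
                              read_refs = read_refs, stage = "raw")
  read_refs <- ev_raw$read_refs

  trimmed <- assembly
  trimmed$otus$consensus <- trim_primers(trimmed$otus$consensus, primer_pair)
  trimmed$otus$length <- nchar(trimmed$otus$consensus)
  clustered <- collapse_identical(trimmed)
  ev_trim <- evaluate_assembly(clustered, reads, references,
                               min_identity = min_identity,
                               read_refs = read_refs,
                               stage = "trimmed_clustered")

  flags <- flag_chimera(
    setNames(clustered$otus$consensus, clustered$otus$otu_id),
    references, min_identity = min_identity
  )
  cleaned <- clustered
  drop <- flags$id[flags$is_chimera]
  if (length(drop) > 0) {
    cleaned$otus <- cleaned$otus[!cleaned$otus$otu_id %in% drop, ]
    cleaned$membership$otu_id[cleaned$membership$otu_id %in% drop] <-
      "excluded_chimera"
  }
  ev_chim <- evaluate_assembly(cleaned, reads, references,
                               min_identity = min_identity,
                               read_refs = read_refs,
                               stage = "chimera_removed")
  structure(
    list(
      raw = ev_raw,
      trimmed_clustered = ev_trim,
      chimera_removed = ev_chim,
      assembly = cleaned,
      chimera_flags = flags,
      summary = dplyr::bind_rows(
        ev_raw$summary, ev_trim$summary, ev_chim$summary
      )
    ),
    class = "assembly_stages"
  )
}

#' @export
print.assembly_stages <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Sweep assembler parameters and evaluate each assembly
#'
#' Assembles the same read set under every combination of minimum
#' overlap length and minimum overlap identity, evaluates each assembly
#' at the three cleanup stages, and tabulates total error, OTU count and
#' singleton percentage — the machine-readable twin of an error
#' trade-off figure.
#'
#' @param reads Reads (a `read_set`, tibble, or named vector).
#' @param references Reference templates.
#' @param ml Vector of minimum overlap lengths (default
#'   `c(50, 100, ..., 400)`).
#' @param mi Vector of minimum overlap identities in percent (default
#'   92).
#' @param primer_pair Primer pair for trimming.
#' @param min_identity Reference-match identity floor.
#' @param ... Further arguments passed to [assemble()].
#' @return A tibble of class `assembly_sweep`: `ml`, `mi`, `stage`,
#'   `total_error`, `n_otus`, `pct_singletons`, `n_singletons`.
#' @export
sweep_assembly <- function(reads, references,
                           ml = seq(50, 400, by = 50), mi = 92,
                           primer_pair = get_primer_pair("UT"),
                           min_identity = 55, ...) {
  seqs <- if (inherits(reads, "read_set")) {
    setNames(reads$reads$sequence, reads$reads$read_id)
  } else {
    as_named_seqs(reads, id_col = "read_id", seq_col = "sequence")
  }
  refs <- if (inherits(references, "template_panel")) {
    setNames(references$templates$sequence, references$templates$template_id)
  } else {
    as_named_seqs(references)
  }
  # reads never change across the sweep: match them to references once
  read_refs <- best_reference_match(
    seqs, refs, min_identity = min_identity,
    band = auto_band(length(seqs), length(refs))
  ) |>
    dplyr::rename(read_id = "query_id")

  grid <- tidyr::expand_grid(ml = ml, mi = mi)
  rows <- purrr::pmap(grid, function(ml, mi) {
    asm <- assemble(seqs, ml = ml, mi = mi, ...)
    st <- evaluate_stages(asm, seqs, refs, primer_pair = primer_pair,
                          min_identity = min_identity,
                          read_refs = read_refs)
    dplyr::transmute(
      st$summary,
      ml = ml, mi = mi, stage = .data$stage,
      total_error = .data$total_error, n_otus = .data$n_otus,
      pct_singletons = .data$pct_singletons,
      n_singletons = .data$n_singletons
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("assembly_sweep", class(out))
  out
}
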