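# Synthetic data generation: template panels with a controlled pairwise
# identity envelope, amplicon read sets sequenced from both ends, and
# annotated genome fixtures with designed intra-/inter-species
# divergence for the barcode-gap pipeline.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly k randomly chosen positions to a different base.
substitute_k <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Poisson substitution process at expected `d` substitutions/site (each
# hit replaces the base by a uniform different base), so that
# model-corrected distances recover `d` in expectation.
evolve_seq <- function(seq, d) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- rpois(length(chars), d)
  for (p in which(hits > 0)) {
    for (h in seq_len(hits[p])) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  }
  paste(chars, collapse = "")
}

#' Derive a template at a target identity to a parent sequence
#'
#' Substitutes exactly `round((1 - identity) * length)` positions of the
#' parent, so the pairwise identity of parent and child is the target up
#' to rounding (1 position in `length`). Useful for constructing close
#' template pairs (e.g. a 96% pair) explicitly.
#'
#' @param parent Parent sequence.
#' @param identity Target pairwise identity as a fraction.
#' @param seed Optional RNG seed.
#' @return The derived sequence.
#' @export
mutate_to_identity <- function(parent, identity, seed = NULL) {
  stopifnot(identity > 0, identity <= 1)
  with_seed(seed, {
    substitute_k(parent, round((1 - identity) * nchar(parent)))
  })
}

#' Generate a synthetic template panel
#'
#' Builds a panel of cpn60-UT-like template sequences by mutating a
#' random ancestor along a star tree, with per-branch substitution counts
#' drawn so that all pairwise identities land inside the `[lo, hi]`
#' envelope; violating pairs are rejection-adjusted by redrawing one
#' member. Template lengths vary by at most one codon around `length`
#' (insertion or deletion of 3 bp), matching the length class of the
#' universal target. Deterministic given `seed`.
#'
#' The default emulates a 20-member community of cloned universal targets
#' with pairwise identities ranging over 56-96%. Default branch
#' divergences are drawn on `[0.05, (1 - lo)/2]`, which keeps realized
#' identities inside the envelope while leaving distinct templates
#' separated by at least roughly 10%; deliberately close template pairs
#' (e.g. two species at 96%) can be added via [mutate_to_identity()].
#'
#' @param n Number of templates.
#' @param lo,hi Pairwise identity envelope (fractions, `0 < lo <= hi < 1`).
#' @param length Core template length in bp (default 555).
#' @param seed RNG seed (default 42).
#' @param divergence Optional length-2 range of per-branch divergences;
#'   default `c(0.05, (1 - lo) / 2)`.
#' @param indel Whether templates may gain/lose one codon (default TRUE).
#' @param max_tries Rejection-adjustment budget before declaring the
#'   bounds infeasible.
#' @return An object of class `template_panel`: list with `templates`
#'   (tibble `template_id`, `sequence`, `length`), `lo`, `hi`, `seed`,
#'   `primer_pair` (the UT pair, used to flank simulated amplicons).
#' @export
generate_panel <- function(n = 20, lo = 0.56, hi = 0.96, length = 555,
                           seed = 42, divergence = NULL, indel = TRUE,
                           max_tries = 200) {
  stopifnot(n >= 2, lo > 0, lo <= hi, hi < 1, length >= 60)
  if (is.null(divergence)) {
    divergence <- c(min(0.05, (1 - lo) / 4), (1 - lo) / 2)
  }
  stopifnot(length(divergence) == 2, divergence[1] <= divergence[2])

  with_seed(seed, {
    ancestor <- random_seq(length)
    draw <- function() {
      d <- runif(1, divergence[1], divergence[2])
      s <- substitute_k(ancestor, round(d * length))
      if (indel) {
        move <- sample(c("none", "ins", "del"), 1)
        if (move == "ins") {
          at <- sample(nchar(s) - 1, 1)
          s <- paste0(substr(s, 1, at), random_seq(3),
                      substr(s, at + 1, nchar(s)))
        } else if (move == "del") {
          at <- sample(nchar(s) - 3, 1)
          s <- paste0(substr(s, 1, at), substr(s, at + 4, nchar(s)))
        }
      }
      s
    }
    templates <- vapply(seq_len(n), function(i) draw(), character(1))

    pair_id <- function(i, j) panel_pair_identity(templates[i], templates[j])
    # Nudge the identity of an equal-length pair toward a target by
    # substituting matching positions (to lower it) or copying the
    # partner's base at mismatching positions (to raise it).
    nudge <- function(child, parent, target) {
      pc <- strsplit(parent, "", fixed = TRUE)[[1]]
      cc <- strsplit(child, "", fixed = TRUE)[[1]]
      L <- length(cc)
      delta <- round((sum(pc != cc) / L - (1 - target)) * L)
      if (delta > 0) {  # too dissimilar: repair mismatches
        fix <- sample(which(pc != cc), min(delta, sum(pc != cc)))
        cc[fix] <- pc[fix]
      } else if (delta < 0) {  # too similar: break matches
        brk <- sample(which(pc == cc), min(-delta, sum(pc == cc)))
        for (p in brk) cc[p] <- sample(setdiff(c("A", "C", "G", "T"), cc[p]), 1)
      }
      paste(cc, collapse = "")
    }
    ok <- FALSE
    # identity is quantised in steps of 1/length, so the bounds carry a
    # one-position slack
    tol <- 1 / length
    for (try in seq_len(max_tries)) {
      bad <- NULL
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          idij <- pair_id(i, j)
          if (idij < lo - tol || idij > hi + tol) {
            bad <- c(i, j, idij)
            break
          }
        }
        if (!is.null(bad)) break
      }
      if (is.null(bad)) {
        ok <- TRUE
        break
      }
      i <- bad[1]; j <- bad[2]
      if (nchar(templates[i]) == nchar(templates[j])) {
        target <- if (bad[3] > hi) hi else lo
        templates[j] <- nudge(templates[j], templates[i], target)
      } else {
        templates[j] <- draw()
      }
    }
    if (!ok) {
      stop("could not satisfy identity bounds [", lo, ", ", hi,
           "] for n = ", n, " templates after ", max_tries,
           " adjustments; bounds may be infeasible", call. = FALSE)
    }
    pp <- get_primer_pair("UT")
    # each cloned template carries one fixed primer-flanked amplicon;
    # degenerate primer positions are concretised once per template
    amplicons <- vapply(templates, function(tpl) {
      paste0(
        concretize_primer(pp$forward), tpl,
        revcomp(concretize_primer(pp$reverse))
      )
    }, character(1), USE.NAMES = FALSE)
    structure(
      list(
        templates = tibble::tibble(
          template_id = sprintf("T%02d", seq_len(n)),
          sequence = templates,
          length = nchar(templates),
          amplicon = amplicons
        ),
        lo = lo, hi = hi, seed = seed,
        primer_pair = pp
      ),
      class = "template_panel"
    )
  })
}

#' @export
print.template_panel <- function(x, ...) {
  cat("<template_panel> ", nrow(x$templates), " templates, ",
      min(x$templates$length), "-", max(x$templates$length),
      " bp, identity envelope [", x$lo, ", ", x$hi, "], seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# Pairwise template identity: fraction of identical positions for
# equal-length pairs (a mismatch count), overlap-alignment identity
# when lengths differ (codon indels).
panel_pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(b, "", fixed = TRUE)[[1]]
    return(mean(ca == cb))
  }
  cpp_best_overlap(a, b, band = -1L)$identity / 100
}

#' All pairwise template identities of a panel
#'
#' Identity is the fraction of identical positions for equal-length
#' template pairs and the best overlap-alignment identity otherwise.
#'
#' @param panel A `template_panel`.
#' @return Tibble `id_a`, `id_b`, `identity` (fraction).
#' @export
panel_identities <- function(panel) {
  tpl <- panel$templates
  pairs <- utils::combn(nrow(tpl), 2)
  tibble::tibble(
    id_a = tpl$template_id[pairs[1, ]],
    id_b = tpl$template_id[pairs[2, ]],
    identity = vapply(seq_len(ncol(pairs)), function(k) {
      panel_pair_identity(tpl$sequence[pairs[1, k]],
                          tpl$sequence[pairs[2, k]])
    }, numeric(1))
  )
}

#' Primer-flanked amplicons of a panel
#'
#' @param panel A `template_panel`.
#' @return Named character vector of amplicon sequences (fixed at panel
#'   generation).
#' @export
panel_amplicons <- function(panel) {
  setNames(panel$templates$amplicon, panel$templates$template_id)
}

#' Simulate amplicon reads from a template panel
#'
#' Draws reads alternately from the 5' end (forward orientation) and the
#' 3' end (reverse-complement orientation) of each template's
#' primer-flanked amplicon, emulating amplicon pyrosequencing from both
#' ends. Read lengths follow a normal distribution with the requested
#' median (sd = 0.15 x median) truncated to `[80, amplicon length]`.
#' Substitution errors occur at `error_rate` per base; when
#' `homopolymer_bias > 0`, each homopolymer run of length >= 3 in a read
#' gains or loses one base with that probability (the dominant
#' pyrosequencing error mode).
#'
#' @param panel A `template_panel`.
#' @param reads_per_template Reads per template (default 172, i.e. 3,440
#'   reads from the default 20-template panel).
#' @param median_length Target median read length (default 394).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param homopolymer_bias Per-homopolymer probability of a +-1 length
#'   error (default 0).
#' @param seed Optional RNG seed.
#' @return An object of class `read_set`: list with `reads` (tibble
#'   `read_id`, `sequence`, `length`, `direction`, `template_id`),
#'   `truth` (tibble `read_id`, `template_id`) and `params`.
#' @export
simulate_reads <- function(panel, reads_per_template = 172,
                           median_length = 394, error_rate = 0,
                           homopolymer_bias = 0, seed = NULL) {
  stopifnot(inherits(panel, "template_panel"), reads_per_template >= 1)
  with_seed(seed, {
    amplicons <- panel_amplicons(panel)
    if (any(median_length > nchar(amplicons))) {
      stop("median_length exceeds an amplicon length", call. = FALSE)
    }
    sd_len <- 0.15 * median_length
    rows <- list()
    for (i in seq_along(amplicons)) {
      amp <- amplicons[i]
      L <- nchar(amp)
      tid <- panel$templates$template_id[i]
      for (r in seq_len(reads_per_template)) {
        len <- 0L
        while (len < 80L || len > L) {
          len <- as.integer(round(rnorm(1, median_length, sd_len)))
        }
        from_5p <- (r %% 2L) == 1L
        s <- if (from_5p) {
          substr(amp, 1, len)
        } else {
          revcomp(substr(amp, L - len + 1L, L))
        }
        if (error_rate > 0) {
          nerr <- rbinom(1, len, error_rate)
          if (nerr > 0) s <- substitute_k(s, nerr)
        }
        if (homopolymer_bias > 0) {
          s <- jitter_homopolymers(s, homopolymer_bias)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          read_id = sprintf("%s_r%04d", tid, r),
          sequence = s,
          length = nchar(s),
          direction = if (from_5p) "5p" else "3p",
          template_id = tid
        )
      }
    }
    reads <- dplyr::bind_rows(rows)
    structure(
      list(
        reads = reads,
        truth = reads[, c("read_id", "template_id")],
        params = list(
          reads_per_template = reads_per_template,
          median_length = median_length, error_rate = error_rate,
          homopolymer_bias = homopolymer_bias, seed = seed
        )
      ),
      class = "read_set"
    )
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", nrow(x$reads), " reads from ",
      length(unique(x$reads$template_id)), " templates, median length ",
      median(x$reads$length), "\n", sep = "")
  invisible(x)
}

# +-1 errors in homopolymer runs of length >= 3.
jitter_homopolymers <- function(s, p) {
  m <- gregexpr("(A{3,}|C{3,}|G{3,}|T{3,})", s)[[1]]
  if (m[1] == -1) return(s)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # process right-to-left so earlier coordinates stay valid
  for (k in rev(seq_along(starts))) {
    if (runif(1) < p) {
      base <- substr(s, starts[k], starts[k])
      newlen <- lens[k] + sample(c(-1L, 1L), 1)
      s <- paste0(
        substr(s, 1, starts[k] - 1L),
        strrep(base, newlen),
        substr(s, starts[k] + lens[k], nchar(s) + 1L)
      )
    }
  }
  s
}

#' Write a read set as FASTQ (placeholder qualities) or FASTA
#'
#' @param read_set A `read_set`.
#' @param path Output path; format chosen by extension (`.fastq`/`.fq`
#'   for FASTQ, anything else FASTA).
#' @return `path`, invisibly.
#' @export
write_reads <- function(read_set, path) {
  r <- read_set$reads
  if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) {
    lines <- as.vector(rbind(
      paste0("@", r$read_id), r$sequence, "+",
      strrep("I", nchar(r$sequence))
    ))
    writeLines(lines, path)
  } else {
    write_fasta(setNames(r$sequence, r$read_id), path)
  }
  invisible(path)
}

#' Generate an annotated genome fixture with designed divergences
#'
#' Builds a small collection of synthetic annotated genomes for the
#' marker-extraction and barcode-gap pipeline: a root marker sequence is
#' evolved to species ancestors (pairwise divergence ~ `inter`) and then
#' to genomes within each species (pairwise divergence ~ `intra`), for a
#' 16S-like rRNA gene and a cpn60-like CDS embedded with random flanking
#' sequence. Every second cpn60 copy is placed on the minus strand.
#' Paralogs beyond the first are evolved at `paralog_divergence`,
#' emulating the highly divergent chaperonin paralogs of some taxa.
#'
#' @param n_species Number of species.
#' @param genomes_per_species Genomes per species.
#' @param paralogs cpn60-like copies per genome.
#' @param intra Designed intra-species pairwise divergence
#'   (substitutions/site).
#' @param inter Designed inter-species pairwise divergence; must exceed
#'   `intra`.
#' @param paralog_divergence Designed divergence of extra paralogs.
#' @param marker_length Length of the cpn60-like marker (the 16S-like
#'   marker is 3 x this).
#' @param flank Random flanking sequence on each side of each gene.
#' @param seed Optional RNG seed.
#' @return An object of class `genome_fixture`: list with `records`
#'   (genome records as from [read_genbank()]), `genbank` (flat-file
#'   text), `taxonomy` (tibble), and `params`.
#' @export
generate_genome_fixture <- function(n_species = 5, genomes_per_species = 3,
                                    paralogs = 1, intra = 0.01,
                                    inter = 0.30, paralog_divergence = 0.4,
                                    marker_length = 555, flank = 150,
                                    seed = NULL) {
  stopifnot(n_species >= 1, genomes_per_species >= 1, paralogs >= 1,
            inter > intra, intra >= 0)
  with_seed(seed, {
    root_cpn <- random_seq(marker_length)
    root_16s <- random_seq(3 * marker_length)
    records <- list()
    tax <- list()
    for (sp in seq_len(n_species)) {
      sp_cpn <- evolve_seq(root_cpn, inter / 2)
      sp_16s <- evolve_seq(root_16s, inter / 2)
      taxon <- sprintf("9%04d", sp)
      tax[[sp]] <- tibble::tibble(
        taxon_id = taxon,
        species = sprintf("Synthecoccus_species_%02d", sp),
        lineage = paste("Bacteria", "Synthetica", "Synthecoccus",
                        sep = ";")
      )
      for (g in seq_len(genomes_per_species)) {
        gid <- sprintf("SYN%02dG%02d", sp, g)
        cpn <- evolve_seq(sp_cpn, intra / 2)
        s16 <- evolve_seq(sp_16s, intra / 2)
        genes <- list(list(
          type = "rRNA", product = "16S ribosomal RNA",
          gene = NA_character_, seq = s16, strand = "+"
        ))
        cpn_products <- c("cpn60", "groEL chaperonin",
                          "60 kDa chaperonin", "heat shock protein Hsp60")
        copy <- cpn
        for (p in seq_len(paralogs)) {
          if (p > 1) copy <- evolve_seq(cpn, paralog_divergence)
          genes[[length(genes) + 1L]] <- list(
            type = "CDS",
            product = cpn_products[(p - 1) %% length(cpn_products) + 1],
            gene = if (p == 1) "groEL" else sprintf("groEL%d", p),
            seq = copy,
            strand = if (p %% 2 == 0) "-" else "+"
          )
        }
        seqparts <- character(0)
        feats <- list()
        pos <- 1L
        for (gn in genes) {
          left <- random_seq(flank)
          seqparts <- c(seqparts, left)
          pos <- pos + flank
          gl <- nchar(gn$seq)
          placed <- if (gn$strand == "-") revcomp(gn$seq) else gn$seq
          seqparts <- c(seqparts, placed)
          feats[[length(feats) + 1L]] <- tibble::tibble(
            type = gn$type, start = pos, end = pos + gl - 1L,
            strand = gn$strand, gene = gn$gene, product = gn$product
          )
          pos <- pos + gl
        }
        seqparts <- c(seqparts, random_seq(flank))
        records[[length(records) + 1L]] <- new_genome_record(
          genome_id = gid, taxon_id = taxon,
          sequence = paste(seqparts, collapse = ""),
          features = dplyr::bind_rows(feats)
        )
      }
    }
    taxonomy <- dplyr::bind_rows(tax)
    structure(
      list(
        records = records,
        genbank = write_genbank(records),
        taxonomy = taxonomy,
        params = list(
          n_species = n_species,
          genomes_per_species = genomes_per_species,
          paralogs = paralogs, intra = intra, inter = inter,
          paralog_divergence = paralog_divergence, seed = seed
        )
      ),
      class = "genome_fixture"
    )
  })
}

#' @export
print.genome_fixture <- function(x, ...) {
  p <- x$params
  cat("<genome_fixture> ", p$n_species, " species x ",
      p$genomes_per_species, " genomes, ", p$paralogs,
      " cpn60-like paralog(s); designed divergence intra ", p$intra,
      ", inter ", p$inter, "\n", sep = "")
  invisible(x)
}
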