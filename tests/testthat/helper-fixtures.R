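# Shared fixture builders. Everything is generated in code; the GenBank
# text fixture is formatted by hand so parser tests do not depend on the
# package's own writer.

make_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly k positions of a sequence (helper-local copy so the
# tests do not lean on package internals).
sub_k <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Hand-formatted GenBank flat text for one locus.
gb_text <- function(sequence, features, locus = "TESTG1", taxon = "1234") {
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
            locus, nchar(sequence)),
    sprintf("DEFINITION  %s test fixture.", locus),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence)),
    "                     /organism=\"test organism\"",
    if (!is.na(taxon)) sprintf("                     /db_xref=\"taxon:%s\"", taxon)
  )
  for (f in features) {
    loc <- if (identical(f$strand, "-")) {
      sprintf("complement(%d..%d)", f$start, f$end)
    } else {
      sprintf("%d..%d", f$start, f$end)
    }
    lines <- c(lines, sprintf("     %-15s %s", f$type, loc))
    if (!is.null(f$gene)) {
      lines <- c(lines, sprintf("                     /gene=\"%s\"", f$gene))
    }
    if (!is.null(f$product)) {
      lines <- c(lines,
                 sprintf("                     /product=\"%s\"", f$product))
    }
  }
  lines <- c(lines, "ORIGIN")
  for (p in seq(1, nchar(sequence), by = 60)) {
    chunk <- substr(sequence, p, min(p + 59, nchar(sequence)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  paste(c(lines, "//"), collapse = "\n")
}

# Error-free reads tiled across a template (all forward).
tile_reads <- function(template, n, len, prefix = "r") {
  L <- nchar(template)
  starts <- round(seq(1, L - len + 1, length.out = n))
  setNames(
    vapply(starts, function(s) substr(template, s, s + len - 1),
           character(1)),
    sprintf("%s%03d", prefix, seq_len(n))
  )
}

# Independent brute-force confusion-count oracle: explicit set
# enumeration over a labelled fixture.
oracle_confusion <- function(otu, membership, otu_refs, read_refs) {
  keep <- membership$otu_id != "singleton" &
    membership$otu_id %in% otu_refs$otu_id
  m <- membership[keep, , drop = FALSE]
  ref_of_read <- setNames(read_refs$ref_id, read_refs$read_id)
  ref_of_otu <- setNames(otu_refs$ref_id, otu_refs$otu_id)
  tgt <- ref_of_otu[[otu]]
  tp <- fp <- tn <- fn <- 0
  for (r in seq_len(nrow(m))) {
    rref <- ref_of_read[[m$read_id[r]]]
    if (is.na(rref)) next
    oid <- m$otu_id[r]
    if (oid == otu) {
      if (!is.na(tgt) && rref == tgt) tp <- tp + 1 else fp <- fp + 1
    } else {
      own <- ref_of_otu[[oid]]
      if (!is.na(tgt) && rref == tgt) {
        fn <- fn + 1
      } else if (!is.na(own) && rref == own &&
                 (is.na(tgt) || own != tgt)) {
        tn <- tn + 1
      }
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Random labelled fixture for the confusion-count property tests.
random_label_fixture <- function(n_otus, n_reads, refs = LETTERS[1:5],
                                 p_na = 0.05) {
  otus <- sprintf("OTU_%03d", seq_len(n_otus))
  membership <- tibble::tibble(
    read_id = sprintf("r%03d", seq_len(n_reads)),
    otu_id = sample(c(otus, "singleton"), n_reads, replace = TRUE)
  )
  otu_refs <- tibble::tibble(
    otu_id = otus,
    ref_id = sample(refs, n_otus, replace = TRUE)
  )
  read_refs <- tibble::tibble(
    read_id = membership$read_id,
    ref_id = ifelse(runif(n_reads) < p_na, NA_character_,
                    sample(refs, n_reads, replace = TRUE))
  )
  list(membership = membership, otu_refs = otu_refs, read_refs = read_refs)
}
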