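# Independent oracles and small in-code fixtures. Everything here is kept
# deliberately naive (explicit walks, O(n^2) closures, whole-protein
# retranslation) so that it exercises none of the package's own shortcuts.

# hard-coded one- to three-letter residue map (oracle-side copy)
ORACLE_AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "*")

# translate via seqinr (independent of Biostrings)
oracle_translate_codon <- function(codon) {
  aa1 <- seqinr::translate(strsplit(codon, "")[[1]])
  unname(ORACLE_AA3[aa1])
}

oracle_translate_protein <- function(cds) {
  aa1 <- seqinr::translate(strsplit(cds, "")[[1]])
  unname(ORACLE_AA3[aa1])
}

# genomic positions of CDS bases in transcript order, by explicit walk
oracle_cds_walk <- function(tx) {
  out <- integer(0)
  ex <- tx$exons
  if (tx$strand == "+") {
    for (i in seq_len(nrow(ex))) out <- c(out, seq(ex$start[i], ex$end[i]))
  } else {
    for (i in rev(seq_len(nrow(ex)))) out <- c(out, seq(ex$end[i], ex$start[i]))
  }
  out
}

# brute-force transitive closure over pairwise linkage; returns a list of
# position-vectors (clusters of size >= 2), sorted
oracle_closure_clusters <- function(calls, max_gap, transcripts = NULL) {
  n <- nrow(calls)
  if (n == 0) return(list())
  codon_of <- function(i) {
    keys <- character(0)
    for (tx in (transcripts %||% list())) {
      if (tx$contig != calls$contig[i]) next
      cc <- tryCatch(genomic_to_cds(tx, calls$pos[i]), error = function(e) NULL)
      if (!is.null(cc)) keys <- c(keys, paste0(tx$transcript_id, "#", cc$codon_number))
    }
    keys
  }
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { link[i, j] <- TRUE; next }
    if (calls$contig[i] != calls$contig[j]) next
    gap <- abs(calls$pos[j] - calls$pos[i]) - 1L
    same_codon <- length(intersect(codon_of(i), codon_of(j))) > 0
    link[i, j] <- gap <= max_gap || same_codon
  }
  repeat {                                   # Warshall-style closure
    nxt <- link | (link %*% link > 0)
    if (identical(nxt, link)) break
    link <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    cid <- cid + 1L
    comp[which(link[i, ])] <- cid
  }
  out <- lapply(split(seq_len(n), comp), function(g)
    sort(paste0(calls$contig[g], ":", calls$pos[g])))
  out <- Filter(function(g) length(g) >= 2, out)
  unname(out[order(vapply(out, `[`, "", 1))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-CDS retranslation oracle: apply edits to the coding sequence, then
# translate the whole protein and diff residues against the wild type
oracle_retranslate <- function(cds, edits) {
  alt <- cds
  for (i in seq_len(nrow(edits)))
    substr(alt, edits$c_position[i], edits$c_position[i]) <- edits$alt[i]
  ref_prot <- oracle_translate_protein(cds)
  alt_prot <- oracle_translate_protein(alt)
  data.frame(codon_number = seq_along(ref_prot), ref_aa = ref_prot,
             alt_aa = alt_prot)[ref_prot != alt_prot | seq_along(ref_prot) %in%
                                  unique((edits$c_position - 1) %/% 3 + 1), ]
}

# a small hand-made reference + plus/minus transcripts used across tests
make_manual_reference <- function() {
  # ctgP layout: 10 bp pad | exon1 (9 bp: ATG GGA TC) wait - keep simple:
  # exon1 = ATGGGATC (8 bp), intron (5 bp), exon2 (7 bp) -> CDS 15 nt
  ex1 <- "ATGGGATC"; intr <- "TTTTT"; ex2 <- "ACTGTAA"
  ctgP <- paste0("GGGGGGGGGG", ex1, intr, ex2, "CCCCCCCCCC")
  # minus-strand transcript: coding sequence ATG TAC AAA TAA (12 nt),
  # single exon; genomic = revcomp placed after 6 bp pad
  cds_m <- "ATGTACAAATAA"
  ctgM <- paste0("AAAAAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cds_m))), "GGGGGG")
  reference_sequence(c(ctgP = ctgP, ctgM = ctgM))
}

manual_plus_tx <- function() {
  # CDS: ATGGGATC + ACTGTAA = ATG GGA TCA CTG TAA (codon 4 = CTG spans
  # the junction: T,C in exon1? no: positions 9..16 exon1, 22..28 exon2.
  transcript("TXP", "GENEP", "ctgP", "+",
             data.frame(start = c(11, 24), end = c(18, 30)),
             downstream_seq = "CCCCCCCCC")
}

manual_minus_tx <- function(downstream = "") {
  transcript("TXM", "GENEM", "ctgM", "-",
             data.frame(start = 7, end = 18), downstream_seq = downstream)
}

# random transcript embedded in a random contig; returns list(ref, tx, cds)
random_manual_tx <- function(seed) {
  set.seed(seed)
  n_codons <- sample(20:60, 1)
  cds_len <- 3L * n_codons
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(1:3, 1)
  cuts <- sort(sample(seq_len(cds_len - 1), n_ex - 1))
  lens <- diff(c(0L, cuts, cds_len))
  cds <- paste(sample(c("A", "C", "G", "T"), cds_len, replace = TRUE),
               collapse = "")
  pieces <- substring(cds, cumsum(c(1L, lens))[seq_along(lens)], cumsum(lens))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  parts <- pad(10)
  ivs <- matrix(0L, n_ex, 2)
  if (strand == "+") {
    for (i in seq_len(n_ex)) {
      if (i > 1) parts <- paste0(parts, pad(7))
      ivs[i, 1] <- nchar(parts) + 1L
      parts <- paste0(parts, pieces[i])
      ivs[i, 2] <- nchar(parts)
    }
  } else {
    for (i in rev(seq_len(n_ex))) {
      ivs[i, 1] <- nchar(parts) + 1L
      parts <- paste0(parts, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pieces[i]))))
      ivs[i, 2] <- nchar(parts)
      if (i > 1) parts <- paste0(parts, pad(7))
    }
  }
  parts <- paste0(parts, pad(10))
  ref <- reference_sequence(stats::setNames(parts, "ctgR"))
  tx <- transcript("TXR", "GENER", "ctgR", strand,
                   data.frame(start = ivs[, 1], end = ivs[, 2]))
  list(ref = ref, tx = tx, cds = cds)
}

# materialize a fixture into a session temp dir and run the pipeline
run_fixture_pipeline <- function(fixture, dir = tempfile("fixture"),
                                 bam = TRUE, ...) {
  paths <- materialize_fixture(fixture, dir, reads = bam)
  cfg <- run_config(paths$reference, paths$transcripts, paths$vcf,
                    bam = if (bam) paths$bam else NULL,
                    out_dir = file.path(dir, "out"), ...)
  run_pipeline(cfg, quiet = TRUE)
}
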