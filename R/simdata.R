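# Deterministic generator of synthetic references, transcript models,
# planted-MNV reads and truth sets. Fixtures reproduce the coding (c.)
# positions and codon changes of the published simulated and clinical MNV
# tables on synthetic contigs; no external genome is required. All
# randomness is driven by the seed stored in the fixture spec, so
# (spec, seed) -> identical bytes.

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rand_nonstop_codons <- function(n) {
  if (n == 0) return(character(0))
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- rand_bases(3)
      if (!cod %in% STOP_CODONS) break
    }
    out[i] <- cod
  }
  out
}

#' Declare a synthetic transcript layout
#'
#' @param transcript_id,gene,contig,strand Identifiers and orientation.
#' @param n_codons CDS length in codons (including the stop codon).
#' @param exon_lengths Coding lengths (nt) of the CDS exons in transcript
#'   order; must sum to `3 * n_codons`.
#' @param downstream_stop_codon 1-based codon index of the first in-frame
#'   stop in the generated downstream (post-stop) region, or `NA` for a
#'   downstream region with no in-frame stop.
#' @param downstream_extra_codons Codons generated beyond the downstream
#'   stop (default 4).
#' @return List describing the transcript layout.
#' @export
transcript_layout <- function(transcript_id, gene, contig, strand, n_codons,
                              exon_lengths = n_codons * 3L,
                              downstream_stop_codon = 10L,
                              downstream_extra_codons = 4L) {
  if (sum(exon_lengths) != 3L * n_codons)
    stop("exon coding lengths must sum to 3 * n_codons (CDS not a multiple of 3)")
  list(transcript_id = transcript_id, gene = gene, contig = contig,
       strand = strand, n_codons = as.integer(n_codons),
       exon_lengths = as.integer(exon_lengths),
       downstream_stop_codon = downstream_stop_codon,
       downstream_extra_codons = as.integer(downstream_extra_codons))
}

#' Declare a fixture: transcripts, planted variants and read parameters
#'
#' @param transcripts List of [transcript_layout()] declarations.
#' @param variants data.frame with columns `transcript_id`, `codon_number`,
#'   `wt_codon`, `var_codon`, `zygosity` (`"hom"`/`"het"`), `phase`
#'   (`"cis"`/`"trans"`, het only) and optionally `expected_category`.
#'   May have zero rows (pure wild-type fixture).
#' @param read_length,coverage,error_rate Read simulation parameters
#'   (defaults: 150 bp single-end reads, 30x template coverage, error-free).
#' @param padding Random-sequence padding around and between transcripts.
#' @param intron_length Length of generated introns.
#' @param seed RNG seed driving every random choice of the fixture.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(transcripts, variants = empty_variants(),
                         read_length = 150L, coverage = 30, error_rate = 0,
                         padding = 300L, intron_length = 120L, seed = 1L) {
  variants <- as.data.frame(variants)
  if (nrow(variants) > 0) {
    need <- c("transcript_id", "codon_number", "wt_codon", "var_codon",
              "zygosity")
    if (!all(need %in% names(variants)))
      stop("variants need columns: ", paste(need, collapse = ", "))
    if (!"phase" %in% names(variants)) variants$phase <- "cis"
    if (!"expected_category" %in% names(variants))
      variants$expected_category <- NA_character_
    if (any(variants$wt_codon == variants$var_codon))
      stop("variant codon must differ from wild-type codon")
    if (any(!variants$zygosity %in% c("hom", "het")))
      stop("zygosity must be 'hom' or 'het'")
    tx_ids <- vapply(transcripts, `[[`, "", "transcript_id")
    if (any(!variants$transcript_id %in% tx_ids))
      stop("variant refers to unknown transcript")
    for (tid in unique(variants$transcript_id)) {
      sub <- variants[variants$transcript_id == tid, ]
      if (anyDuplicated(sub$codon_number))
        stop("planted variants overlap at a codon of ", tid)
      lay <- transcripts[[which(tx_ids == tid)]]
      if (any(sub$codon_number < 1 | sub$codon_number > lay$n_codons))
        stop("planted codon outside CDS of ", tid)
      at_stop <- sub$codon_number == lay$n_codons
      if (any(at_stop & !sub$wt_codon %in% STOP_CODONS))
        stop("wild-type codon at the final CDS codon of ", tid,
             " must be a stop codon")
      if (any(!at_stop & sub$wt_codon %in% STOP_CODONS))
        stop("wild-type stop codon planted before the end of the CDS of ", tid)
    }
  }
  structure(list(transcripts = transcripts, variants = variants,
                 read_length = as.integer(read_length), coverage = coverage,
                 error_rate = error_rate, padding = as.integer(padding),
                 intron_length = as.integer(intron_length),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

empty_variants <- function() {
  data.frame(transcript_id = character(0), codon_number = integer(0),
             wt_codon = character(0), var_codon = character(0),
             zygosity = character(0), phase = character(0),
             expected_category = character(0))
}

#' Build a fixture: reference, transcripts and truth set
#'
#' Generates, deterministically from `spec$seed`, a synthetic reference
#' whose transcripts carry the declared wild-type codons at the declared
#' codon positions, CDS filler codons free of premature stops, and a
#' downstream region whose first in-frame stop sits at the declared codon
#' distance. The truth set lists the component SNVs (VCF-style), the
#' expected merged MNV records and the expected naive/merged HGVS strings —
#' all derived from the declared codons, independently of the calling
#' pipeline.
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `mnv_fixture`: `spec`, `reference`
#'   (`DNAStringSet`), `transcripts`, `truth` (list with `snvs`, `mnvs`,
#'   `naive`).
#' @export
build_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  contig_parts <- list()
  transcripts <- list()
  for (lay in spec$transcripts) {
    vars <- spec$variants[spec$variants$transcript_id == lay$transcript_id, ,
                          drop = FALSE]
    codons <- c("ATG", rand_nonstop_codons(lay$n_codons - 2L), "TAA")
    for (i in seq_len(nrow(vars)))
      codons[vars$codon_number[i]] <- vars$wt_codon[i]
    cds <- paste(codons, collapse = "")
    ds <- if (is.na(lay$downstream_stop_codon)) {
      paste(rand_nonstop_codons(12L), collapse = "")
    } else {
      paste(c(rand_nonstop_codons(lay$downstream_stop_codon - 1L), "TAA",
              rand_nonstop_codons(lay$downstream_extra_codons)),
            collapse = "")
    }
    pieces <- substring(cds, cumsum(c(1L, lay$exon_lengths))[seq_along(lay$exon_lengths)],
                        cumsum(lay$exon_lengths))
    cur <- if (is.null(contig_parts[[lay$contig]])) {
      list(seq = rand_bases(spec$padding), len = spec$padding)
    } else contig_parts[[lay$contig]]
    append_seg <- function(s) {
      cur$seq <<- paste0(cur$seq, s)
      iv <- c(cur$len + 1L, cur$len + nchar(s))
      cur$len <<- cur$len + nchar(s)
      iv
    }
    n_ex <- length(pieces)
    ex_iv <- matrix(0L, n_ex, 2)
    if (lay$strand == "+") {
      for (i in seq_len(n_ex)) {
        if (i > 1) append_seg(rand_bases(spec$intron_length))
        ex_iv[i, ] <- append_seg(pieces[i])
      }
      append_seg(ds)
    } else {
      append_seg(revcomp(ds))
      for (i in rev(seq_len(n_ex))) {
        ex_iv[i, ] <- append_seg(revcomp(pieces[i]))
        if (i > 1) append_seg(rand_bases(spec$intron_length))
      }
    }
    append_seg(rand_bases(spec$padding))
    contig_parts[[lay$contig]] <- cur
    transcripts[[lay$transcript_id]] <-
      transcript(lay$transcript_id, lay$gene, lay$contig, lay$strand,
                 data.frame(start = ex_iv[, 1], end = ex_iv[, 2]), ds)
  }
  reference <- reference_sequence(
    stats::setNames(vapply(contig_parts, `[[`, "", "seq"),
                    names(contig_parts)))
  # safety: declared wild-type codons must be present in the built reference
  for (i in seq_len(nrow(spec$variants))) {
    v <- spec$variants[i, ]
    got <- codon_sequence(transcripts[[v$transcript_id]], reference,
                          v$codon_number)
    if (got != v$wt_codon)
      stop("internal fixture error: generated codon ", got,
           " != declared wild type ", v$wt_codon)
  }
  truth <- fixture_truth(spec, transcripts, reference)
  structure(list(spec = spec, reference = reference,
                 transcripts = unname(transcripts), truth = truth),
            class = "mnv_fixture")
}

# Truth set derived from the declared codons (not from the calling path).
fixture_truth <- function(spec, transcripts, reference) {
  snvs <- list(); mnvs <- list(); naive <- list()
  for (i in seq_len(nrow(spec$variants))) {
    v <- spec$variants[i, ]
    tx <- transcripts[[v$transcript_id]]
    wt <- strsplit(v$wt_codon, "")[[1]]
    vr <- strsplit(v$var_codon, "")[[1]]
    offs <- which(wt != vr)
    cpos <- (v$codon_number - 1L) * 3L + offs
    gpos <- cds_to_genomic(tx, cpos)
    gref <- wt[offs]; galt <- vr[offs]
    if (tx$strand == "-") {
      gref <- vapply(gref, revcomp, character(1))
      galt <- vapply(galt, revcomp, character(1))
    }
    zyg <- if (v$zygosity == "hom") "hom_alt" else "het"
    ord <- order(gpos)
    snvs[[i]] <- data.frame(
      contig = tx$contig, pos = gpos[ord], ref = gref[ord], alt = galt[ord],
      genotype = zyg, variant_id = i, transcript_id = v$transcript_id,
      phase = v$phase, member_index = seq_along(offs),
      c_position = cpos[ord])
    # expected merged record + HGVS
    start <- min(gpos); end <- max(gpos)
    ref_allele <- ref_bases(reference, tx$contig, start, end)
    alt_allele <- ref_allele
    for (k in seq_along(gpos)) {
      o <- gpos[k] - start + 1L
      substr(alt_allele, o, o) <- galt[k]
    }
    ref_aa <- translate_codon(v$wt_codon)
    alt_aa <- translate_codon(v$var_codon)
    eff <- codon_effect(ref_aa, alt_aa, v$codon_number)
    ext <- if (eff == "stop_lost") stop_extension_length(tx$downstream_seq)
           else NA_integer_
    merged_p <- paste0("p.", p_descriptor(v$codon_number, ref_aa, alt_aa,
                                          eff, ext, !is.na(ext)))
    merged_c <- if (length(offs) >= 2)
      sprintf("c.%d_%ddelins%s", min(cpos), max(cpos),
              substr(v$var_codon, min(offs), max(offs)))
    else sprintf("c.%d%s>%s", cpos, wt[offs], vr[offs])
    mnvs[[i]] <- data.frame(
      variant_id = i, transcript_id = v$transcript_id, gene = tx$gene,
      contig = tx$contig, start = start, end = end,
      ref_allele = ref_allele, alt_allele = alt_allele, genotype = zyg,
      is_mnv = length(offs) >= 2, phase = v$phase,
      hgvs_c = merged_c, hgvs_p = merged_p, effect = eff,
      extension_length = ext,
      expected_category = v$expected_category)
    # expected naive per-SNV annotations
    naive[[i]] <- do.call(rbind, lapply(seq_along(offs), function(k) {
      ncod <- wt; ncod[offs[k]] <- vr[offs[k]]
      naa <- translate_codon(paste(ncod, collapse = ""))
      neff <- codon_effect(ref_aa, naa, v$codon_number)
      next_ext <- if (neff == "stop_lost")
        stop_extension_length(tx$downstream_seq) else NA_integer_
      data.frame(variant_id = i, member_index = k,
                 c_position = cpos[k],
                 hgvs_c = sprintf("c.%d%s>%s", cpos[k], wt[offs[k]],
                                  vr[offs[k]]),
                 hgvs_p = paste0("p.", p_descriptor(v$codon_number, ref_aa,
                                                    naa, neff, next_ext,
                                                    !is.na(next_ext))),
                 effect = neff)
    }))
  }
  snv_df <- if (length(snvs)) do.call(rbind, snvs) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               genotype = character(0), variant_id = integer(0),
               transcript_id = character(0), phase = character(0),
               member_index = integer(0), c_position = integer(0))
  snv_df <- snv_df[order(snv_df$contig, snv_df$pos), , drop = FALSE]
  rownames(snv_df) <- NULL
  list(snvs = snv_df,
       mnvs = if (length(mnvs)) do.call(rbind, mnvs) else NULL,
       naive = if (length(naive)) do.call(rbind, naive) else NULL)
}

# Effect of one codon substitution (ref/alt residues in 3-letter code).
codon_effect <- function(ref_aa, alt_aa, codon_number) {
  if (ref_aa == "*" && alt_aa == "*") "stop_retained"
  else if (ref_aa == "*") "stop_lost"
  else if (alt_aa == "*") "stop_gained"
  else if (codon_number == 1L && ref_aa == "Met" && alt_aa != "Met") "start_lost"
  else if (ref_aa == alt_aa) "synonymous"
  else "missense"
}

#' @export
print.mnv_fixture <- function(x, ...) {
  cat(sprintf("<MNV fixture: %d contig(s), %d transcript(s), %d planted variant(s), seed %d>\n",
              length(x$reference), length(x$transcripts),
              nrow(x$spec$variants), x$spec$seed))
  invisible(x)
}

#' Simulate aligned reads over a fixture
#'
#' Emits pre-aligned single-end reads (all-match CIGAR, MAPQ 60) drawn
#' uniformly over each contig from two haplotype sequences: homozygous
#' variants appear on both haplotypes (so on every overlapping read);
#' heterozygous cis variants place all member alternate bases on haplotype
#' 2; heterozygous trans variants alternate members between the two
#' haplotypes. Templates are assigned a haplotype at random (about 50/50).
#' Per-base errors are injected at `error_rate` (default 0: error-free, so
#' truth is exact). With a fixed seed the emitted BAM is byte-identical
#' across runs.
#'
#' @param fixture An `mnv_fixture`.
#' @param bam Output BAM path (a `.bai` index is written alongside).
#' @param seed RNG seed (default: the fixture seed).
#' @return Invisibly, a list with `bam`, `n_templates`, `site_truth`
#'   (data.frame of per-site simulated allele depths) and `templates`
#'   (data.frame of per-template span and haplotype assignment — the
#'   simulator's internal truth).
#' @export
simulate_reads <- function(fixture, bam, seed = fixture$spec$seed) {
  spec <- fixture$spec
  if (spec$coverage <= 0)
    stop("coverage must be positive: no alignments would be generated")
  snvs <- fixture$truth$snvs
  if (nrow(fixture$truth$snvs) > 0 && !is.null(fixture$truth$mnvs)) {
    span <- max(fixture$truth$mnvs$end - fixture$truth$mnvs$start + 1L)
    if (spec$read_length <= span + 4L)
      stop("read length must exceed the MNV span plus flanking margin")
  }
  set.seed(seed)
  haps <- list()
  for (ctg in names(fixture$reference)) {
    base <- as.character(fixture$reference[[ctg]])
    h1 <- base; h2 <- base
    sub <- snvs[snvs$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      p <- sub$pos[i]; a <- sub$alt[i]
      if (sub$genotype[i] == "hom_alt") {
        substr(h1, p, p) <- a; substr(h2, p, p) <- a
      } else if (sub$phase[i] == "cis") {
        substr(h2, p, p) <- a
      } else {                                  # trans: split members
        if (sub$member_index[i] %% 2L == 1L) substr(h2, p, p) <- a
        else substr(h1, p, p) <- a
      }
    }
    haps[[ctg]] <- c(h1, h2)
  }
  rl <- spec$read_length
  sam <- c("@HD\tVN:1.6\tSO:unsorted",
           vapply(names(fixture$reference), function(ctg)
             sprintf("@SQ\tSN:%s\tLN:%d", ctg,
                     length(fixture$reference[[ctg]])),
             character(1)))
  qual <- paste(rep("I", rl), collapse = "")
  n_total <- 0L
  site_rows <- list()
  template_rows <- list()
  for (ctg in names(fixture$reference)) {
    len <- length(fixture$reference[[ctg]])
    if (len < rl) stop("contig ", ctg, " shorter than the read length")
    n <- max(1L, as.integer(round(len * spec$coverage / rl)))
    starts <- sample.int(len - rl + 1L, n, replace = TRUE)
    hap <- sample.int(2L, n, replace = TRUE)
    o <- order(starts)
    starts <- starts[o]; hap <- hap[o]
    seqs <- vapply(seq_len(n), function(i)
      substr(haps[[ctg]][hap[i]], starts[i], starts[i] + rl - 1L),
      character(1))
    if (spec$error_rate > 0) {
      for (i in seq_len(n)) {
        hits <- which(stats::runif(rl) < spec$error_rate)
        for (p in hits) {
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1L)
        }
      }
    }
    sam <- c(sam, vapply(seq_len(n), function(i)
      paste(sprintf("%s_t%06d", ctg, n_total + i), 0L, ctg, starts[i], 60L,
            paste0(rl, "M"), "*", 0L, 0L, seqs[i], qual, sep = "\t"),
      character(1)))
    template_rows[[length(template_rows) + 1L]] <- data.frame(
      qname = sprintf("%s_t%06d", ctg, n_total + seq_len(n)), contig = ctg,
      start = starts, end = starts + rl - 1L, hap = hap)
    n_total <- n_total + n
    # per-site simulated allele depths (simulator's internal truth)
    sub <- snvs[snvs$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      p <- sub$pos[i]
      cov <- which(starts <= p & starts + rl - 1L >= p)
      bases <- vapply(cov, function(j) substr(seqs[j], p - starts[j] + 1L,
                                              p - starts[j] + 1L),
                      character(1))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        contig = ctg, pos = p, ref = sub$ref[i], alt = sub$alt[i],
        n_total = length(cov), n_alt = sum(bases == sub$alt[i]),
        n_ref = sum(bases == sub$ref[i]))
    }
  }
  samfile <- tempfile(fileext = ".sam")
  on.exit(unlink(samfile), add = TRUE)
  writeLines(sam, samfile)
  tmpbam <- Rsamtools::asBam(samfile, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  on.exit(unlink(tmpbam), add = TRUE)
  Rsamtools::sortBam(tmpbam, sub("\\.bam$", "", bam))
  Rsamtools::indexBam(bam)
  invisible(list(bam = bam, n_templates = n_total,
                 site_truth = if (length(site_rows))
                   do.call(rbind, site_rows) else NULL,
                 templates = do.call(rbind, template_rows)))
}

#' Materialize a fixture bundle on disk
#'
#' Writes `ref.fa` (+ `.fai`), `transcripts.tsv`, `calls.vcf` (the
#' component SNVs as a variant caller would emit them), `truth_mnvs.tsv`
#' (expected merged records) and, when `reads = TRUE`, `reads.bam` (+
#' `.bai`).
#'
#' @param fixture An `mnv_fixture`.
#' @param dir Output directory (created if needed).
#' @param reads Simulate and write the BAM (default TRUE).
#' @return List of file paths.
#' @export
materialize_fixture <- function(fixture, dir, reads = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(dir, "ref.fa"),
    transcripts = file.path(dir, "transcripts.tsv"),
    vcf = file.path(dir, "calls.vcf"),
    truth = file.path(dir, "truth_mnvs.tsv"),
    bam = if (reads) file.path(dir, "reads.bam") else NULL)
  Biostrings::writeXStringSet(fixture$reference, paths$reference)
  Rsamtools::indexFa(paths$reference)
  write_transcripts_tsv(fixture$transcripts, paths$transcripts)
  calls <- fixture$truth$snvs
  lens <- stats::setNames(Biostrings::width(fixture$reference),
                          names(fixture$reference))
  write_snv_vcf(snv_calls(calls$contig, calls$pos, calls$ref, calls$alt,
                          ifelse(calls$genotype == "hom_alt", "hom_alt",
                                 "het")),
                paths$vcf, contig_lengths = lens)
  if (!is.null(fixture$truth$mnvs))
    utils::write.table(fixture$truth$mnvs, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  else writeLines(paste(c("variant_id", "hgvs_c", "hgvs_p"), collapse = "\t"),
                  paths$truth)
  if (reads) simulate_reads(fixture, paths$bam)
  paths
}

#' Fixture emulating the five simulated homozygous MNVs
#'
#' Two plus-strand transcripts on one synthetic contig: a 444-codon
#' HNF4A-like transcript carrying CTG>TTC at codon 280 (c.838_840), TCC>AGC
#' at codon 356 (edits at c.1066_1067), TCT>TGA at codon 421 (edits at
#' c.1262_1263) and AAG>AGT at codon 425 (edits at c.1274_1275); and a
#' 396-codon isoform whose stop codon mutates TAA>TGG (c.1186_1188), with a
#' synthetic downstream region whose first in-frame stop lies 26 codons
#' after the original stop. All five variants are homozygous, mirroring a
#' GT 1/1 call with no reads supporting the reference allele. The
#' `expected_category` column records the expected diagnostic-risk call for
#' each variant.
#'
#' @param seed RNG seed (default 1).
#' @return An `mnv_fixture`.
#' @export
simulated_mnv_fixture <- function(seed = 1L) {
  txs <- list(
    transcript_layout("SYNTX-175914", "HNF4A", "chr20sim", "+", 444L,
                      exon_lengths = c(898L, 301L, 133L),
                      downstream_stop_codon = 10L),
    transcript_layout("SYNTX-1030004", "HNF4A", "chr20sim", "+", 396L,
                      exon_lengths = c(600L, 588L),
                      downstream_stop_codon = 26L))
  vars <- data.frame(
    transcript_id = c("SYNTX-175914", "SYNTX-1030004", "SYNTX-175914",
                      "SYNTX-175914", "SYNTX-175914"),
    codon_number = c(280L, 396L, 356L, 421L, 425L),
    wt_codon = c("CTG", "TAA", "TCC", "TCT", "AAG"),
    var_codon = c("TTC", "TGG", "AGC", "TGA", "AGT"),
    zygosity = "hom", phase = "cis",
    expected_category = c("false_negative_risk", "false_negative_risk",
                          "false_positive_risk", "false_negative_risk",
                          "changed_effect"))
  build_fixture(fixture_spec(txs, vars, seed = seed))
}

#' Fixture emulating the four clinical heterozygous MNVs
#'
#' Four cis heterozygous codon changes across three synthetic genes:
#' GCC>TTC at codon 752 (INSR-like, plus strand), GAT>TCT at codon 615
#' (EIF2AK3-like, plus strand), and GAG>AGG at codon 421 plus TAC>CAA at
#' codon 61 on a minus-strand GCK-like transcript.
#'
#' @param seed RNG seed (default 1).
#' @return An `mnv_fixture`.
#' @export
clinical_mnv_fixture <- function(seed = 1L) {
  txs <- list(
    transcript_layout("SYNTX-INSR", "INSR", "chr19sim", "+", 770L,
                      exon_lengths = c(1800L, 510L)),
    transcript_layout("SYNTX-EIF2AK3", "EIF2AK3", "chr2sim", "+", 630L,
                      exon_lengths = c(1200L, 690L)),
    transcript_layout("SYNTX-GCK", "GCK", "chr7sim", "-", 466L,
                      exon_lengths = c(700L, 698L)))
  vars <- data.frame(
    transcript_id = c("SYNTX-INSR", "SYNTX-EIF2AK3", "SYNTX-GCK",
                      "SYNTX-GCK"),
    codon_number = c(752L, 615L, 421L, 61L),
    wt_codon = c("GCC", "GAT", "GAG", "TAC"),
    var_codon = c("TTC", "TCT", "AGG", "CAA"),
    zygosity = "het", phase = "cis",
    expected_category = NA_character_)
  build_fixture(fixture_spec(txs, vars, seed = seed))
}

#' Pure wild-type fixture (no planted variants)
#'
#' @param seed RNG seed (default 1).
#' @return An `mnv_fixture`.
#' @export
wildtype_fixture <- function(seed = 1L) {
  txs <- list(transcript_layout("SYNTX-WT", "WTGENE", "chrWsim", "+", 300L,
                                exon_lengths = c(600L, 300L)))
  build_fixture(fixture_spec(txs, seed = seed))
}

#' Fixture planting a heterozygous trans pair
#'
#' The two member substitutions of the planted codon change lie on opposite
#' haplotypes, so a read-backed phaser must refuse to merge them.
#'
#' @param seed RNG seed (default 1).
#' @return An `mnv_fixture`.
#' @export
trans_fixture <- function(seed = 1L) {
  txs <- list(transcript_layout("SYNTX-TRANS", "TRGENE", "chrTsim", "+", 300L,
                                exon_lengths = 900L))
  vars <- data.frame(transcript_id = "SYNTX-TRANS", codon_number = 100L,
                     wt_codon = "CTG", var_codon = "TTC", zygosity = "het",
                     phase = "trans", expected_category = NA_character_)
  build_fixture(fixture_spec(txs, vars, seed = seed))
}

#' Random planted-MNV fixture
#'
#' Draws a random transcript layout (random strand, 150-300 codons, two
#' exons) and plants `n_variants` random intra-codon MNVs (two or three
#' changed bases per codon, random zygosity, cis phase) at well-separated
#' codons. Used for multi-seed recovery experiments.
#'
#' @param seed RNG seed.
#' @param n_variants Number of planted MNVs (default 3).
#' @return An `mnv_fixture`.
#' @export
random_fixture <- function(seed, n_variants = 3L) {
  set.seed(seed)
  n_codons <- sample(150:300, 1L)
  cut <- sample(seq(30L, n_codons - 30L), 1L) * 3L
  strand <- sample(c("+", "-"), 1L)
  cands <- seq(5L, n_codons - 5L)
  codons <- sort(sample(cands, n_variants))
  while (n_variants > 1 && min(diff(codons)) < 4L)
    codons <- sort(sample(cands, n_variants))
  wt <- rand_nonstop_codons(n_variants)
  var <- vapply(wt, function(w) {
    offs <- sort(sample(1:3, sample(2:3, 1L)))
    v <- strsplit(w, "")[[1]]
    for (o in offs) v[o] <- sample(setdiff(BASES, v[o]), 1L)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  vars <- data.frame(transcript_id = "SYNTX-RAND", codon_number = codons,
                     wt_codon = wt, var_codon = var,
                     zygosity = sample(c("hom", "het"), n_variants,
                                       replace = TRUE),
                     phase = "cis", expected_category = NA_character_)
  txs <- list(transcript_layout("SYNTX-RAND", "RANDGENE", "chrRsim", strand,
                                n_codons,
                                exon_lengths = c(cut, n_codons * 3L - cut)))
  build_fixture(fixture_spec(txs, vars, seed = seed))
}
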