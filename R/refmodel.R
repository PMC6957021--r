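#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom IRanges IRanges
NULL

# Amino-acid one-letter -> three-letter display names; "*" is the stop symbol.
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "*"
)

#' Validate a reference sequence set
#'
#' A reference is represented as a named [Biostrings::DNAStringSet], one
#' element per contig, restricted to the alphabet A/C/G/T/N. All positions
#' are 1-based inclusive, matching VCF and HGVS conventions.
#'
#' @param x A named character vector or `DNAStringSet` of contig sequences.
#' @return A validated `DNAStringSet` (uppercase).
#' @export
reference_sequence <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (!methods::is(x, "DNAStringSet"))
    stop("reference must be a DNAStringSet or named character vector")
  if (length(x) == 0 || is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("reference contigs must be named")
  if (any(Biostrings::width(x) == 0)) stop("reference contigs must be non-empty")
  counts <- Biostrings::alphabetFrequency(x)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(counts[, !colnames(counts) %in% allowed, drop = FALSE])
  if (any(bad > 0))
    stop("reference alphabet restricted to A/C/G/T/N; offending contig: ",
         names(x)[which(bad > 0)[1]])
  x
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A validated `DNAStringSet`, names truncated at the first whitespace.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  reference_sequence(x)
}

#' Extract reference bases
#'
#' @param reference A `DNAStringSet` as returned by [reference_sequence()].
#' @param contig Contig name.
#' @param start,end 1-based inclusive genomic positions.
#' @return Character string of bases.
#' @export
ref_bases <- function(reference, contig, start, end = start) {
  if (!contig %in% names(reference))
    stop("contig '", contig, "' not present in reference")
  len <- length(reference[[contig]])
  if (start < 1 || end > len || start > end)
    stop("position range ", start, "-", end, " outside contig '", contig,
         "' [1, ", len, "]")
  as.character(Biostrings::subseq(reference[[contig]], start, end))
}

#' Construct a transcript model
#'
#' A strand-aware CDS exon model mapping genomic to coding coordinates.
#' All coordinates are 1-based inclusive (VCF/HGVS convention). `exons` are
#' the CDS portions only (no UTR), given in ascending genomic order; for
#' minus-strand transcripts the coding sequence is read from the genomically
#' last exon backwards and reverse-complemented.
#'
#' @param transcript_id Transcript identifier.
#' @param gene Gene symbol.
#' @param contig Contig name the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end` (1-based
#'   inclusive genomic CDS intervals, ascending, non-overlapping).
#' @param downstream_seq DNA string (coding orientation) beyond the stop
#'   codon (3' UTR and beyond), possibly empty; used to locate the next
#'   in-frame stop after a stop-loss variant.
#' @return An object of class `mnv_transcript`.
#' @export
transcript <- function(transcript_id, gene, contig, strand, exons,
                       downstream_seq = "") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0) stop("transcript needs at least one CDS exon")
  if (any(exons$end < exons$start)) stop("exon end < start")
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("CDS exons overlap")
  cds_len <- sum(exons$end - exons$start + 1L)
  if (cds_len %% 3L != 0L)
    stop("total CDS length (", cds_len, ") not divisible by 3")
  downstream_seq <- toupper(downstream_seq)
  if (nchar(downstream_seq) > 0 &&
      grepl("[^ACGTN]", downstream_seq))
    stop("downstream sequence alphabet restricted to A/C/G/T/N")
  structure(
    list(transcript_id = transcript_id, gene = gene, contig = contig,
         strand = strand, exons = exons, cds_length = cds_len,
         downstream_seq = downstream_seq),
    class = "mnv_transcript")
}

#' @export
print.mnv_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s strand %s, CDS %d nt, %d exon(s)>\n",
              x$transcript_id, x$gene, x$contig,
              paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand, x$cds_length, nrow(x$exons)))
  invisible(x)
}

# Exons in transcript (5'->3') order.
tx_ordered_exons <- function(tx) {
  if (tx$strand == "+") tx$exons else tx$exons[rev(seq_len(nrow(tx$exons))), , drop = FALSE]
}

#' Map a genomic position to a coding (c.) coordinate
#'
#' 1-based throughout. For minus-strand transcripts the coding coordinate
#' counts from the 3'-most genomic base of the CDS.
#'
#' @param tx An `mnv_transcript`.
#' @param position 1-based genomic position(s) within a CDS exon.
#' @return data.frame with columns `c_position`, `codon_number`,
#'   `codon_offset` (one row per input position).
#' @export
genomic_to_cds <- function(tx, position) {
  position <- as.integer(position)
  ex <- tx_ordered_exons(tx)
  widths <- ex$end - ex$start + 1L
  before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  cpos <- vapply(position, function(p) {
    i <- which(p >= ex$start & p <= ex$end)
    if (length(i) != 1)
      stop("position ", tx$contig, ":", p, " is not in the CDS of transcript ",
           tx$transcript_id)
    if (tx$strand == "+") before[i] + (p - ex$start[i] + 1L)
    else before[i] + (ex$end[i] - p + 1L)
  }, integer(1))
  cbind(data.frame(c_position = cpos), cds_to_codon(cpos))
}

#' Map a coding (c.) position to its genomic position
#'
#' Inverse of [genomic_to_cds()].
#'
#' @param tx An `mnv_transcript`.
#' @param c_position 1-based coding position(s) in `[1, cds_length]`.
#' @return Integer vector of genomic positions.
#' @export
cds_to_genomic <- function(tx, c_position) {
  c_position <- as.integer(c_position)
  if (any(c_position < 1 | c_position > tx$cds_length))
    stop("c. position outside CDS [1, ", tx$cds_length, "] of ",
         tx$transcript_id)
  ex <- tx_ordered_exons(tx)
  widths <- ex$end - ex$start + 1L
  before <- c(0L, cumsum(widths))[seq_len(nrow(ex))]
  vapply(c_position, function(cp) {
    i <- max(which(cp > before))
    off <- cp - before[i]
    if (tx$strand == "+") ex$start[i] + off - 1L else ex$end[i] - off + 1L
  }, integer(1))
}

#' Codon number and offset for a coding position
#'
#' @param c_position 1-based coding position(s) (>= 1).
#' @return data.frame with `codon_number` (ceiling(c/3)) and `codon_offset`
#'   (1, 2 or 3 within the codon).
#' @export
cds_to_codon <- function(c_position) {
  c_position <- as.integer(c_position)
  if (any(is.na(c_position)) || any(c_position < 1))
    stop("c. position must be >= 1")
  data.frame(codon_number = (c_position - 1L) %/% 3L + 1L,
             codon_offset = (c_position - 1L) %% 3L + 1L)
}

#' Full coding sequence of a transcript
#'
#' Concatenates CDS exon sequences in transcript order; reverse-complemented
#' for minus-strand transcripts.
#'
#' @param tx An `mnv_transcript`.
#' @param reference A `DNAStringSet`.
#' @return Character string of length `tx$cds_length`.
#' @export
coding_sequence <- function(tx, reference) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    ref_bases(reference, tx$contig, tx$exons$start[i], tx$exons$end[i]),
    character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param s DNA character string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Codon sequence at a codon number
#'
#' Returns the codon in coding orientation; codons spanning exon junctions
#' are assembled by concatenating CDS bases in transcript order.
#'
#' @param tx An `mnv_transcript`.
#' @param reference A `DNAStringSet`.
#' @param codon_number 1-based codon index within the CDS.
#' @return 3-base character string.
#' @export
codon_sequence <- function(tx, reference, codon_number) {
  codon_number <- as.integer(codon_number)
  n_codons <- tx$cds_length %/% 3L
  if (codon_number < 1 || codon_number > n_codons)
    stop("codon ", codon_number, " outside CDS (1..", n_codons, ") of ",
         tx$transcript_id)
  cpos <- (codon_number - 1L) * 3L + 1:3
  g <- cds_to_genomic(tx, cpos)
  bases <- vapply(g, function(p) ref_bases(reference, tx$contig, p), character(1))
  if (tx$strand == "-") bases <- vapply(bases, function(b) revcomp(b), character(1))
  paste(bases, collapse = "")
}

#' Translate a single codon
#'
#' Standard genetic code (translation table 1) via
#' [Biostrings::GENETIC_CODE]; stop codons return `"*"`.
#'
#' @param codon 3-base string over A/C/G/T.
#' @return Three-letter amino-acid code, or `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon))
    stop("cannot translate codon '", codon,
         "': must be 3 unambiguous bases (A/C/G/T)")
  unname(AA_THREE[Biostrings::GENETIC_CODE[[codon]]])
}

#' Translate a coding sequence to residues
#'
#' @param cds In-frame DNA string (length divisible by 3).
#' @return Character vector of three-letter residues (stop = `"*"`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("sequence length not divisible by 3")
  starts <- seq(1, nchar(cds), by = 3)
  vapply(starts, function(i) translate_codon(substr(cds, i, i + 2)), character(1))
}
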