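# Transcript model input: GFF3 (CDS features grouped per transcript) for
# realism, or a flat TSV for trivially auditable fixtures. Both parse to the
# same mnv_transcript type.

#' Read transcript models from a tab-separated config
#'
#' Columns (tab-separated, with header):
#' \describe{
#'   \item{transcript_id}{identifier}
#'   \item{gene}{gene symbol}
#'   \item{contig}{contig name}
#'   \item{strand}{`+` or `-`}
#'   \item{exons}{CDS exon intervals as `start-end` pairs joined by `,`,
#'     1-based inclusive, ascending genomic order}
#'   \item{downstream}{optional: DNA beyond the stop codon, coding
#'     orientation; may be empty or the column absent}
#' }
#'
#' @param path Path to the TSV file.
#' @return List of `mnv_transcript` objects.
#' @export
read_transcripts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("transcript_id", "gene", "contig", "strand", "exons")
  if (!all(need %in% names(df)))
    stop("transcript TSV must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    spans <- strsplit(df$exons[i], ",", fixed = TRUE)[[1]]
    m <- regmatches(spans, regexec("^(\\d+)-(\\d+)$", spans))
    if (any(lengths(m) != 3))
      stop("malformed exon list '", df$exons[i], "' in ", path)
    ex <- data.frame(start = as.integer(vapply(m, `[`, "", 2)),
                     end = as.integer(vapply(m, `[`, "", 3)))
    ds <- if ("downstream" %in% names(df) && !is.na(df$downstream[i]))
      df$downstream[i] else ""
    transcript(df$transcript_id[i], df$gene[i], df$contig[i], df$strand[i],
               ex, ds)
  })
}

#' Write transcript models to the TSV config format
#'
#' @param transcripts List of `mnv_transcript` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  df <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(transcript_id = tx$transcript_id, gene = tx$gene,
               contig = tx$contig, strand = tx$strand,
               exons = paste(paste0(tx$exons$start, "-", tx$exons$end),
                             collapse = ","),
               downstream = tx$downstream_seq)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' CDS features are grouped by their `Parent` (or `transcript_id`) attribute;
#' gene symbols are taken from a `gene` (or `gene_id`) attribute when
#' present. GFF3 carries no sequence, so downstream (post-stop) sequence can
#' be supplied separately per transcript.
#'
#' @param path Path to a GFF3 file.
#' @param downstream Optional named character vector of post-stop DNA
#'   (coding orientation), named by transcript id.
#' @return List of `mnv_transcript` objects.
#' @export
read_transcripts_gff3 <- function(path, downstream = character()) {
  gff <- rtracklayer::readGFF(path)
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop("no CDS features in ", path)
  grp <- if ("Parent" %in% names(cds) && any(lengths(cds$Parent) > 0)) {
    vapply(cds$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else if ("transcript_id" %in% names(cds)) {
    as.character(cds$transcript_id)
  } else stop("CDS features need a Parent or transcript_id attribute")
  if (anyNA(grp)) stop("CDS feature without transcript grouping attribute")
  lapply(split(seq_len(nrow(cds)), grp), function(idx) {
    sub <- cds[idx, , drop = FALSE]
    strand <- unique(as.character(sub$strand))
    contig <- unique(as.character(sub$seqid))
    if (length(strand) != 1 || length(contig) != 1)
      stop("inconsistent strand/contig for transcript ", grp[idx[1]])
    gene <- NA_character_
    for (col in c("gene", "gene_id", "gene_name"))
      if (col %in% names(sub) && !all(is.na(sub[[col]]))) {
        gene <- as.character(sub[[col]][!is.na(sub[[col]])][1]); break
      }
    tid <- sub("^transcript:", "", grp[idx[1]])
    ds <- if (tid %in% names(downstream)) downstream[[tid]] else ""
    transcript(tid, gene, contig, strand,
               data.frame(start = sub$start, end = sub$end), ds)
  })
}

#' Write transcript models as GFF3
#'
#' Emits one `mRNA` feature plus its `CDS` children per transcript. The
#' downstream (post-stop) sequence has no GFF3 representation and is not
#' written; use the TSV format to round-trip it.
#'
#' @param transcripts List of `mnv_transcript` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  lines <- c("##gff-version 3")
  for (tx in transcripts) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    lines <- c(lines,
      paste(tx$contig, "mnvrescue", "mRNA", span[1], span[2], ".", tx$strand,
            ".", sprintf("ID=%s;gene=%s", tx$transcript_id, tx$gene),
            sep = "\t"),
      vapply(seq_len(nrow(tx$exons)), function(i)
        paste(tx$contig, "mnvrescue", "CDS", tx$exons$start[i],
              tx$exons$end[i], ".", tx$strand, ".",
              sprintf("ID=%s.cds%d;Parent=%s;gene=%s", tx$transcript_id, i,
                      tx$transcript_id, tx$gene), sep = "\t"),
        character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read transcripts from either supported format
#'
#' Dispatches on file extension: `.gff`/`.gff3` to [read_transcripts_gff3()],
#' anything else to [read_transcripts_tsv()].
#'
#' @param path Path to a transcript model file.
#' @return List of `mnv_transcript` objects.
#' @export
read_transcripts <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    read_transcripts_gff3(path)
  else read_transcripts_tsv(path)
}
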