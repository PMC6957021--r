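# VCF 4.2 input/output via VariantAnnotation. Emitted merged records carry
# their provenance in three INFO keys (documented in the emitted header):
#   MNV_MEMBERS  - component SNVs as pos:REF>ALT joined by "|"
#   MNV_PHASE    - phase status of the merged cluster
#   MNV_EVIDENCE - per-adjacent-pair template counts
#                  both_alt,alt_ref,ref_alt,both_ref,other joined by "|"

MNV_INFO_HEADER <- S4Vectors::DataFrame(
  Number = c("1", "1", "1"),
  Type = c("String", "String", "String"),
  Description = c(
    "Component SNVs of the merged MNV as pos:REF>ALT joined by |",
    "Phase status of the merged cluster",
    "Spanning-template counts per adjacent pair (both_alt,alt_ref,ref_alt,both_ref,other) joined by |"),
  row.names = c("MNV_MEMBERS", "MNV_PHASE", "MNV_EVIDENCE"))

#' Read biallelic SNV calls from a VCF
#'
#' Extracts single-sample genotype calls with single-base REF and a single
#' single-base ALT and a called non-reference genotype. Everything else
#' (indels, multiallelic sites, reference/uncalled genotypes) is ignored
#' here and passed through untouched by [emit_vcf()].
#'
#' @param path Path to a VCF 4.x file.
#' @param sample Sample index or name (default first sample).
#' @return An `snv_calls` data.frame (possibly empty).
#' @export
read_snv_calls <- function(path, sample = 1L) {
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0)
    return(snv_calls(character(0), integer(0), character(0), character(0),
                     character(0)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, nrow(vcf))
  alt1[n_alt == 1] <- vapply(which(n_alt == 1),
                             function(i) as.character(altl[[i]][1]),
                             character(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path)
  gt <- gt[, sample]
  geno <- rep(NA_character_, nrow(vcf))
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  geno[gt %in% c("1/1", "1|1", "1")] <- "hom_alt"
  keep <- !is.na(alt1) & nchar(ref) == 1 & nchar(alt1) == 1 &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    !is.na(geno)
  if (!any(keep))
    return(snv_calls(character(0), integer(0), character(0), character(0),
                     character(0)))
  snv_calls(contig = as.character(GenomicRanges::seqnames(rr))[keep],
            pos = GenomicRanges::start(rr)[keep],
            ref = ref[keep], alt = alt1[keep], genotype = geno[keep],
            source_id = rownames(vcf)[keep])
}

# Build a single-sample CollapsedVCF from a plain record table.
# records: data.frame(contig, pos, id, ref, alt, qual, filter, gt) plus
# optional info columns given in `info` (a DataFrame, may have zero columns).
build_vcf_object <- function(records, sample_name = "SAMPLE",
                             info = NULL, info_header = NULL,
                             contig_lengths = NULL) {
  n <- nrow(records)
  ids <- if ("id" %in% names(records) && !anyNA(records$id)) records$id
    else sprintf("%s:%s_%s/%s", records$contig, records$pos, records$ref,
                 records$alt)
  gr <- GenomicRanges::GRanges(
    records$contig,
    IRanges::IRanges(records$pos, records$pos + nchar(records$ref) - 1L))
  names(gr) <- ids
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- contig_lengths
  }
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(records$ref),
    ALT = do.call(Biostrings::DNAStringSetList,
                  strsplit(records$alt, ",", fixed = TRUE)),
    QUAL = if ("qual" %in% names(records)) as.numeric(records$qual)
           else rep(NA_real_, n),
    FILTER = if ("filter" %in% names(records)) records$filter
             else rep("PASS", n))
  if (is.null(info)) info <- S4Vectors::DataFrame(matrix(nrow = n, ncol = 0))
  rownames(info) <- ids
  geno <- S4Vectors::SimpleList(
    GT = matrix(records$gt, ncol = 1, dimnames = list(ids, sample_name)))
  hdr <- VariantAnnotation::VCFHeader(samples = sample_name)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  if (!is.null(info_header)) VariantAnnotation::info(hdr) <- info_header
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr, fixed = fixed, info = info, geno = geno,
    colData = S4Vectors::DataFrame(Samples = 1, row.names = sample_name),
    collapsed = TRUE)
  metadata(vcf)$header <- hdr
  vcf
}

gt_string <- function(genotype) ifelse(genotype == "hom_alt", "1/1", "0/1")

#' Emit a merged VCF
#'
#' Replaces the component SNV records of each merged MNV by one delins
#' record (REF/ALT are the equal-length span alleles); all untouched records
#' pass through with their original fixed fields, INFO and genotypes, and
#' the output is coordinate-sorted. Merged records carry `MNV_MEMBERS`,
#' `MNV_PHASE` and `MNV_EVIDENCE` INFO fields (header lines added).
#'
#' @param input Path to the original VCF.
#' @param merged List of `mnv_record` objects derived from records present
#'   in `input`.
#' @param output Path for the merged VCF.
#' @param sample Sample index or name used for the merged genotypes.
#' @return `output`, invisibly.
#' @export
emit_vcf <- function(input, merged, output, sample = 1L) {
  vcf <- VariantAnnotation::readVcf(input)
  keys <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(vcf)),
                  GenomicRanges::start(vcf))
  member_keys <- unlist(lapply(merged, function(r)
    paste0(r$contig, ":", r$members$pos)))
  if (length(member_keys) && !all(member_keys %in% keys))
    stop("merged record members absent from input VCF: ",
         paste(setdiff(member_keys, keys), collapse = ", "))
  drop <- keys %in% member_keys
  passthrough <- vcf[!drop, ]

  hdr <- VariantAnnotation::header(vcf)
  old_info_hdr <- VariantAnnotation::info(hdr)
  new_info_hdr <- rbind(old_info_hdr,
                        MNV_INFO_HEADER[!rownames(MNV_INFO_HEADER) %in%
                                          rownames(old_info_hdr), ,
                                        drop = FALSE])
  VariantAnnotation::info(hdr) <- new_info_hdr

  # passthrough part as plain tables
  rr <- SummarizedExperiment::rowRanges(passthrough)
  n_pass <- length(rr)
  alt_strings <- vapply(seq_len(n_pass), function(i)
    paste(as.character(rr$ALT[[i]]), collapse = ","), character(1))
  samples <- colnames(VariantAnnotation::geno(vcf)$GT)
  sample_name <- if (is.numeric(sample)) samples[sample] else sample
  pass_df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), id = names(rr),
    ref = as.character(rr$REF), alt = alt_strings,
    qual = rr$QUAL, filter = rr$FILTER,
    gt = if (n_pass) VariantAnnotation::geno(passthrough)$GT[, sample_name]
         else character(0))
  mrg_df <- do.call(rbind, lapply(merged, function(r) data.frame(
    contig = r$contig, pos = r$start,
    id = paste0("MNV_", r$contig, "_", r$start, "_", r$end),
    ref = r$ref_allele, alt = r$alt_allele, qual = NA_real_,
    filter = "PASS", gt = gt_string(r$genotype))))

  old_info <- VariantAnnotation::info(passthrough)
  all_df <- rbind(pass_df, mrg_df)
  n_all <- nrow(all_df)
  n_mrg <- length(merged)
  info <- S4Vectors::DataFrame(matrix(nrow = n_all, ncol = 0))
  for (col in rownames(old_info_hdr)) {
    v <- old_info[[col]]
    filler <- if (is.list(v) || methods::is(v, "List")) NA else NA
    info[[col]] <- c(v, rep(filler, n_mrg))
  }
  info$MNV_MEMBERS <- c(rep(NA_character_, n_pass), vapply(merged, function(r)
    paste(sprintf("%d:%s>%s", r$members$pos, r$members$ref, r$members$alt),
          collapse = "|"), character(1)))
  info$MNV_PHASE <- c(rep(NA_character_, n_pass),
                      vapply(merged, function(r) r$phase_status, character(1)))
  info$MNV_EVIDENCE <- c(rep(NA_character_, n_pass),
                         vapply(merged, function(r)
                           paste(vapply(r$pair_evidence, format_evidence,
                                        character(1)), collapse = "|"),
                           character(1)))

  o <- order(all_df$contig, all_df$pos)
  out_vcf <- build_vcf_object(all_df[o, , drop = FALSE],
                              sample_name = sample_name,
                              info = info[o, , drop = FALSE],
                              info_header = new_info_hdr)
  VariantAnnotation::writeVcf(out_vcf, output)
  invisible(output)
}

#' Write a plain component-SNV VCF
#'
#' @param calls An `snv_calls` data.frame.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @param contig_lengths Optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, path, sample_name = "SAMPLE",
                          contig_lengths = NULL) {
  n <- nrow(calls)
  records <- data.frame(contig = calls$contig, pos = calls$pos,
                        id = calls$source_id, ref = calls$ref,
                        alt = calls$alt, qual = rep(100, n),
                        filter = rep("PASS", n),
                        gt = gt_string(calls$genotype))
  vcf <- build_vcf_object(records, sample_name = sample_name,
                          contig_lengths = contig_lengths)
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}
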