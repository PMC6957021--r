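# End-to-end pipeline: cluster per-SNV calls, phase, merge, re-annotate and
# report naive-vs-merged discordance. The TSV report column order is fixed
# and versioned so downstream consumers can diff reports.

REPORT_VERSION <- "1"
REPORT_COLUMNS <- c("cluster_id", "contig", "start", "end", "n_members",
                    "members", "genotype", "phase_status", "merged", "note",
                    "gene", "transcript", "hgvs_c_merged", "hgvs_p_merged",
                    "naive_annotations", "category", "severity_naive_max",
                    "severity_merged", "evidence")

#' Assemble and validate a pipeline run configuration
#'
#' @param reference Path to the reference FASTA.
#' @param transcripts Path to a transcript model file (GFF3 or TSV).
#' @param vcf Path to the per-site variant calls (VCF 4.x).
#' @param bam Path to coordinate-sorted indexed alignments, or `NULL` for
#'   VCF-only auditing.
#' @param out_dir Output directory.
#' @param max_gap Maximum bases strictly between clustered SNVs (default 1).
#' @param min_support,max_conflict_fraction Phase-calling thresholds, see
#'   [classify_phase()].
#' @param min_base_quality,min_mapping_quality Read-filter thresholds, see
#'   [collect_phase_evidence()].
#' @param same_codon_clustering Also co-cluster SNVs sharing a codon of any
#'   supplied transcript regardless of gap (default TRUE).
#' @param merge_homozygous Merge hom/hom clusters without read evidence
#'   (necessarily cis; default TRUE).
#' @param sample Sample index or name in the VCF (default first).
#' @return Object of class `mnv_run_config`.
#' @export
run_config <- function(reference, transcripts, vcf, bam = NULL, out_dir,
                       max_gap = 1, min_support = 3,
                       max_conflict_fraction = 0.1, min_base_quality = 20,
                       min_mapping_quality = 20, same_codon_clustering = TRUE,
                       merge_homozygous = TRUE, sample = 1L) {
  for (p in c(reference, transcripts, vcf, bam))
    if (!file.exists(p)) stop("input file not found: ", p)
  stopifnot(max_gap >= 0, min_support >= 1,
            max_conflict_fraction >= 0, max_conflict_fraction < 0.5,
            min_base_quality >= 0, min_mapping_quality >= 0)
  structure(list(reference = reference, transcripts = transcripts,
                 vcf = vcf, bam = bam, out_dir = out_dir,
                 max_gap = max_gap, min_support = min_support,
                 max_conflict_fraction = max_conflict_fraction,
                 min_base_quality = min_base_quality,
                 min_mapping_quality = min_mapping_quality,
                 same_codon_clustering = same_codon_clustering,
                 merge_homozygous = merge_homozygous, sample = sample),
            class = "mnv_run_config")
}

#' Run the full MNV rescue pipeline
#'
#' Reads calls, clusters nearby SNVs, phases each cluster from spanning
#' reads (or genotype logic when no BAM is given), merges cis clusters into
#' delins records, writes a merged VCF, and writes a discordance report
#' comparing naive per-SNV annotation with merged annotation. Outputs are
#' deterministic for fixed inputs and configuration. Progress is logged to
#' stderr; a machine-readable summary is written alongside the report.
#'
#' @param config An [run_config()] object.
#' @param quiet Suppress stderr logging (default FALSE).
#' @return Invisibly, a list: `merged` (list of `mnv_record`), `report`
#'   (data.frame), `summary` (list), `paths` (output files).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "mnv_run_config"))
  log <- function(...) if (!quiet) message("[mnvrescue] ", sprintf(...))
  reference <- read_reference(config$reference)
  transcripts <- read_transcripts(config$transcripts)
  calls <- read_snv_calls(config$vcf, sample = config$sample)
  check_contig_consistency(calls, reference, transcripts, config$bam)
  log("loaded %d SNV call(s), %d transcript(s), %d contig(s)",
      nrow(calls), length(transcripts), length(reference))

  clusters <- cluster_candidates(
    calls, max_gap = config$max_gap,
    transcripts = if (config$same_codon_clustering) transcripts else NULL)
  log("%d MNV candidate cluster(s)", length(clusters))

  merged <- list()
  rows <- list()
  n_refused <- 0L
  for (ci in seq_along(clusters)) {
    cl <- phase_cluster(clusters[[ci]], bam = config$bam,
                        min_support = config$min_support,
                        max_conflict_fraction = config$max_conflict_fraction,
                        min_base_quality = config$min_base_quality,
                        min_mapping_quality = config$min_mapping_quality)
    mergeable <- cl$phase_status %in%
      c("cis", if (config$merge_homozygous) "assumed_cis_homozygous")
    rec <- NULL
    if (mergeable) {
      rec <- merge_cluster(cl, reference)
      merged[[length(merged) + 1L]] <- rec
    } else n_refused <- n_refused + 1L
    rows[[ci]] <- report_row(ci, cl, rec, reference, transcripts)
  }
  report <- if (length(rows)) do.call(rbind, rows) else empty_report()
  log("%d cluster(s) merged, %d refused", length(merged), n_refused)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(merged_vcf = file.path(config$out_dir, "merged.vcf"),
                report = file.path(config$out_dir, "discordance.tsv"),
                summary = file.path(config$out_dir, "summary.json"))
  emit_vcf(config$vcf, merged, paths$merged_vcf, sample = config$sample)
  write_report(report, paths$report)
  summary <- list(
    report_version = REPORT_VERSION,
    n_input_snv_calls = nrow(calls),
    n_clusters = length(clusters),
    n_merged = length(merged),
    n_refused = n_refused,
    phase_status_counts = as.list(table(report$phase_status)),
    category_counts = as.list(table(report$category)),
    vcf_only = is.null(config$bam))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE)
  log("wrote %s, %s, %s", paths$merged_vcf, paths$report, paths$summary)
  invisible(list(calls = calls, merged = merged, report = report,
                 summary = summary, paths = paths))
}

#' Audit a VCF for MNV candidates without read evidence
#'
#' Identical clustering and consequence computation to [run_pipeline()],
#' but with no alignments: hom/hom pairs are merged as
#' `assumed_cis_homozygous` (a homozygous pair is necessarily cis) and all
#' other clusters are reported as phase-unconfirmed candidates, never
#' merged.
#'
#' @param config An [run_config()] object; any `bam` entry is ignored.
#' @param quiet Suppress stderr logging.
#' @return As [run_pipeline()].
#' @export
audit_vcf_only <- function(config, quiet = FALSE) {
  config$bam <- NULL
  run_pipeline(config, quiet = quiet)
}

check_contig_consistency <- function(calls, reference, transcripts, bam) {
  miss <- setdiff(unique(calls$contig), names(reference))
  if (length(miss))
    stop("contig name mismatch: VCF contig(s) ", paste(miss, collapse = ", "),
         " absent from the reference FASTA")
  tmiss <- setdiff(unique(vapply(transcripts, `[[`, "", "contig")),
                   names(reference))
  if (length(tmiss))
    stop("contig name mismatch: transcript contig(s) ",
         paste(tmiss, collapse = ", "), " absent from the reference FASTA")
  if (!is.null(bam)) {
    bh <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
    bmiss <- setdiff(unique(calls$contig), bh)
    if (length(bmiss))
      stop("contig name mismatch: VCF contig(s) ",
           paste(bmiss, collapse = ", "), " absent from the BAM header")
  }
}

empty_report <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(REPORT_COLUMNS), character(0), simplify = FALSE),
    REPORT_COLUMNS))
  df
}

# One report row per cluster. Annotation is computed against every
# transcript whose CDS contains all member positions; multiple matching
# transcripts yield a row each (same cluster_id).
report_row <- function(cluster_id, cl, rec, reference, transcripts) {
  m <- cl$members
  base <- data.frame(
    cluster_id = cluster_id, contig = m$contig[1], start = min(m$pos),
    end = max(m$pos), n_members = nrow(m),
    members = paste(sprintf("%d:%s>%s", m$pos, m$ref, m$alt), collapse = "|"),
    genotype = if (all(m$genotype == "hom_alt")) "hom_alt" else "het",
    phase_status = cl$phase_status,
    merged = !is.null(rec),
    note = cluster_note(cl, rec),
    evidence = paste(vapply(cl$pair_evidence, format_evidence, character(1)),
                     collapse = ";"))
  hits <- Filter(function(tx) {
    tx$contig == m$contig[1] &&
      all(vapply(m$pos, function(p)
        !inherits(tryCatch(genomic_to_cds(tx, p), error = identity), "error"),
        logical(1)))
  }, transcripts)
  if (length(hits) == 0) {
    ann <- data.frame(gene = NA_character_, transcript = NA_character_,
                      hgvs_c_merged = NA_character_,
                      hgvs_p_merged = NA_character_,
                      naive_annotations = NA_character_,
                      category = "noncoding",
                      severity_naive_max = NA_real_,
                      severity_merged = NA_real_)
    out <- cbind(base, ann)
  } else {
    out <- do.call(rbind, lapply(hits, function(tx) {
      naive <- lapply(seq_len(nrow(m)), function(k)
        annotate_variant(tx, reference,
                         data.frame(pos = m$pos[k], alt = m$alt[k])))
      mrg <- annotate_variant(tx, reference,
                              data.frame(pos = m$pos, alt = m$alt))
      dis <- classify_discordance(naive, mrg)
      cbind(base, data.frame(
        gene = tx$gene, transcript = tx$transcript_id,
        hgvs_c_merged = mrg$hgvs_c, hgvs_p_merged = mrg$hgvs_p,
        naive_annotations = paste(vapply(naive, function(n)
          paste(n$hgvs_c, n$hgvs_p), character(1)), collapse = "; "),
        category = dis$category,
        severity_naive_max = dis$severity_naive_max,
        severity_merged = dis$severity_merged))
    }))
  }
  out[, REPORT_COLUMNS]
}

cluster_note <- function(cl, rec) {
  if (!is.null(rec)) return("")
  switch(cl$phase_status,
         unphased_no_reads = "candidate - phase unconfirmed",
         trans = "trans pair - not a single mutational event",
         ambiguous = "ambiguous phase - not merged",
         assumed_cis_homozygous = "homozygous merge disabled",
         "")
}

write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mnvrescue discordance report v", REPORT_VERSION), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a discordance report written by [run_pipeline()]
#'
#' @param path Path to a `discordance.tsv`.
#' @return data.frame with the versioned report columns.
#' @export
read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Naive versus merged consequence for a single codon change
#'
#' Convenience query requiring no genome: given a wild-type codon and a
#' variant codon, reports the naive annotation of each component
#' single-base substitution, the merged annotation of the joint change, and
#' the discordance category. Stop-loss extension lengths need transcript
#' context and are reported as `ext*?` here.
#'
#' @param wt_codon,var_codon 3-base codons differing at one or more
#'   positions.
#' @param codon_number Codon index used in the `p.` strings (default 1).
#' @return List with `naive` (character vector of `p.` strings), `merged`
#'   (`p.` string), `category`.
#' @export
annotate_codon_change <- function(wt_codon, var_codon, codon_number = 1L) {
  wt_codon <- toupper(wt_codon); var_codon <- toupper(var_codon)
  wt <- strsplit(wt_codon, "")[[1]]; vr <- strsplit(var_codon, "")[[1]]
  if (length(wt) != 3 || length(vr) != 3)
    stop("codons must be 3 bases")
  offs <- which(wt != vr)
  if (length(offs) == 0) stop("variant codon equals wild-type codon")
  ref_aa <- translate_codon(wt_codon)
  desc <- function(alt_codon) {
    alt_aa <- translate_codon(alt_codon)
    eff <- codon_effect(ref_aa, alt_aa, codon_number)
    list(p = paste0("p.", p_descriptor(codon_number, ref_aa, alt_aa, eff,
                                       NA_integer_, FALSE)),
         eff = eff, alt_aa = alt_aa)
  }
  naive <- lapply(offs, function(o) {
    cod <- wt; cod[o] <- vr[o]
    desc(paste(cod, collapse = ""))
  })
  mrg <- desc(var_codon)
  sev_n <- max(DEFAULT_SEVERITY[vapply(naive, `[[`, "", "eff")])
  sev_m <- DEFAULT_SEVERITY[[mrg$eff]]
  category <- if (sev_m > sev_n) "false_negative_risk"
    else if (sev_m < sev_n) "false_positive_risk"
    else if (mrg$p %in% vapply(naive, `[[`, "", "p")) "concordant"
    else "changed_effect"
  list(naive = vapply(naive, `[[`, "", "p"), merged = mrg$p,
       category = category)
}
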