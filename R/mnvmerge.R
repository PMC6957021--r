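# Clustering of nearby SNV calls, read-backed cis/trans phasing, and merging
# of cis clusters into single same-length delins (MNV) records.

PHASE_STATUSES <- c("cis", "trans", "ambiguous", "assumed_cis_homozygous",
                    "unphased_no_reads")

#' Construct a table of SNV calls
#'
#' @param contig,pos,ref,alt,genotype,source_id Vectors (recycled to common
#'   length): contig name, 1-based genomic position, reference and alternate
#'   single bases, genotype (`"het"` or `"hom_alt"`), and the originating
#'   VCF record key.
#' @return data.frame of class `snv_calls`, sorted by contig then position.
#' @export
snv_calls <- function(contig, pos, ref, alt, genotype,
                      source_id = sprintf("%s:%s_%s/%s", contig, pos, ref, alt)) {
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   ref = toupper(ref), alt = toupper(alt),
                   genotype = as.character(genotype),
                   source_id = as.character(source_id))
  if (any(nchar(df$ref) != 1 | nchar(df$alt) != 1) ||
      any(!df$ref %in% c("A", "C", "G", "T")) ||
      any(!df$alt %in% c("A", "C", "G", "T")))
    stop("SNV calls must have single-base A/C/G/T ref and alt")
  if (any(df$ref == df$alt)) stop("ref and alt base must differ")
  if (any(!df$genotype %in% c("het", "hom_alt")))
    stop("genotype must be 'het' or 'hom_alt'")
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("snv_calls", "data.frame")
  df
}

#' Cluster nearby SNV calls into MNV candidates
#'
#' Two SNVs are linked when the number of reference bases strictly between
#' them is at most `max_gap`, or (when transcript models are supplied) when
#' both fall in the same codon of any transcript — which also captures
#' codon-mates separated by an intron. Linkage is transitive; singletons are
#' not reported.
#'
#' @param calls An `snv_calls` data.frame sorted by contig, position.
#' @param max_gap Maximum number of bases strictly between two clustered
#'   SNVs (default 1, i.e. SNVs at most 2 bp apart, span at most 3 bp).
#' @param transcripts Optional list of `mnv_transcript`; enables same-codon
#'   clustering.
#' @return List of `mnv_cluster` objects (each: `members` data.frame,
#'   `pair_status`, `pair_evidence`, `phase_status`).
#' @export
cluster_candidates <- function(calls, max_gap = 1, transcripts = NULL) {
  stopifnot(is.data.frame(calls), max_gap >= 0)
  if (nrow(calls) == 0) return(list())
  o <- order(calls$contig, calls$pos)
  if (!identical(o, seq_len(nrow(calls))))
    stop("calls must be sorted by contig then position")
  codon_key <- same_codon_keys(calls, transcripts)
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      if (calls$contig[j] != calls$contig[i]) break
      linked <- (calls$pos[j] - calls$pos[i] - 1L) <= max_gap ||
        length(intersect(codon_key[[i]], codon_key[[j]])) > 0
      if (linked) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  groups <- Filter(function(g) length(g) >= 2, groups)
  groups <- groups[order(vapply(groups, min, integer(1)))]
  unname(lapply(groups, function(g) {
    new_cluster(calls[g, , drop = FALSE])
  }))
}

# "contig-aware" codon keys: for each call, the set of "tx:codon" strings of
# transcripts whose CDS contains the position.
same_codon_keys <- function(calls, transcripts) {
  if (is.null(transcripts) || length(transcripts) == 0)
    return(rep(list(character(0)), nrow(calls)))
  lapply(seq_len(nrow(calls)), function(i) {
    keys <- character(0)
    for (tx in transcripts) {
      if (tx$contig != calls$contig[i]) next
      cc <- tryCatch(genomic_to_cds(tx, calls$pos[i]), error = function(e) NULL)
      if (!is.null(cc))
        keys <- c(keys, paste0(tx$transcript_id, ":", cc$codon_number))
    }
    keys
  })
}

new_cluster <- function(members) {
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members,
                 pair_evidence = vector("list", max(nrow(members) - 1L, 0L)),
                 pair_status = rep(NA_character_, max(nrow(members) - 1L, 0L)),
                 phase_status = NA_character_),
            class = "mnv_cluster")
}

#' @export
print.mnv_cluster <- function(x, ...) {
  cat(sprintf("<MNV cluster %s:%d-%d, %d members, phase: %s>\n",
              x$members$contig[1], min(x$members$pos), max(x$members$pos),
              nrow(x$members),
              ifelse(is.na(x$phase_status), "unset", x$phase_status)))
  invisible(x)
}

#' Construct a phase-evidence count table
#'
#' Counts refer to distinct read templates (a read pair counts once).
#'
#' @param n_both_alt Templates carrying the alternate base at both sites.
#' @param n_alt_ref,n_ref_alt Templates with alt at one site, ref at the other.
#' @param n_both_ref Templates carrying the reference base at both sites.
#' @param n_other Templates with a third allele or a base-quality failure at
#'   either site.
#' @return Object of class `phase_evidence`.
#' @export
phase_evidence <- function(n_both_alt = 0, n_alt_ref = 0, n_ref_alt = 0,
                           n_both_ref = 0, n_other = 0) {
  counts <- c(n_both_alt = n_both_alt, n_alt_ref = n_alt_ref,
              n_ref_alt = n_ref_alt, n_both_ref = n_both_ref,
              n_other = n_other)
  if (any(counts < 0)) stop("phase evidence counts must be >= 0")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "phase_evidence")
}

#' @export
print.phase_evidence <- function(x, ...) {
  cat(sprintf("<phase evidence alt/alt=%d alt/ref=%d ref/alt=%d ref/ref=%d other=%d>\n",
              x$n_both_alt, x$n_alt_ref, x$n_ref_alt, x$n_both_ref, x$n_other))
  invisible(x)
}

format_evidence <- function(ev) {
  if (is.null(ev)) return("NA")
  sprintf("%d|%d|%d|%d|%d", ev$n_both_alt, ev$n_alt_ref, ev$n_ref_alt,
          ev$n_both_ref, ev$n_other)
}

#' Collect spanning-read phase evidence for a pair of SNV sites
#'
#' Tallies, over distinct read templates that cover both sites with passing
#' base and mapping qualities, how often the two alternate alleles co-occur
#' on the same template. CIGAR-aware base extraction is done with
#' [GenomicAlignments::sequenceLayer()]; overlapping mates are
#' de-duplicated by template name (consistent duplicated observations count
#' once, contradictory ones go to `n_other`).
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param site_a,site_b Single rows of an `snv_calls` data.frame (same
#'   contig).
#' @param min_base_quality Minimum Phred base quality at each site
#'   (default 20).
#' @param min_mapping_quality Minimum mapping quality (default 20).
#' @return A `phase_evidence` object.
#' @export
collect_phase_evidence <- function(bam, site_a, site_b,
                                   min_base_quality = 20,
                                   min_mapping_quality = 20) {
  if (site_a$contig != site_b$contig)
    stop("phase evidence requires both sites on one contig")
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM file must be indexed for random access: ", bam)
  lo <- min(site_a$pos, site_b$pos); hi <- max(site_a$pos, site_b$pos)
  which <- GenomicRanges::GRanges(site_a$contig, IRanges::IRanges(lo, hi))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    which = which)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  obs <- data.frame(qname = character(0), site = character(0),
                    base = character(0), pass = logical(0))
  if (length(gal) > 0) {
    mq <- S4Vectors::mcols(gal)$mapq
    keep <- !is.na(mq) & mq >= min_mapping_quality
    gal <- gal[keep]
  }
  if (length(gal) > 0) {
    seqs <- GenomicAlignments::sequenceLayer(
      S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal))
    quals <- GenomicAlignments::sequenceLayer(
      S4Vectors::mcols(gal)$qual, GenomicAlignments::cigar(gal))
    starts <- GenomicAlignments::start(gal)
    ends <- GenomicAlignments::end(gal)
    grab <- function(i, p) {
      if (p < starts[i] || p > ends[i]) return(NULL)
      off <- p - starts[i] + 1L
      b <- substr(as.character(seqs[[i]]), off, off)
      q <- as.integer(Biostrings::PhredQuality(substr(as.character(quals[[i]]), off, off)))
      list(base = b, pass = length(q) == 1 && !is.na(q) && q >= min_base_quality &&
             b %in% c("A", "C", "G", "T"))
    }
    rows <- list()
    for (i in seq_along(gal)) {
      for (s in list(list(key = "a", pos = site_a$pos),
                     list(key = "b", pos = site_b$pos))) {
        g <- grab(i, s$pos)
        if (!is.null(g))
          rows[[length(rows) + 1L]] <- data.frame(
            qname = S4Vectors::mcols(gal)$qname[i], site = s$key,
            base = g$base, pass = g$pass)
      }
    }
    if (length(rows)) obs <- do.call(rbind, rows)
  }
  tally_phase_observations(obs, site_a, site_b)
}

# Collapse per-read site observations into per-template joint counts.
tally_phase_observations <- function(obs, site_a, site_b) {
  counts <- c(n_both_alt = 0L, n_alt_ref = 0L, n_ref_alt = 0L,
              n_both_ref = 0L, n_other = 0L)
  if (nrow(obs) > 0) for (qn in unique(obs$qname)) {
    sub <- obs[obs$qname == qn, , drop = FALSE]
    resolve <- function(key, site) {
      ss <- sub[sub$site == key, , drop = FALSE]
      if (nrow(ss) == 0) return(NA_character_)   # template does not cover site
      ok <- ss[ss$pass, , drop = FALSE]
      if (nrow(ok) == 0 || length(unique(ok$base)) > 1) return("fail")
      b <- ok$base[1]
      if (b == site$alt) "alt" else if (b == site$ref) "ref" else "fail"
    }
    a <- resolve("a", site_a); b <- resolve("b", site_b)
    if (is.na(a) || is.na(b)) next                # must cover both sites
    key <- paste(a, b)
    counts[[switch(key,
                   "alt alt" = "n_both_alt", "alt ref" = "n_alt_ref",
                   "ref alt" = "n_ref_alt", "ref ref" = "n_both_ref",
                   "n_other")]] <-
      counts[[switch(key,
                     "alt alt" = "n_both_alt", "alt ref" = "n_alt_ref",
                     "ref alt" = "n_ref_alt", "ref ref" = "n_both_ref",
                     "n_other")]] + 1L
  }
  do.call(phase_evidence, as.list(counts))
}

#' Classify the phase of a pair of SNVs from read evidence
#'
#' A pair of homozygous-alternate calls is necessarily cis and is classified
#' `assumed_cis_homozygous` regardless of read evidence. Otherwise the pair
#' is `cis` when at least `min_support` templates carry both alternate
#' alleles and the fraction of conflicting (mixed) templates among
#' informative templates is at most `max_conflict_fraction`; `trans` under
#' the mirrored condition for mixed templates; `unphased_no_reads` when no
#' informative template exists; `ambiguous` otherwise.
#'
#' @param evidence A `phase_evidence` object.
#' @param genotypes Character vector of length 2 (`"het"`/`"hom_alt"`).
#' @param min_support Minimum supporting templates (default 3).
#' @param max_conflict_fraction Maximum tolerated fraction of conflicting
#'   templates, in `[0, 0.5)` (default 0.1).
#' @return One of `r paste(PHASE_STATUSES, collapse = ", ")`.
#' @export
classify_phase <- function(evidence, genotypes, min_support = 3,
                           max_conflict_fraction = 0.1) {
  stopifnot(min_support >= 1,
            max_conflict_fraction >= 0, max_conflict_fraction < 0.5,
            length(genotypes) == 2)
  if (all(genotypes == "hom_alt")) return("assumed_cis_homozygous")
  both <- evidence$n_both_alt
  mixed <- evidence$n_alt_ref + evidence$n_ref_alt
  informative <- both + mixed
  if (informative == 0) return("unphased_no_reads")
  if (both >= min_support && mixed / informative <= max_conflict_fraction)
    return("cis")
  if (mixed >= min_support && both / informative <= max_conflict_fraction)
    return("trans")
  "ambiguous"
}

#' Phase all adjacent pairs of a cluster
#'
#' Computes per-pair evidence (when a BAM is available) and a per-pair then
#' overall phase status. Without a BAM, hom/hom pairs are
#' `assumed_cis_homozygous` and everything else `unphased_no_reads`. A
#' cluster merges only when every adjacent pair is cis-classified; a single
#' trans pair marks the cluster trans, otherwise any ambiguous pair demotes
#' it to ambiguous, then any unphased pair to unphased_no_reads.
#'
#' @param cluster An `mnv_cluster`.
#' @param bam Path to an indexed BAM, or `NULL` for VCF-only auditing.
#' @param min_support,max_conflict_fraction,min_base_quality,min_mapping_quality
#'   Thresholds, see [classify_phase()] and [collect_phase_evidence()].
#' @return The cluster with `pair_evidence`, `pair_status` and
#'   `phase_status` filled in.
#' @export
phase_cluster <- function(cluster, bam = NULL, min_support = 3,
                          max_conflict_fraction = 0.1,
                          min_base_quality = 20, min_mapping_quality = 20) {
  m <- cluster$members
  for (k in seq_len(nrow(m) - 1L)) {
    a <- m[k, ]; b <- m[k + 1L, ]
    ev <- if (is.null(bam)) phase_evidence() else
      collect_phase_evidence(bam, a, b, min_base_quality, min_mapping_quality)
    cluster$pair_evidence[[k]] <- ev
    cluster$pair_status[k] <- classify_phase(ev, c(a$genotype, b$genotype),
                                             min_support,
                                             max_conflict_fraction)
  }
  st <- cluster$pair_status
  cluster$phase_status <-
    if (all(st == "assumed_cis_homozygous")) "assumed_cis_homozygous"
    else if (all(st %in% c("cis", "assumed_cis_homozygous"))) "cis"
    else if (any(st == "trans")) "trans"
    else if (any(st == "ambiguous")) "ambiguous"
    else "unphased_no_reads"
  cluster
}

#' Merge a cis cluster into a single delins MNV record
#'
#' The merged record spans from the first to the last member position;
#' intervening reference bases are retained unchanged, so REF and ALT always
#' have equal length (no indels are ever produced). Clusters that are not
#' cis-classified are refused with an error of class `mnv_refuse_merge` —
#' they are reported, never silently merged.
#'
#' @param cluster A phased `mnv_cluster`.
#' @param reference A `DNAStringSet`.
#' @return Object of class `mnv_record` with fields `contig`, `start`,
#'   `end`, `ref_allele`, `alt_allele`, `genotype`, `members`,
#'   `phase_status`, `pair_evidence`.
#' @export
merge_cluster <- function(cluster, reference) {
  if (is.na(cluster$phase_status) ||
      !cluster$phase_status %in% c("cis", "assumed_cis_homozygous"))
    stop(structure(class = c("mnv_refuse_merge", "error", "condition"),
                   list(message = paste0(
                     "refusing to merge cluster ", cluster$members$contig[1],
                     ":", min(cluster$members$pos), "-",
                     max(cluster$members$pos), " with phase status '",
                     cluster$phase_status, "'"), call = sys.call())))
  m <- cluster$members
  start <- min(m$pos); end <- max(m$pos)
  ref_allele <- ref_bases(reference, m$contig[1], start, end)
  for (k in seq_len(nrow(m))) {
    off <- m$pos[k] - start + 1L
    if (substr(ref_allele, off, off) != m$ref[k])
      stop("reference mismatch at ", m$contig[k], ":", m$pos[k],
           ": VCF says ", m$ref[k], ", FASTA says ",
           substr(ref_allele, off, off))
  }
  alt_allele <- ref_allele
  for (k in seq_len(nrow(m))) {
    off <- m$pos[k] - start + 1L
    substr(alt_allele, off, off) <- m$alt[k]
  }
  structure(list(contig = m$contig[1], start = start, end = end,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 genotype = if (all(m$genotype == "hom_alt")) "hom_alt" else "het",
                 members = m, phase_status = cluster$phase_status,
                 pair_evidence = cluster$pair_evidence),
            class = "mnv_record")
}

#' @export
print.mnv_record <- function(x, ...) {
  cat(sprintf("<MNV %s:%d-%d %s>%s [%s, %s, %d members]\n", x$contig,
              x$start, x$end, x$ref_allele, x$alt_allele, x$genotype,
              x$phase_status, nrow(x$members)))
  invisible(x)
}
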