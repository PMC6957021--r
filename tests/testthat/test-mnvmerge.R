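cluster_keys <- function(clusters) {
  out <- lapply(clusters, function(cl)
    sort(paste0(cl$members$contig, ":", cl$members$pos)))
  unname(out[order(vapply(out, `[`, "", 1))])
}

test_that("clustering matches a brute-force transitive closure on random site sets", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 60
    pos <- sort(sample(1:400, n))
    contig <- sort(sample(c("c1", "c2"), n, replace = TRUE))
    calls <- snv_calls(contig, pos, rep("A", n), rep("G", n),
                       sample(c("het", "hom_alt"), n, replace = TRUE))
    for (max_gap in 0:2) {
      got <- cluster_keys(cluster_candidates(calls, max_gap = max_gap))
      want <- oracle_closure_clusters(calls, max_gap)
      expect_equal(got, want, info = paste("seed", seed, "gap", max_gap))
    }
  }
})

test_that("same-codon SNVs cluster regardless of gap and singletons are dropped", {
  ref <- make_manual_reference()
  txp <- manual_plus_tx()
  # codon 4 (CTG at ctgP:25-27): sites at offsets 1 and 3, inner gap 1
  calls <- snv_calls(c("ctgP", "ctgP"), c(25, 27), c("C", "G"), c("T", "C"),
                     c("hom_alt", "hom_alt"))
  expect_length(cluster_candidates(calls, max_gap = 1), 1)
  # gap 1 exceeds max_gap 0, but the shared codon still clusters them
  expect_length(cluster_candidates(calls, max_gap = 0,
                                   transcripts = list(txp)), 1)
  expect_length(cluster_candidates(calls, max_gap = 0), 0)
  # a lone SNV is not a cluster
  expect_length(cluster_candidates(calls[1, ], max_gap = 1), 0)
  # unsorted input is an ordering error
  expect_error(cluster_candidates(calls[2:1, ], max_gap = 1), "sorted")
})

test_that("phase classification reproduces its defining inequalities on random tables", {
  oracle <- function(ev, gts, ms, mcf) {
    if (all(gts == "hom_alt")) return("assumed_cis_homozygous")
    both <- ev$n_both_alt; mixed <- ev$n_alt_ref + ev$n_ref_alt
    if (both + mixed == 0) return("unphased_no_reads")
    if (both >= ms && mixed / (both + mixed) <= mcf) return("cis")
    if (mixed >= ms && both / (both + mixed) <= mcf) return("trans")
    "ambiguous"
  }
  set.seed(42)
  for (i in 1:300) {
    ev <- phase_evidence(sample(0:30, 1), sample(0:8, 1), sample(0:8, 1),
                         sample(0:30, 1), sample(0:5, 1))
    gts <- sample(c("het", "hom_alt"), 2, replace = TRUE)
    ms <- sample(1:5, 1)
    mcf <- stats::runif(1, 0, 0.49)
    got <- classify_phase(ev, gts, ms, mcf)
    expect_equal(got, oracle(ev, gts, ms, mcf))
    # symmetric under swapping the two sites
    swapped <- phase_evidence(ev$n_both_alt, ev$n_ref_alt, ev$n_alt_ref,
                              ev$n_both_ref, ev$n_other)
    expect_equal(classify_phase(swapped, rev(gts), ms, mcf), got)
  }
  expect_equal(classify_phase(phase_evidence(30, 0, 0, 0, 0), c("het", "het")),
               "cis")
  expect_equal(classify_phase(phase_evidence(0, 0, 0, 12, 0), c("het", "het")),
               "unphased_no_reads")
  expect_equal(classify_phase(phase_evidence(0, 0, 0, 0, 0),
                              c("hom_alt", "hom_alt")),
               "assumed_cis_homozygous")
  expect_error(classify_phase(phase_evidence(), c("het", "het"),
                              min_support = 0))
})

test_that("spanning-read evidence matches the simulator's haplotype truth", {
  fx <- clinical_mnv_fixture(seed = 5)
  dir <- withr::local_tempdir()
  bam <- file.path(dir, "reads.bam")
  sim <- simulate_reads(fx, bam)
  snvs <- fx$truth$snvs
  for (vid in unique(snvs$variant_id)) {
    pair <- snvs[snvs$variant_id == vid, ][1:2, ]
    ev <- collect_phase_evidence(bam, pair[1, ], pair[2, ])
    tpl <- sim$templates
    covers <- tpl$contig == pair$contig[1] &
      tpl$start <= min(pair$pos) & tpl$end >= max(pair$pos)
    # cis het truth: haplotype 2 carries both alts, haplotype 1 neither
    expect_equal(ev$n_both_alt, sum(covers & tpl$hap == 2))
    expect_equal(ev$n_both_ref, sum(covers & tpl$hap == 1))
    expect_equal(ev$n_alt_ref + ev$n_ref_alt + ev$n_other, 0)
  }
  # homozygous fixture: every covering template carries both alts
  fh <- simulated_mnv_fixture(seed = 5)
  bam_h <- file.path(dir, "hom.bam")
  sim_h <- simulate_reads(fh, bam_h)
  pair <- fh$truth$snvs[fh$truth$snvs$variant_id == 1, ]
  ev <- collect_phase_evidence(bam_h, pair[1, ], pair[2, ])
  tpl <- sim_h$templates
  covers <- tpl$contig == pair$contig[1] &
    tpl$start <= min(pair$pos) & tpl$end >= max(pair$pos)
  expect_equal(ev$n_both_alt, sum(covers))
  expect_equal(ev$n_alt_ref + ev$n_ref_alt + ev$n_both_ref + ev$n_other, 0)
  # sites farther apart than the read length: no spanning template
  far <- snvs[c(1, nrow(snvs)), ]
  far <- far[far$contig == far$contig[1], ]
  a <- snvs[1, ]; b <- snvs[snvs$contig == a$contig, ]
  b <- b[which.max(b$pos), ]
  if (b$pos - a$pos > fx$spec$read_length) {
    ev0 <- collect_phase_evidence(bam, a, b)
    expect_equal(ev0$n_both_alt + ev0$n_alt_ref + ev0$n_ref_alt +
                   ev0$n_both_ref + ev0$n_other, 0)
    expect_equal(classify_phase(ev0, c(a$genotype, b$genotype)),
                 "unphased_no_reads")
  }
  # an unindexed BAM is unusable for random access
  noidx <- file.path(dir, "noidx.bam")
  file.copy(bam, noidx)
  expect_error(collect_phase_evidence(noidx, pair[1, ], pair[2, ]),
               "indexed")
})

test_that("merging builds equal-length delins alleles and refuses non-cis clusters", {
  ref <- make_manual_reference()
  # codon 4 CTG at ctgP:25-27, edits at both ends -> TTC-style delins
  calls <- snv_calls(c("ctgP", "ctgP"), c(25, 27), c("C", "G"), c("T", "C"),
                     c("hom_alt", "hom_alt"))
  cl <- cluster_candidates(calls, max_gap = 1)[[1]]
  cl <- phase_cluster(cl, bam = NULL)
  rec <- merge_cluster(cl, ref)
  expect_s3_class(rec, "mnv_record")
  expect_equal(rec$ref_allele, "CTG")
  expect_equal(rec$alt_allele, "TTC")
  expect_equal(nchar(rec$ref_allele), nchar(rec$alt_allele))
  expect_equal(rec$genotype, "hom_alt")
  # adjacent pair without retained middle base
  calls2 <- snv_calls(c("ctgP", "ctgP"), c(25, 26), c("C", "T"), c("A", "G"),
                      c("hom_alt", "hom_alt"))
  cl2 <- phase_cluster(cluster_candidates(calls2, max_gap = 1)[[1]])
  rec2 <- merge_cluster(cl2, ref)
  expect_equal(rec2$ref_allele, "CT")
  expect_equal(rec2$alt_allele, "AG")
  # applying the merged allele equals applying each member independently
  set.seed(7)
  for (i in 1:20) {
    rt <- random_manual_tx(i + 100)
    len <- length(rt$ref[[1]])
    pos <- sort(sample(5:(len - 5), 2))
    if (pos[2] - pos[1] > 1) pos[2] <- pos[1] + sample(1:2, 1)
    refb <- vapply(pos, function(p) ref_bases(rt$ref, "ctgR", p), "")
    altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    calls_i <- snv_calls(rep("ctgR", 2), pos, refb, altb, rep("hom_alt", 2))
    cl_i <- phase_cluster(cluster_candidates(calls_i, max_gap = 1)[[1]])
    rec_i <- merge_cluster(cl_i, rt$ref)
    whole <- as.character(rt$ref[[1]])
    via_members <- whole
    for (k in 1:2) substr(via_members, pos[k], pos[k]) <- altb[k]
    via_merged <- whole
    substr(via_merged, rec_i$start, rec_i$end) <- rec_i$alt_allele
    expect_equal(via_merged, via_members)
  }
  # trans and ambiguous clusters are refused, never silently merged
  het <- snv_calls(c("ctgP", "ctgP"), c(25, 27), c("C", "G"), c("T", "C"),
                   c("het", "het"))
  cl_t <- cluster_candidates(het, max_gap = 1)[[1]]
  cl_t$phase_status <- "trans"
  expect_error(merge_cluster(cl_t, ref), class = "mnv_refuse_merge")
  cl_t$phase_status <- "ambiguous"
  expect_error(merge_cluster(cl_t, ref), class = "mnv_refuse_merge")
  # VCF/FASTA disagreement is caught
  bad <- snv_calls(c("ctgP", "ctgP"), c(25, 27), c("A", "G"), c("T", "C"),
                   c("hom_alt", "hom_alt"))
  cl_b <- phase_cluster(cluster_candidates(bad, max_gap = 1)[[1]])
  expect_error(merge_cluster(cl_b, ref), "reference mismatch")
})

test_that("emitted VCF replaces member records and round-trips the merged fields", {
  fx <- simulated_mnv_fixture(seed = 3)
  res <- run_fixture_pipeline(fx)
  out <- res$paths$merged_vcf
  vcf <- VariantAnnotation::readVcf(out)
  expect_equal(nrow(vcf), 5)                       # 10 SNVs -> 5 delins
  expect_equal(nrow(read_snv_calls(out)), 0)       # no single-base records left
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  got <- data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
                    start = GenomicRanges::start(rr),
                    ref = as.character(rr$REF),
                    alt = vapply(seq_len(nrow(vcf)),
                                 function(i) as.character(rr$ALT[[i]][1]), ""),
                    phase = info$MNV_PHASE)
  for (rec in res$merged) {
    row <- got[got$start == rec$start & got$contig == rec$contig, ]
    expect_equal(nrow(row), 1)
    expect_equal(row$ref, rec$ref_allele)
    expect_equal(row$alt, rec$alt_allele)
    expect_equal(row$phase, rec$phase_status)
    members <- info$MNV_MEMBERS[got$start == rec$start]
    expect_equal(members,
                 paste(sprintf("%d:%s>%s", rec$members$pos, rec$members$ref,
                               rec$members$alt), collapse = "|"))
  }
  # an empty merge list passes every record through unchanged
  dir <- withr::local_tempdir()
  fpaths <- materialize_fixture(fx, dir, reads = FALSE)
  out2 <- file.path(dir, "noop.vcf")
  emit_vcf(fpaths$vcf, list(), out2)
  a <- read_snv_calls(fpaths$vcf); b <- read_snv_calls(out2)
  expect_equal(b[, c("contig", "pos", "ref", "alt", "genotype")],
               a[, c("contig", "pos", "ref", "alt", "genotype")])
  # merged records whose members are absent are a consistency error
  expect_error(emit_vcf(fpaths$vcf, res$merged["wrong" != "wrong"], out2), NA)
  fake <- res$merged[[1]]; fake$members$pos <- fake$members$pos + 10000L
  expect_error(emit_vcf(fpaths$vcf, list(fake), out2), "absent")
})
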