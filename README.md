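# mnvrescue

Rescue multi-nucleotide variants (MNVs) that a short-variant pipeline has
miscalled as independent SNVs.

## The problem

An MNV is a set of substitutions on the same haplotype within a few bases
of each other — most consequentially, within one codon. Standard
per-SNV callers emit each substitution as its own VCF record, and
annotators then score each record against the reference codon in
isolation. The joint change can mean something entirely different: a `CTG`
(Leu) codon tolerates `c.838C>T` or `c.840G>C` silently, but the joint
change to `TTC` is the missense p.Leu280Phe. HGVS nomenclature requires
the joint event to be written as a single deletion–insertion,
`c.838_840delinsTTC`. Annotated naively, such variants produce
false-negative results (the true consequence is worse than either per-SNV
annotation) or false-positive results (it is milder) in diagnostic
testing.

`mnvrescue` post-processes a call set (VCF + BAM + reference FASTA +
transcript models):

1. **cluster** nearby SNVs (gap ≤ `max_gap`, default 1 base between sites,
   or same codon of any transcript);
2. **phase** each cluster from the sequencing templates that physically
   span both sites — cis when ≥ `min_support` templates carry both
   alternate alleles with ≤ `max_conflict_fraction` conflicting templates,
   trans under the mirrored condition, and hom/hom pairs cis by necessity;
3. **merge** cis clusters into single equal-length delins records
   (`REF=CTG ALT=TTC`), refusing trans/ambiguous clusters explicitly;
4. **re-annotate** both ways — each SNV alone and the joint edit — with
   codon-aware translation and HGVS-style `c.`/`p.` strings, including
   stop-loss extension lengths (`p.*396Trpext*26`);
5. **report** every cluster where naive and merged annotation disagree,
   graded `false_negative_risk` / `false_positive_risk` /
   `changed_effect` / `concordant` under a configurable severity ranking
   (synonymous 1, missense 2, stop gain/loss and start loss 4).

A bundled deterministic simulator regenerates planted-MNV test data
(reference, transcripts, reads, truth set) so the entire pipeline is
testable offline.

## Worked example

```r
library(mnvrescue)

fx    <- simulated_mnv_fixture(seed = 1)              # five homozygous planted MNVs
paths <- materialize_fixture(fx, "demo")       # ref.fa, transcripts.tsv,
                                               # calls.vcf, reads.bam, truth
cfg <- run_config(paths$reference, paths$transcripts, paths$vcf,
                  bam = paths$bam, out_dir = "demo/out")
res <- run_pipeline(cfg)
res$report[, c("hgvs_c_merged", "hgvs_p_merged", "category")]
```

```
[mnvrescue] loaded 10 SNV call(s), 2 transcript(s), 1 contig(s)
[mnvrescue] 5 MNV candidate cluster(s)
[mnvrescue] 5 cluster(s) merged, 0 refused
        hgvs_c_merged   hgvs_p_merged            category
1  c.838_840delinsTTC     p.Leu280Phe false_negative_risk
2 c.1066_1067delinsAG     p.Ser356Ser false_positive_risk
3 c.1262_1263delinsGA       p.Ser421* false_negative_risk
4 c.1274_1275delinsGT     p.Lys425Ser      changed_effect
5 c.1187_1188delinsGG p.*396Trpext*26 false_negative_risk
```

The ten input SNVs collapse to five delins records. Row 1 is the
false-negative archetype: two individually silent changes that are jointly
missense. Row 2 is the mirror image (two missense calls that jointly
change nothing). Row 3 is a nonsense variant hidden behind a
missense + synonymous pair. Row 4 swaps one missense for another
(interpretation could move either way), and row 5 abolishes a stop codon —
translation runs on for 26 further codons — where the naive calls see only
a retained stop. The merged VCF (`demo/out/merged.vcf`) carries each
event's members, phase status and spanning-template counts in
`MNV_MEMBERS`, `MNV_PHASE` and `MNV_EVIDENCE` INFO fields, and
`demo/out/discordance.tsv` is the versioned lab-facing report.

Without a BAM, `audit_vcf_only()` performs the same clustering and
annotation but merges only hom/hom pairs (necessarily cis) and lists
everything else as phase-unconfirmed candidates. A small synthetic
example bundle (reference, transcript TSV and per-SNV VCF — the
`simulated_mnv_fixture(seed = 1)` inputs, no reads) ships under
`inst/extdata/` for trying audit mode directly:

```r
ext <- function(f) system.file("extdata", f, package = "mnvrescue")
cfg <- run_config(ext("synthetic_hnf4a_ref.fa"),
                  ext("synthetic_hnf4a_transcripts.tsv"),
                  ext("synthetic_hnf4a_calls.vcf"),
                  out_dir = tempfile())
audit_vcf_only(cfg)
```

A thin command-line front end is installed with the package
(`system.file("scripts", "mnvrescue", package = "mnvrescue")`) with
subcommands `merge`, `audit`, `fixtures` and `annotate`:

```sh
mnvrescue annotate --wt-codon TCT --var-codon TGA --codon-number 421
# naive:   p.Ser421Cys, p.Ser421Ser
# merged:  p.Ser421*
# category: false_negative_risk
```

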