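---
title: "Methods: merging miscalled multi-nucleotide variants"
author: "mnvrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging miscalled multi-nucleotide variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnvrescue)
```

## The problem

A multi-nucleotide variant (MNV) is a set of two or more substitutions that
lie on the same haplotype within a few bases of each other — most
consequentially, within a single codon. Widely used short-variant pipelines
emit each substitution as an independent SNV record, and downstream
annotators then score each SNV against the reference codon in isolation.
The joint change can have a completely different protein consequence: a
leucine codon `CTG` can tolerate either `C>T` at its first base or `G>C` at
its third base silently, yet the joint change to `TTC` is a
missense (Leu→Phe). Under a diagnostic testing model this produces
false-negative risks (the joint change is more severe than either
single-SNV annotation suggests) and false-positive risks (less severe), and
HGVS nomenclature requires such events to be described as a single
deletion–insertion (`delins`) in the first place.

`mnvrescue` post-processes a per-SNV call set: it clusters nearby SNVs,
establishes whether they are in cis (same haplotype) from the reads that
physically span both sites, merges cis clusters into single equal-length
delins records, recomputes codon-aware consequences, and reports every
cluster where the naive per-SNV annotation and the merged annotation
disagree, graded by diagnostic risk.

## Pipeline model

### Clustering

Two SNVs are linked when at most `max_gap` reference bases lie strictly
between them (default `max_gap = 1`, i.e. sites at most 2 bp apart and a
merged span of at most 3 bp), or — when transcript models are supplied —
when both sites fall in the same codon of any transcript, which also
captures codon mates separated by an intron. Linkage is closed
transitively; singletons are not candidates. The default gap mirrors the
maximum-distance setting used by read-backed MNV post-processors and is
deliberately tight: within-codon events are the clinically consequential
ones, and a small span bounds the delins size.

### Read-backed phasing

For each adjacent pair in a cluster, spanning templates are tallied into a
2×2-plus-other table: `n_both_alt`, `n_alt_ref`, `n_ref_alt`,
`n_both_ref`, and `n_other` (third alleles or base-quality failures).
Counts refer to distinct templates: overlapping mates that agree count
once; mates that contradict each other are routed to `n_other`. Reads must
pass `min_mapping_quality` (default 20) and each base `min_base_quality`
(default 20). Base extraction is CIGAR-aware, so soft-clipped and gapped
alignments are handled, although the bundled simulator only emits
full-match alignments.

The pair is then classified:

* both genotypes homozygous-alternate → `assumed_cis_homozygous`: a hom/hom
  pair is necessarily cis, no read evidence needed (merging on this basis
  can be disabled with `merge_homozygous = FALSE`);
* `cis` when `n_both_alt >= min_support` (default 3 templates) and the
  conflicting fraction `(n_alt_ref + n_ref_alt) / informative` is at most
  `max_conflict_fraction` (default 0.1), where `informative` counts
  `n_both_alt + n_alt_ref + n_ref_alt`;
* `trans` under the mirrored condition for mixed templates;
* `unphased_no_reads` when no informative template exists;
* `ambiguous` otherwise.

The thresholds are configuration, chosen conservatively: three error-free
spanning templates with at most 10 % conflict is modest evidence at typical
panel depths (30× and up) while refusing to merge on one or two stray
reads. The classification is symmetric under swapping the two sites.
Clusters of three or more SNVs merge only if *every* adjacent pair is
cis-classified; a single trans pair marks the cluster trans and any
ambiguous pair demotes the whole cluster to reported-but-not-merged,
avoiding chimeric haplotypes.

### Merging

A cis cluster becomes one delins record spanning first to last member
position; intervening reference bases are retained, so REF and ALT always
have equal length and no indel is ever produced. Non-cis clusters are
refused with a distinct error class and surfaced in the report — never
silently merged. Quality scores of the component records are deliberately
not aggregated into a merged quality (there is no principled way to
combine them); instead the merged record carries its members, phase status
and evidence counts in `MNV_MEMBERS`, `MNV_PHASE` and `MNV_EVIDENCE` INFO
fields, and the report keeps the full provenance.

### Consequence recomputation

All member edits are applied jointly to the transcript coding sequence and
affected codons are retranslated (standard genetic code; coordinates
1-based inclusive everywhere, matching VCF and HGVS). Naive annotations
apply each member alone. Effects are classed as synonymous,
stop_retained, missense, stop_gained, stop_lost or start_lost. Protein
strings follow the three-letter, `*`-for-stop style of clinical reports:
`p.Leu280Phe`, `p.Ser356Ser`, `p.Ser421*`, `p.*396*`, `p.*396Trpext*26`.
Start-codon disruption reports `p.Met1?` without attempting
downstream-ATG rescue.

For a lost stop codon the extension length `N` in `ext*N` is the 1-based
index, counted in codons immediately after the original stop, of the first
in-frame stop in the transcript's downstream (post-stop) sequence. This
counting convention makes a stop in the very next codon `ext*1`; it is
exercised against downstream sequences constructed with stops at known
distances 1–10 and reproduces the printed extension on the bundled
stop-loss fixture. When no in-frame stop is reachable the string degrades
to `ext*?` rather than failing.

### Discordance grading

Each effect class carries a severity rank, supplied as configuration
(`DEFAULT_SEVERITY`): synonymous and stop_retained 1, missense 2,
stop_gained / stop_lost / start_lost 4. The ranking generalises a
dominant, loss-of-function testing model: rank-4 outcomes are the ones a
lab reports as likely pathogenic, missense is reportable-but-uncertain,
rank 1 is not reportable. A merged annotation more severe than every naive
annotation is a `false_negative_risk` (the per-SNV pipeline under-calls);
less severe, `false_positive_risk`; equal severity with a different
residue outcome, `changed_effect` (a missense-for-missense swap whose
clinical interpretation may go either way); `concordant` requires every
merged per-codon outcome to be reproduced by a naive annotation at that
codon. Under this rule a naive stop-gained beside a merged missense grades
as a false-positive risk — the consistent application of the ranking even
where no published implication is available.

## What the simulator emulates

The `simdata` functions generate the entire test bed in code:

* `simulated_mnv_fixture()` — five homozygous intra-codon MNVs (CTG→TTC, TAA→TGG
  at a stop codon, TCC→AGC, TCT→TGA, AAG→AGT) at the canonical coding
  positions c.838, c.1186, c.1066, c.1261 and c.1273 of two plus-strand
  multi-exon transcripts on one synthetic contig. Homozygous planting
  mirrors a GT 1/1 call with no reference-supporting reads. The
  stop-carrying transcript's synthetic downstream region places its first
  in-frame stop 26 codons after the original stop, emulating the real
  3' UTR behaviour of the gene that motivated the fixture; the contig
  itself is synthetic and no external genome is needed.
* `clinical_mnv_fixture()` — four heterozygous cis MNVs (GCC→TTC, GAT→TCT,
  GAG→AGG, TAC→CAA) across three synthetic genes, one of them on the minus
  strand so strand handling is exercised end to end.
* `trans_fixture()` — a het pair planted on opposite haplotypes, which a
  correct phaser must refuse.
* `random_fixture(seed)` — random transcript layouts (either strand) with
  2–3-base codon changes at well-separated codons and random zygosity, for
  multi-seed recovery experiments.

Reads are single-end 150 bp at 30× template coverage, error-free by
default, with all-match CIGARs and MAPQ 60 — the read geometry is a
package choice, chosen so every planted span is comfortably covered by
many spanning templates. Error-free defaults make the truth set exact:
recovery below sensitivity 1 or any spurious merge is then a genuine
defect, not noise. Fixture generation is pure: the same spec and seed
yield byte-identical outputs.

What the simulator does *not* model — and hence what passing tests do not
demonstrate about real data: sequencing errors and quality-score
distributions (an `error_rate` knob exists but defaults to 0), alignment
artefacts (soft clips, indels, mismapping around repeats), duplicate
reads, strand bias, and allele-specific coverage. Real-data performance
depends on the upstream caller and aligner; the package's claims are about
correct post-processing of calls whose reads are available.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in every interface.
* Codons spanning exon junctions are assembled by concatenating CDS bases
  in transcript order; minus-strand transcripts are reverse-complemented
  into coding orientation before any codon logic runs.
* A merged record is checked base-by-base against the reference FASTA; a
  VCF/FASTA disagreement aborts with an explicit message rather than
  emitting a wrong allele.
* Ambiguous bases (N) in a codon make translation an error, not a silent
  `X`; untranslatable fixtures are a bug by construction.
* A cluster outside every supplied transcript CDS is still merged (phase
  permitting) but reported as `noncoding` with no HGVS strings.
* Empty inputs degrade gracefully: a wild-type VCF produces a header-only
  report and a merged VCF semantically identical to the input.
* Re-running the pipeline on its own output merges nothing further, since
  delins records are no longer SNV calls (idempotence).

## Test problem sizes

The suite runs entirely from generated data: coordinate mapping is checked
against an exhaustive CDS walk on random multi-exon transcripts of both
strands; clustering against an O(n²) transitive-closure oracle on random
site sets; joint annotation against a whole-protein retranslation oracle
(independent translation implementation) on 1,000+ random codon/edit
cases; planted-MNV recovery on 20 random fixtures (sensitivity 1, zero
spurious merges required); and the two bundled fixtures reproduce their
expected HGVS strings byte-for-byte. These sizes were chosen to exercise
every branch several hundred times while keeping the default test run
fast.

## Known limitations

* Only substitution MNVs are handled; SNV+indel events are out of scope,
  as are splice-site, UTR and regulatory consequences and any
  pathogenicity scoring or population-frequency lookup.
* Phase comes from physical read overlap (or hom/hom logic) only; there is
  no statistical or pedigree phasing, so het pairs farther apart than the
  template length remain `unphased_no_reads` candidates.
* One genetic code (the standard table) is implemented; selenocysteine
  recoding and annotated frameshifts are not.
* Multi-codon MNVs produce a single delins `c.` string and a compound
  `p.[...;...]` description; only intra-codon cases are exercised by the
  bundled fixtures.
* The transcript model is CDS-only; UTR-anchored HGVS positions (`c.-n`,
  `c.*n`) are not emitted.
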