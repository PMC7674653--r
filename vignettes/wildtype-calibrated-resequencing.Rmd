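---
title: "Wild-type-calibrated variant filtering for clonal bacterial resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wild-type-calibrated variant filtering for clonal bacterial resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a clonal bacterial strain is mutagenised and its offspring are
resequenced against the parent ("wild-type") genome, the biological signal
is tiny — often a handful of SNPs, a few short indels and occasionally a
copy-number change per strain — while a standard short-read calling chain
(trim, map, deduplicate, pileup, call) emits tens of raw candidate
variants per strain. Most of the excess is systematic: mapping artifacts
near repeats and coverage anomalies that recur in every sample sequenced
on the same platform against the same reference.

The idea implemented here is to *calibrate the filter on known false
positives*. The wild-type strain is resequenced in the same run and called
against **its own** assembly; every resulting call is false by
construction. Those false calls define an empirical null, and two summary
statistics of that null become filter thresholds for the mutant calls:

* **relative coverage** — site depth divided by the strain's genome-wide
  mean depth. A mutant call passes only if its relative coverage is
  *strictly greater* than the highest relative coverage seen among the
  wild-type false calls (default 0.259, the published calibration for a
  *Clostridium beijerinckii* NRRL B-598 resequencing run);
* **population fraction** — the fraction of reads at the site supporting
  the alternate allele. A call passes only if this fraction is *at least*
  the threshold (default 0.308, same provenance).

In addition, any mutant call whose (position, ref, alt) also appears in
the wild-type call set against the reference is subtracted outright
(`shared_with_wt`). Filtering is identical for SNVs and short indels, and
no multiple-testing machinery is layered on top: the method is a
deliberate empirical max-rule, not an FDR model.

### Reading "population fraction" as read fraction

The source description speaks of variants "called in a fraction of the
population". Reads drawn from a clonal culture sample individual cells,
so the alternate-allele read fraction at a site is the natural estimator
of the fraction of the population carrying the variant, and it is the
only quantity computable from a single pooled sequencing run. The package
therefore implements the population-fraction rule on `alt_count / depth`.

### Calibration uses the maximum, not a quantile

`calibrate_thresholds()` takes the *maximum* relative coverage and the
maximum alternate fraction over the wild-type false calls. Because the
coverage comparison is strict ("more than") while the fraction comparison
is inclusive ("at least"), re-applying calibrated thresholds to the very
call set that produced them passes zero calls — the maximal false
positive itself fails. This self-consistency is asserted in the test
suite. When the wild-type self-run produces no calls at all (the usual
case for a clean simulated run), the published fallback pair
(0.259, 0.308) is used unchanged.

## The pipeline and its assumptions

`run_pipeline()` chains the stages in the order a practitioner would run
them: simulate (or load) reads → quality-trim → map → mark duplicates →
pileup → raw calling → calibrate → subtract shared → threshold → CNV
detection → codon-level annotation → cross-strain comparison.

Key design commitments, in the package's own terms:

* **Coordinates are 1-based inclusive everywhere** — sequence positions,
  gene intervals, variant tables, CNV calls. The only conversion happens
  at the BED boundary (0-based half-open), in `write_bed()`. This makes
  `size = end - start + 1` hold for every reported interval and removes
  the likeliest silent-bug class in genomic bookkeeping.
* **References are linear.** Real bacterial chromosomes are circular, but
  at the scales simulated here origin-spanning fragments are irrelevant;
  the simulator never emits them and the mapper never wraps.
* **Clonal haploid samples.** The caller emits at most one alternate
  allele per site (highest count, ties to the lexicographically smallest
  allele); genotype likelihoods are meaningless at these allele fractions
  and are not modelled.
* **Raw calling is permissive by design** (`min_depth = 10`,
  `min_alt_count = 3`, `min_alt_fraction = 0.10`): the two-stage logic
  requires the calibrated filter, not the caller, to remove noise. This
  reproduces the characteristic raw-versus-filtered count gap the method
  was designed around.
* **Indels are left-normalised.** Indels in repetitive context admit
  several equivalent anchored encodings; both the caller and the
  truth-table generator canonicalise through `normalize_variant()`, so
  parameter-recovery comparisons are representation-independent. Short
  indels are restricted to ≤ 10 bases in the simulator; anything longer
  must be expressed as a duplication or segment deletion and is the CNV
  detector's job.

## The mapper

`map_reads()` is a k-mer seed-and-extend aligner: exact 21-mer seeds at
the read start, middle and end vote by diagonal on both strands;
candidate placements are extended ungapped, and when the mismatch count
exceeds `max_mismatches` (default 6 per 150-base mate, generous for a
0.5% error rate) a banded single-indel alignment (band 10) attempts to
recover short indels. A gapped alignment is accepted only when it
resolves at least three mismatches and keeps at least six aligned bases
on each side of the gap — a cheap guard against spurious end-of-read
indels. Reads whose two best placements tie are flagged ambiguous and
excluded from pileups, mirroring the common practice of dropping
mapping-quality-zero reads without modelling a full MAPQ. There is no
soft-clipping, no split-read logic and no rescue of repeat-induced
multi-mappers; the ambiguity rule handles them conservatively.

Duplicate marking groups pairs by both mates' 5' coordinates plus
orientation and keeps the pair with the highest summed base quality —
the standard optical/PCR-duplicate criterion at pair resolution.

## Copy-number detection

`detect_cnv()` is purely depth-comparative: per window,
`(mutant depth / mutant mean) / (wild-type depth / wild-type mean)`.
Detection is a two-threshold segmentation: a call needs a *seed* of at
least `min_windows` (default 5) consecutive windows beyond the full
threshold (`gain_min = 1.75`, `loss_max = 0.25`; seeds separated by at
most one window merge), and the seed then *extends* across windows beyond
the midpoint between the threshold and 1 (1.375 for gains, 0.625 for
losses). The two-threshold form matters in practice: a tandem duplication
in a genome of length L inflates the mutant's genome-wide mean, so the
expected in-event ratio is not 2.0 but `2L/(L + s)` for a duplication of
size s (≈ 1.85 at the simulated scales), and single windows of sampling
noise would otherwise fragment one event into several calls. Boundaries
are then refined to base resolution by scanning the per-position ratio
outward from the run edges until it crosses the same midpoint, and the
reported copy ratio is the median window ratio over the call.

Two consequences are worth knowing. First, a deletion's boundaries are
recovered with a "shoulder": reads cannot span the deletion junction, so
coverage ramps down over roughly a read length on each side and the
refined interval slightly over-covers the true one. Second, losses
shorter than `min_windows x window` cannot seed at the default window
(100 bases); the fine-window mode (window 25, `min_windows` 4) exists for
changes in the 150–800 base range, at the price of noisier windows.
Assembly-based evidence (re-assembly, discordant pairs) is deliberately
out of scope — this detector is a stand-in for that class of tools, not a
re-implementation.

## Effect annotation

`annotate_variants()` assigns each call to its containing feature (gene
intervals are required to be non-overlapping; ambiguous containment is an
error, not a guess) and classifies coding SNPs by extracting the affected
codon in coding orientation, substituting the alternate base and
translating both codons with the bacterial/archaeal genetic code
(translation table 11; stop is `*`). Effects are `synonymous`,
`missense`, `nonsense`, `stop_lost` for SNPs; indels are `frameshift`
or `inframe_indel` by length arithmetic, with amino-acid fields left
empty. Pseudogenes are annotated *as if coding*, taking the frame from
the annotated interval — the source variant catalogue reports amino-acid
changes inside pseudogenes, and this is the only convention that
reproduces them. rRNA/tRNA features get `non_coding_gene` with no amino
acids; printed amino-acid letters for rRNA records in the source
catalogue are annotation-pipeline artifacts and are deliberately not
reproduced. No start-codon special-casing is applied: annotated CDSs are
assumed in frame from their first base.

## Cross-strain comparison

`build_binary_matrix()` reduces each strain's passing variants to a
gene-level 0/1 matrix (intergenic records are excluded; CDS, pseudogene
and rRNA/tRNA loci all count, and an indel marks its locus exactly as a
SNP does). "Binary distance" is the asymmetric binary measure
`(b + c)/(a + b + c)` — the Jaccard complement — which is the
conventional meaning of the term in statistical clustering; a
simple-matching variant is exposed as an option. `complete_linkage()`
implements the standard maximum-update agglomeration with a fully
deterministic tie-break (lexicographically smallest pair of cluster
labels, clusters represented by their smallest member label). Leaf order
is a rendering convenience, not an analysis result: distance ties make it
convention-dependent, so only merge heights and cluster memberships are
asserted anywhere.

## What the simulator emulates — and what it does not

`generate_genome()` + `inject_mutations()` + `simulate_reads()` emulate a
sized-down version of the study conditions: an annotated bacterial
chromosome; mutants carrying 1–20 SNPs, a few ≤ 10-base indels, one
multi-kb tandem duplication and one 150–800 base deletion; 150-base
paired-end reads at 115–221× coverage (default 150×, the range midpoint)
with per-base Phred qualities from a truncated normal centred at Q35
(sd 3, clamped to [2, 41]) and independent substitution errors (default
0.5%). Fragment lengths are normal (mean 300, sd 50), fragment starts
uniform.

Deliberate omissions: no PCR-duplicate excess, GC bias, quality-by-cycle
decay, adapter contamination, indel sequencing errors, or coupling
between quality and error. Real data's false-positive structure —
mapping artifacts at repeats, which is precisely what the published
calibration run captured — is largely absent from a random genome, which
is why a clean simulated wild-type self-run usually yields zero false
calls and the calibration falls back to the published thresholds. Passing
the parameter-recovery tests therefore demonstrates that the machinery is
correct and the filter behaves as specified, *not* that the thresholds
would transfer to any particular real platform; on real data the
calibration must come from the user's own wild-type self-run, which is
exactly what the interface encourages.

## Problem sizes and numerical choices

The test suite runs the full chain at a 100 kb genome, 30 genes, 120×
coverage, 15 SNPs + 2 short indels + one 8 kb duplication + one 759-base
deletion — large enough that window statistics and allele fractions are
in the regime the method assumes, small enough to run comfortably on one
CPU; unit tests use 4–30 kb genomes. Degenerate inputs are handled
explicitly: empty read sets, zero-variant call sets, all-zero binary
vectors (distance defined as 0 with a warning), zero-depth wild-type
windows (masked from CNV ratios), and features that an imported GFF3
might overlap (location queries raise an error rather than guessing).

## Known limitations

* The mapper targets functional equivalence with production aligners,
  not bit-level agreement; it has no MAPQ model and drops, rather than
  rescues, ambiguous reads.
* Depth-only CNV detection cannot see copy-neutral rearrangements,
  dispersed duplications, or novel insertions, and resolves breakpoints
  only to the coverage shoulder.
* The population-fraction threshold is a read-fraction surrogate; at
  extreme coverage imbalance it is a biased estimator of the true
  population fraction.
* Whether the published 30.8% figure was itself a maximum over wild-type
  false-positive fractions is not documented in the source; the package
  treats the strictness conventions (strict for coverage, inclusive for
  fraction) as stated wording and documents them rather than claiming
  provenance.
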