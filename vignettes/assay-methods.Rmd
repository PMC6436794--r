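---
title: "Methods: a targeted cytochrome-b eDNA assay for invasive carps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a targeted cytochrome-b eDNA assay for invasive carps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpassay)
```

## The problem

Silver carp (*Hypophthalmichthys molitrix*) and bighead carp
(*H. nobilis*) are invasive planktivores advancing toward the Laurentian
Great Lakes. Environmental DNA (eDNA) metabarcoding can reveal their
presence in water samples - for example from bait-shop tanks - without
capturing a fish. `carpassay` implements a complete targeted assay for this
purpose: a short, diagnostic mitochondrial cytochrome-*b* amplicon is
sequenced at high depth from many multiplexed libraries, reads are filtered
and denoised into amplicon sequence variants (ASVs), a detection cutoff is
calibrated from sequenced positive controls, and surviving ASVs are assigned
to species and intraspecific haplotypes.

The package has five coupled parts:

1. **Haplotype panel** - parse a variant-key table (haplotype x
   gene-position substitutions relative to a reference haplotype),
   reconstruct full-length sequences on a backbone, compute Hamming
   distances, and collapse haplotypes into the equivalence classes the assay
   can actually discern.
2. **Amplicon tools** - IUPAC degenerate-primer matching and in-silico PCR.
3. **Read pipeline** - spacer/primer verification, overlap merging,
   dereplication, Poisson denoising, chimera removal.
4. **Calibration and assignment** - positive-control cutoff, no-template
   control (NTC) checks, Hamming best-match assignment, below-cutoff
   divergence flagging.
5. **Simulator** - seeded synthetic backbones, mock controls and full runs
   with truth tables, so every stage is testable without any downloads.

## The haplotype key and the diagnostic window

The packaged key (`silver_carp_variants()`) covers the eight North American
silver carp haplotypes A-H over 58 variant positions (47 in a 1141 nt
cytochrome-*b* gene, 11 in a 1551 nt COI gene). Coordinates are 1-based and
gene-relative. Haplotype H is a highly divergent lineage attributed to
historic introgression from largescale silver carp (*H. harmandi*); it
differs from the reference haplotype A at 48 sites, while B-G differ at 1-9.

The assay amplifies a 135 nt cytochrome-*b* insert with a degenerate primer
pair (forward degeneracy 48, reverse 16). We place the insert at cytb
**115-249** with the reverse primer occupying 250-272. This one-base shift
relative to the naive reading of "begins at nt 114" is deliberate: with the
insert at 115-249 the reverse primer's single degenerate R position falls
exactly on the polymorphic site 258, whose two observed alleles (A in most
haplotypes, G in haplotype H) are precisely the two bases R matches. Under
the 114-248 reading the primer site would conflict with the reference allele
at 258 and could not bind any haplotype exactly. The window's variable sites
(117-228) and hence all windowed distances and classes are identical under
either reading; only the reported coordinates differ.

Within that window the assay cannot separate A from C (their only
difference, cytb 864, lies outside) nor F from G, giving the class partition
`A/C, B, D, E, F/G, H`:

```{r classes}
vt <- silver_carp_variants()
amp <- amplicon_definition()
backbone <- make_backbone(vt, amp, seed = 11)
panel <- reference_panel(reconstruct_haplotypes(vt, backbone))
collapse_classes(panel, diagnostic_window())
```

Reconstruction requires a backbone sequence. Real gene sequences can be
supplied as FASTA; for self-contained analyses `make_backbone()` builds a
seeded pseudorandom backbone that installs the reference alleles at their
variant positions and concrete primer expansions at the flanking sites, so
that in-silico PCR, simulation and assignment are exact by construction.
Positions never mentioned by the key are arbitrary, which is irrelevant to
every windowed quantity but means full-length distances to *external*
sequences are not meaningful in fixture mode.

## Read model and verification

Each library's reads are expected to read, 5' to 3':
`spacer + primer + template`, with read 1 carrying the forward primer and
read 2 the reverse primer on the opposite strand. Spacers are short
library-specific sequences between the sequencing adapter tail and the
template primer; because a read mis-assigned to another library by index
hopping keeps its original spacers, an exact spacer comparison doubles as a
hop filter. Verification therefore proceeds:

* **spacer**: exact match, no tolerance (`spacer_mismatch` on failure);
* **primer**: IUPAC-aware match with up to `primer_mismatch` (default 2)
  mismatches (`missing_primer`);
* **length**: after trimming, each mate must carry at least
  `ceiling((insert + min_overlap)/2)` nt of template - 78 nt for the 135 nt
  assay - the smallest mate length at which a pair can still span the full
  insert with the required overlap (`bad_length`; primer dimers at ~20-40 nt
  fail by a wide margin). A naive floor of "insert length minus a small
  tolerance" would be impossible: a 150 nt mate minus a 7 nt spacer and a
  26 nt primer carries at most 117 nt of a 135 nt insert;
* **ambiguity**: any N in the template rejects the pair (`ambiguous_base`),
  keeping ASVs strictly ACGT.

Merging aligns the mates at the best ungapped overlap of at least
`min_overlap` (20) nt with mismatch fraction at most `max_overlap_mismatch`
(0.1), preferring the lowest mismatch fraction and, at ties, the larger
overlap. Disagreements resolve to the higher-quality base (qualities are
phred+33; agreements keep the maximum). Merged sequences must hit the insert
length exactly (`merged_length_tol = 0`) - the assay has a fixed-length,
indel-free amplicon, so the post-merge length check is the authoritative
length verification. Every rejection is tallied in a per-sample ledger whose
rows always balance: raw = verified + rejections, verified = merged +
merge rejections.

## Denoising and chimera removal

Dereplication groups identical merged sequences (100% identity) with
per-sample counts. Denoising then asks, for each ASV in descending pooled
abundance, whether its count is explicable as sequencing error off a more
abundant "parent". With per-base error rate `e` over length `L`, a specific
read of a parent with pooled count `N` is misread into one specific sequence
at Hamming distance `d` with probability `(e/3)^d (1-e)^(L-d)`, giving an
expected error count

&nbsp;&nbsp;&nbsp;&nbsp;lambda = N (e/3)^d (1-e)^(L-d).

The minor ASV is kept as real only when the Poisson upper tail
P(X >= k | X >= 1) <= `alpha` under the most plausible parent (the one
maximising lambda). Two details matter:

* the tail is **conditioned on the variant being observed at all**.
  Unconditioned, any singleton at distance >= 3 from its parent is
  "significant" (its lambda is ~1e-6), so sequencing junk with one read
  would survive; conditioning makes singletons never significant, which is
  also how established ASV denoisers behave.
* absorbed counts are **added to the parent**, not discarded, so read
  totals are conserved and class fractions are not deflated.

Passes repeat until a fixed point, making the operation idempotent.
`e` is the platform's assumed substitution rate (default 0.001; set it to
the platform's known rate - the denoiser has no error-learning loop, by
design), and `alpha` defaults to 1e-4.

A bimera test follows: an ASV is removed when some breakpoint splits it into
a perfect prefix of one ASV and a perfect suffix of another, both at least
`chimera_fold` (2) times more abundant and neither identical to it. This is
detected in O(parents) per ASV via longest-common-prefix/suffix lengths.

## Calibration, assignment and flagging

Each run carries positive controls - mixtures of known taxa (the field
protocol used ten Sanger-verified marine fish; the simulator's
`mock_control_inserts()` emulates them). Any control ASV not exactly
matching an expected sequence is erroneous; the **largest single erroneous
ASV fraction across the run's controls becomes the detection cutoff**. An
ASV in a field sample is retained iff its fraction of the sample's merged
reads is >= the cutoff (the boundary is retained; a clean control yields
cutoff 0). NTCs pass only when their verified-read count is <=
`ntc_max_reads` (0): raw reads that all fail verification - hops, dimers -
do not fail an NTC.

Assignment is Hamming best match against the panel's insert table: on a
fixed-length 135 nt locus this is equivalent, for panel taxa, to a
best-e-value search against a regional reference database, while removing
the external-database dependency; user FASTA panels can be imported to
extend coverage. Distance 0 is a `known` haplotype,
reported as its window class; a distance in (0, `novel_max` = 2] with a
unique best species is a `novel` intraspecific haplotype (the motivating
cases are novel silver carp haplotypes one substitution off haplotype B);
equal best distance to two species is `ambiguous` and never silently
resolved; anything farther is `unassigned`.

Below-cutoff ASVs are not silently deleted. One that assigns to a panel
species *and* lies more than 10% of the insert length (> 13.5 nt for 135)
from **every** retained ASV in its sample is too divergent to be an error
off anything present, and is flagged `below_cutoff_flagged` as a putative
detection requiring confirmation. The motivating case is a bighead carp
haplotype observed below cutoff at 14 and 15 nt from the retained silver
carp ASVs; note 14 clears a >13.5 floor but would not clear a ceiling-based
">14" rule, which is why the floor is the exact fraction, not its ceiling.
All positive detections carry `requires_confirmation`: the assay design
confirms positives by re-sequencing on a separate run with non-shared
spacers, and the re-run itself is out of scope here.

## The simulator and what it does (not) emulate

`simulate_run()` emits per-library gzip FASTQ pairs plus a truth table.
Reads are 150 nt per mate (spacers 7 nt), guaranteeing a 102 nt overlap on
the 135 nt insert. It models: per-base substitution error at a configurable
rate (errors get Q15, correct bases Q35, so merge tie-breaking is
exercised); index hopping (a read lands in another library, keeping its
origin spacers); primer dimers (short templates); and two-parent chimeras
spliced at a uniform breakpoint. NTC libraries emit only dimers and received
hops. A fixed seed reproduces the output byte for byte.

It does **not** emulate instrument quality-by-cycle decay, indels,
context-dependent error, PhiX spike-ins, PCR amplification bias, or
abundance-to-biomass relationships. Passing tests therefore demonstrate the
pipeline's correctness under a substitution-only, fixed-length error model -
not performance on any particular instrument run.

The synthetic bighead insert (`synthetic_bighead_insert()`) is a labelled
stand-in, not a GenBank sequence: haplotype A's insert with transitions at
14 fixed positions chosen outside the silver variant sites, reproducing the
assay-region divergences reported for the real haplotype (14 nt to silver A,
15 nt to silver B) by construction.

## Test and acceptance problem sizes

The test suite reconstructs the full panel, checks every distance against a
position-by-position oracle, and runs simulated runs of 300-3,000 read
pairs per library for filter, ledger and determinism properties. The
replicated recovery study uses 20 seeded runs of 5,000 field reads plus
1,000 positive-control reads at a per-base error rate of 0.005 (with the
denoiser's assumed rate set to match), asserting class-fraction recovery
within 3 percentage points and perfect species-level precision and recall.
Denoiser and chimera decisions are cross-checked against brute-force oracles
on tables of up to 10 ASVs.

## Known limitations

* Assignment assumes the fixed-length locus; indel-bearing variants would be
  `unassigned` rather than aligned.
* The denoiser's single global error rate is an approximation; it has no
  per-position or quality-aware error model.
* Calibration is per run, pooled over that run's positive controls; a run
  without controls cannot set a cutoff.
* Full-length (outside-window) distances are only meaningful when real
  backbones are supplied.
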