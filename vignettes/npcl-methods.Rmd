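---
title: "Methods and design of the NPCL marker pipeline"
author: "NPCLtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the NPCL marker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices and the known limitations of `NPCLtools`. It is the place where
every genuinely open design decision is recorded with its rationale.

## The marker-development model

Universal NPCL (nuclear protein-coding locus) markers are long exonic loci
that (i) occur exactly once in the genome, (ii) are conserved enough across
the clade of interest that one primer pair amplifies them everywhere, and
(iii) evolve slowly relative to mitochondrial references. The pipeline
operationalizes each requirement:

- **Length**: only exons strictly longer than 600 bp enter the candidate
  set (`mineExons(minLen = 601)`), so that a 700–1200 bp amplicon fits
  inside a single exon and no intron interrupts the PCR product.
- **Single copy**: an exon is single-copy iff its only within-genome
  alignment hit with identity > 0.80 and query coverage > 0.50 is its own
  locus. The published protocol does not state its duplicate criterion;
  we reuse the orthology thresholds so one homology rule governs both
  scans, which keeps the filter interpretable and testable. The self-hit
  is recognised by > 50 % genomic overlap with the exon's own span.
- **Cross-genome conservation**: the best hit in the query genome (both
  strands; ties broken toward the lower subject coordinate) must exceed
  both thresholds *strictly* — "more than 80 %" excludes exactly 0.80.

### The internal aligner

Searching a genome with each exon is done by an internal BLASTN-like
aligner (C++): exact k-mer seeds (default k = 11) are grouped into
diagonal bands (pad 32 diagonals), and each band is solved by a banded
affine-gap local dynamic program with row-level X-drop termination
(default X = 20). Scoring defaults are match +1, mismatch −2, gap open −5,
gap extend −2 (a length-g gap costs `open + g·extend`). Because the banded
search space is a strict subset of the full dynamic program, the reported
score can never exceed the Smith–Waterman optimum under the same scheme —
the test suite asserts this against an exact implementation from an
independent library, together with identity agreement within ±0.03 on
≤ 1 kb pairs. Identity is `matches / alignment columns` (gap columns count
in the denominator); coverage is alignment columns over template length,
capped at 1 so the rare gapped alignment cannot report coverage above 1.
Word size and E-value of the original BLAST runs are not recoverable from
the published protocol; the defaults above are this package's own choices
and all of them are configurable.

## Primer design

Single-primer constraints: length 18–25 nt, GC fraction 0.20–0.80
(inclusive bounds, computed as (#G + #C)/length), self-complementarity
< 6.00 and 3′-anchored self-complementarity < 3.00. The complementarity
score is the maximum over all antiparallel ungapped offsets of
(+1 per Watson–Crick pair, −1 otherwise), floored at zero; with 3′
anchoring only offsets covering the primer's 3′-terminal base count. The
+1/−1 weights put the score on the same integer scale as the published
thresholds (< 6.00, < 3.00), which is the simplest scheme consistent with
them; full Primer3 thermodynamic parity is a non-goal. Melting temperature
is reported from `Tm = 64.9 + 41(nGC − 16.4)/L` and never filtered on,
because the protocol filters only length, GC and complementarity.

Pairs must give an inclusive product (forward 5′ start to reverse 5′ end
on the template) of 700–1200 bp and a pair 3′ score < 3.00 (either primer
anchored). Ranking is by **conservation score** — the fraction of
identical aligned template/query columns inside the union of the two
primer windows, gaps counting as mismatches — then product length closest
to 950 bp, then leftmost forward start; residual ties fall back on primer
lengths and the reverse window position so the order is total. The
conservation formula itself is a design decision: the published protocol
selects "the most conserved" pair without printing a formula, and
per-site identity over the binding sites is the simplest score that
preserves that selection intent. A window not covered by the alignment
has undefined conservation and ranks below every scored pair.

Full forward × reverse enumeration is combinatorial (millions of pairs on
a 1–2 kb locus), so `designPairs()` caps each side at
`maxCandidatesPerSide` (default 200) primers chosen by per-window
conservation — forward ties prefer the leftmost start, reverse ties the
rightmost, keeping the two capped sides product-compatible — and returns
the top `maxPairs` (default 100) ranked pairs; if a cap leaves no
in-range pair it is enlarged ×4 until pairs appear or enumeration is
exhaustive. Unit tests operate below the caps, where enumeration is
exhaustive and checked for set equality against a brute-force oracle.

## Distances and rate calibration

`overallMeanDistance()` is the mean over all unordered pairwise distances;
models are p-distance, JC69 (`−¾ ln(1 − 4p/3)`) and K2P
(`−½ ln((1 − 2P − Q)√(1 − 2Q))`). The published analysis names the program
but not the model; the default here is the p-distance (that program's own
default for overall mean distances) with the corrected models selectable —
transparency was preferred over guessing a correction. Columns containing
N or '-' are deleted *per pair* (complete deletion can be emulated by
pre-filtering columns); a pair with no comparable sites, or a saturated
pair where a model's log argument is ≤ 0, is an error by default and can
be dropped with a warning (`onUndefined = "drop"`).

The standard error comes from bootstrapping alignment columns: 1000
replicates by default, one seed governing all replicate draws, each
replicate an independent column-index resample. Internally replicates are
evaluated as weight-matrix products over per-pair per-column indicator
matrices, in blocks of 250 replicates, which makes the 1000-replicate
default cheap even on multi-kilobase alignments.

Rates are calibrated as `mu = (d_locus / d_cytb) × mu_cytb` with
`mu_cytb = 0.01035` substitutions/site/million years, the standard avian
cytochrome-b rate. All outputs are substitutions/site/My. Note that some
published rate figures for this kind of analysis are printed as
"×10⁻⁸ per site per million years" while the cyt-b calibrator equals
1.035 × 10⁻⁸ per site per *year*; the two conventions are mutually
inconsistent and cannot be reconciled from the text, so this package
reports /site/My throughout and leaves the discrepancy documented rather
than forcing agreement.

## Polymorphism and neutrality

`popgenSummary()` computes S (columns with ≥ 2 distinct A/C/G/T bases;
gap/N excluded per column), H (distinct haplotype strings), Nei's
`Hd = n(1 − Σp²)/(n − 1)`, the mean pairwise difference count k̂ under
pairwise deletion, and `π = k̂ / L_used` with `L_used` the mean number of
comparable sites per pair — the common defaults of the standard
polymorphism software this mirrors. Tajima's D uses the 1989 constants
(`tajimaConstants()`); D is undefined (NA) for monomorphic loci and
requires n ≥ 4. Inputs are **phased haplotype alignments** (two per
diploid for nuclear loci, one for mtDNA): phase resolution from
chromatograms is upstream of this package.

The HKA test is implemented in the one-species + divergence form
(polymorphism within the focal species versus divergence to an explicit
outgroup), the form population software commonly exposes. Per locus i
with per-site θᵢ and scaled divergence time T:
`E[Sᵢ] = θᵢ a1(nᵢ) L_poly`, `Var[Sᵢ] = E[Sᵢ] + (θᵢ L_poly)² a2(nᵢ)`,
`E[Dᵢ] = θᵢ L_div (T + (nᵢ+1)/(2nᵢ))`, and
`Var[Dᵢ] = E[Dᵢ] + (θᵢ L_div (nᵢ+1)/(2nᵢ))²` — the 1987 two-species
variance with its (1+f)/2 coefficient mapped onto the sample-vs-outgroup
coefficient (n+1)/(2n) that the expectation uses. Parameters minimize the
X² sum directly (L-BFGS-B on log parameters; Watterson-based starting
values plus one perturbed restart; the optimum is validated against a
refining grid search to ~10⁻⁴ in the tests). Degrees of freedom are
2L − (L + 1) = L − 1, so at least two loci are required. Exact numeric
parity with any particular desktop implementation is not promised;
correctness is defined by the 1987 moment equations and the grid-search
oracle. Both per-site and per-locus θ̂ are reported.

## Supermatrix and trees

`concatenateLoci()` builds the partitioned supermatrix (taxa missing a
locus are gap-padded; duplicate taxa within one locus are an error) and
both the raw and gap-stripped column counts are available
(`supermatrixLengths()`), since published concatenation lengths do not
always say whether ambiguous columns were removed. Maximum-likelihood
inference is deliberately delegated: the package writes relaxed PHYLIP
and RAxML-style partition files, while the in-package, fully tested tree
method is neighbor joining (exact on additive matrices — asserted to
1e-8/1e-9 on random additive instances). Bootstrap supports resample
columns, rebuild the tree per replicate, and report per-split percentages;
the 70 % "strong support" threshold is stored as a flag, never a filter.

## What the simulators emulate — and what they do not

The genome-pair simulator emulates the template/query genome comparison:
uniform-random ancestral exons (default 800–1200 bp, comfortably above
both the 600 bp mining rule and the 700 bp product minimum), per-site
Jukes–Cantor substitution at divergence d (default 0.08, inside the 80 %
identity screen as the real songbird/fowl exon comparison is), planted
paralog copies at 5 % divergence, random spacer "introns" of 200–400 bp,
locus deletion probability 0.10 in the query, and ~30 % minus-strand
annotations. It does **not** model indels inside exons, repeats,
GC-content heterogeneity, codon structure or rate variation among sites —
so passing truth-recovery tests demonstrates the correctness of the
screening logic, not robustness to repeat-rich real genomes (where the
single-copy filter is doing the heavy lifting).

The coalescent sampler implements Hudson's algorithm without
recombination, on the scale where `E[S] = θ·a1(n)` and `E[k̂] = θ`;
mutations occupy distinct columns (an infinite-sites violation raises an
error rather than silently colliding). It does not model recombination,
migration or demography, so Tajima's D calibration checks the statistic
under the equilibrium null only. Seeding is hierarchical: a master seed
spawns per-locus child seeds, so any locus subset regenerates identically.

## Numerical and degenerate-input choices

- Coordinates are 1-based inclusive everywhere, the native GRanges/GFF3
  convention; adopting the host ecosystem's convention removes the
  off-by-one conversions that a 0-based internal scheme would need at
  every Biostrings call. Minus-strand exon sequences are stored 5′→3′
  after reverse complementation, so primer design always sees the sense
  strand.
- FASTA input maps any character outside A/C/G/T/N/- to N with a counted
  warning; readers never silently drop records.
- Sequences shorter than the seed length give an empty alignment result,
  not an error; an empty ortholog screen is a valid outcome.
- `calibrateRate()` refuses a zero cyt-b distance; p ≥ 0.75 under JC69 is
  an explicit saturation error.
- NJ requires a symmetric, zero-diagonal matrix with ≥ 3 taxa; tie-breaks
  inside the NJ implementation are those of the underlying library,
  deterministic for a fixed input order.
- All stochastic functions take explicit seeds and restore the caller's
  RNG state, so pipeline runs are reproducible end to end (the demo run
  writes a manifest recording every parameter's provenance: default,
  config file, or override).

## Problem sizes used by the test suite

The suite exercises the statistical claims at sizes chosen to make the
checks sharp yet quick on one core: Smith–Waterman comparisons on ≤ 1 kb
pairs; coalescent calibration with 5000 replicates (mean S at n = 10,
θ = 5) and 2000 replicates (mean Tajima's D at n = 20, θ = 5, expected in
(−0.2, 0.2)); bootstrap-SE scaling across alignment lengths 250/1000/4000
with 50 replicates per length; rate-recovery coverage over 100 simulated
locus/reference pairs (≥ 95 % within 3 bootstrap SEs); and full
truth-table recovery on a 50-locus genome pair with 5 paralogs and ~5
deletions at d = 0.08.

## Known limitations

- The aligner is nucleotide-space only (no translated search, chaining or
  masking); highly repetitive templates should be pre-masked upstream.
- Primer scoring is combinatorial, not thermodynamic: no secondary
  structure, no multiplexing, no degenerate bases.
- The HKA implementation requires an explicit outgroup divergence input;
  the two-species 1987 variant is not implemented.
- Enumeration caps in `designPairs()` mean the returned list is the top
  of the ranking, not the exhaustive pair set, on loci large enough to
  need the caps.
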