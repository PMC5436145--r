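---
title: "Quantifying histone variant H2A.J by mass spectrometry and ChIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone variant H2A.J by mass spectrometry and ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histvar)
```

# The problem

H2A.J is a replication-independently expressed H2A variant that accumulates
in senescent cells carrying persistent DNA damage, rising from about 1% to
about 10% of canonical H2A. It differs from canonical H2A species at only a
handful of residues — an Ala11Val substitution in the N-terminal tail and a
divergent, SQK-containing C-terminus — so quantifying it requires either
intact-mass (top-down) measurement or a diagnostic tryptic peptide
(bottom-up), and characterising its chromatin deposition requires ChIP-seq
read-level statistics rather than peak calling (its distribution is broad,
like bulk H2A). This package implements those four quantitative layers, plus
seeded simulators that generate inputs with the statistical structure each
layer assumes.

# Mass arithmetic and the proteoform registry

All numbering is relative to the initiator methionine (Met1). Intact
histones are modelled as *proteoforms*: a sequence, a Met1-cleavage flag
(mature intact histones default to cleaved), and a set of modification
offsets. Masses are residue-mass sums plus one water plus offsets; the
residue tables hold both monoisotopic and average values, with monoisotopic
the default because deconvoluted neutral masses from high-resolution
Orbitrap workflows are monoisotopic. Modification offsets are
elemental-composition sums: propionyl C3H4O (+56.026215 Da mono), acetyl
C2H2O, and the performic-oxidation products used when histones come from
tissue (Met sulfone +31.990, Cys cysteic acid +47.985 Da). "Mild" performic
treatment is not a fully specified chemistry, so the per-residue products
are configurable; the defaults take every Met to the sulfone and every Cys
to cysteic acid, the fully oxidised endpoints.

H2A species split chromatographically into two C18 fractions determined by
residue 52: leucine places a species in fraction H2A2, methionine in H2A1.
`classifyH2AFraction()` implements exactly that rule and refuses sequences
shorter than 52 residues.

The H2A.J sequence itself is obtained by translating the Flag-HA-tagged
*H2AFJ* coding sequence bundled in `inst/extdata` (the mature protein starts
at the internal ATG; 129 aa, Val11, Leu52). The canonical comparators in
`inst/extdata/h2a_canonical_synthetic.fasta` are best-effort reconstructions
of the named UniProt entries, labelled synthetic: they are guaranteed to
carry the residues the analyses key on (Ala11, the Gly5–Arg12 peptide
GKQGGKAR, Leu52 or Met52 as labelled) but should not be treated as
database-faithful at every other position. Nothing in the package asserts
their absolute intact masses against external values.

# Top-down quantification

`matchPeaks()` assigns each deconvoluted peak to the theoretical mass
minimising the absolute error, if within tolerance. The default tolerance is
1.0 Da absolute on the neutral mass — generous for isotopically resolved
intact ~14-kDa proteins but appropriate for deconvolution artefacts; a ppm
mode is available. Ties are broken to the lexicographically first label and
flagged ambiguous, so matching is deterministic. Species that are
indistinguishable by mass should be merged into one registry label upstream.
Several peaks may map to one label (adducts, satellite peaks) and are summed.

`relativeAbundance()` divides per-label intensity by the total intensity of
the spectrum's peaks, in percent; the unassigned remainder is reported
explicitly, so shares always sum to exactly 100. Abundances are therefore
*within-fraction* quantities — the H2A2-fraction share of H2A.J is not the
genome-wide fraction of all H2A, which is what the bottom-up layer measures.

# Bottom-up quantification

Propionylation of lysines before digestion blocks trypsin at Lys, giving
ArgC-like specificity; a second derivatisation round propionylates the new
peptide N-termini. `propionylDigest()` cleaves after every Arg not followed
by Pro (the no-P rule is standard and configurable), never after Lys, and
returns peptides that tile the sequence exactly, each carrying one propionyl
per Lys plus one N-terminal propionyl in its mass. Missed cleavages
(0–2, default 0) emit additional merged species.

`diagnosticPeptide()` digests a variant/canonical pair and returns the
unique same-span peptide pair whose sequences differ. Real histone pairs can
differ in more than one same-span peptide (some canonical H2As differ from
H2A.J at positions 17 or 40 as well as 11), so the function takes an
optional `region` restriction and errors informatively, listing the
differing pairs, when the choice is ambiguous. For H2A.J versus the bundled
type 1-C-like comparator the unique pair is Gly5–Arg12:
GKQGGKVR / GKQGGKAR. Because the propionyl offsets cancel on peptides of
identical Lys content, their mass difference is exactly the Val−Ala residue
difference, 28.0313 Da, which is what makes the pair resolvable and the
quantification clean.

`variantFraction()` is the area-ratio estimator
100·A_v/(A_v + A_c). It is scale-invariant and complementary
(f(a,b) + f(b,a) = 100); integrated chromatographic areas are consumed
as-is — XIC extraction is out of scope.

# ChIP-seq tag handling

Tags live in a `TagLibrary`: 1-based 5′-end positions per chromosome and
strand over an explicit genome (`Seqinfo`). BED6 is the ingestion format
(5′ end = start+1 for +, end for −; half-open 0-based at the file boundary,
1-based internally — both conventions are asserted in the tests). Duplicate
removal keeps one tag per (chromosome, strand, position); blacklist
filtering removes tags whose 5′ position falls inside an excluded interval.
5′-containment (rather than any-overlap of the full read) was chosen because
the library abstraction stores only 5′ ends; for typical blacklist interval
sizes (kilobases) the two rules differ negligibly. The two filters commute,
which the suite checks property-style.

Coverage tracks realise a "50-bp bandwidth" as a 51-bp centred box kernel
(bandwidths round up to odd), in RPM, with edge windows renormalised to
their effective width; a Gaussian kernel is available. Mass is conserved
away from chromosome ends.

# Strand cross-correlation

For each chromosome c with tags, the statistic correlates the plus-strand
5′-count vector with the minus-strand vector shifted by δ, over the overlap
x ∈ [1, L_c−δ], and averages across chromosomes with weights N_c/N:

c(δ) = Σ_c (N_c/N) · P[n_c⁺(x), n_c⁻(x+δ)].

Numerical choices: the shift grid defaults to 0–400 bp in 1-bp steps;
Pearson is computed over the truncated overlap only (no padding, so the
moments change with δ); chromosomes without tags are excluded from C, and a
zero-variance strand vector yields a flagged 0 contribution rather than an
error. The implementation is sparse — prefix sums over sorted tag positions
give the per-shift moments and a pair-difference tabulation gives the cross
term — making a 3×1-Mb, 50,000-tag profile a sub-second computation while
agreeing with a dense `cor()`-based double loop to 1e-12 (tested).

The fragment-length peak δ* is the argmax after excluding
|δ − readLength| ≤ 10 bp, the phantom peak caused by mapping artefacts at
the read length; ties go to the smallest shift, and the guard can be
disabled. `secondaryPeaks()` reports local maxima above the profile median
beyond the primary peak — on nucleosome-periodic chromatin these appear near
δ* + k·repeat (di-/tri-/tetra-nucleosome protection).

# TSS metagenes

`windowCounts()` counts tag 5′ ends of both strands in non-overlapping
60-bp windows tiling [−flank, +flank) around each TSS, mirrored for
minus-strand genes so column 1 is always the most upstream window, and
scales by 10⁶/N (RPM). The flank defaults to ±1,980 bp — 33 windows per
side, enough to see the TSS-proximal structure while keeping window maps
exact multiples of 60. Genes whose flank crosses a chromosome end keep
their row with out-of-bounds windows set NA and are flagged. A tag can be
counted in at most one window per gene, but nearby genes with overlapping
flanks will each count it — row sums can exceed N in dense annotations.

`log2EnrichmentProfile()` collapses gene × window matrices to per-window
means (median available) and returns log2((m_IP + ε)/(m_input + ε)) with
ε = 0.5 RPM by default — small against typical window means but enough to
keep empty windows finite. The profile is exactly 0 when IP = input and
antisymmetric under swapping the two. `stratifyByExpression()` makes
equal-count expression quantile bins with ties broken by gene id, so
stratified profiles are reproducible run to run.

# What the simulators emulate — and what they do not

Every generator is a pure function of its arguments including the seed (the
RNG state is saved and restored, so callers' streams are untouched), and
each returns its generating truth for parameter-recovery testing.

* `simDeconvolutedSpectrum()`: one peak per proteoform at theoretical mass +
  N(0, 0.2 Da), intensities proportional to shares times mean-1 lognormal
  noise (5% CV default) — the multiplicative noise convention for MS
  intensities. Not emulated: isotope envelopes, adducts, deconvolution
  harmonics, chimeric peaks.
* `simPeptideAreas()`: replicate area pairs around a true fraction (default
  10%, the senescent regime) with lognormal noise. Not emulated: retention
  drift, interference, saturation.
* `simTagLibrary()`: fragments centred uniformly (background) or at
  `enrichFold` times background density inside enriched intervals, snapped
  to a nucleosome lattice when a repeat is set; each fragment of length
  N(150, 10) emits a + tag at centre − len/2 and a − tag at centre + len/2,
  read length 50 bp — the defaults match the analysed libraries' designed
  regime. TSS depletion thins tag 5′ ends with a triangular kernel deepest
  at the TSS: the depletion the metagene measures is 5′-end density, and
  thinning fragment *centres* instead would displace the dip by half a
  fragment length (~89 bp) away from the TSS-adjacent windows, which is not
  the depletion geometry being modelled. The kernel is triangular rather
  than flat so the simulated nucleosome-depleted region is unimodal,
  mirroring the steep TSS-proximal dip seen in real profiles. Not emulated:
  mappability, GC bias, sequencing error, duplicate structure.
* `simTSSAnnotation()`: evenly spaced candidate slots (5-kb spacing, 2.1-kb
  end margins so default flanks never truncate), random strands, lognormal
  expression.

Passing parameter-recovery tests on these inputs shows the estimators are
correct and well-conditioned under their design assumptions; it does not
show robustness to the real-data artefacts listed above, which the study's
upstream tooling (aligners, duplicate markers) is responsible for removing.

# Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
desk scale: toy chromosomes (≤10 kb, ≤1,000 tags) wherever an O(L·δ) oracle
is compared exactly, and 3×1-Mb genomes with 50,000–200,000 tags for
parameter recovery — sizes chosen so the full suite completes in about a
minute while keeping the statistics (share recovery within 3 points,
fragment length within ±5 bp, dip localisation to one 60-bp window) sharply
testable. All stochastic checks fix their seeds; the acceptance script
derives every stream from its `--seed` argument.

# Known limitations

* Charge-state deconvolution, PTM localisation and MS/MS identification are
  upstream of this package; it consumes their outputs.
* Abundances are per-spectrum intensity fractions; cross-fraction totals
  are left to the caller, as chromatographic response differs by fraction.
* The canonical H2A panel is synthetic (see above); users with database
  access should substitute curated FASTA.
* NSC/RSC quality metrics and peak calling are out of scope for the
  cross-correlation layer, as are full gene-body metagenes for the TSS
  layer.
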