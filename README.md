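# histvar

Quantitative toolkit for histone-variant analysis, built around H2A.J — the
H2A variant that accumulates in the chromatin of senescent cells with
persistent DNA damage. H2A.J differs from canonical H2A only by an Ala11Val
substitution and a unique SQK-containing C-terminus, which makes it invisible
to most antibody reagents and hard to resolve by gel; mass spectrometry and
ChIP-seq are the assays that see it, and this package implements the
quantitative core of both:

* **Proteoform registry** — histone sequences numbered from Met1, CDS
  translation, intact monoisotopic/average masses with modification offsets
  (propionyl, acetyl, performic-oxidation products), and classification of
  H2A species into the two reverse-phase C18 fractions by residue 52
  (Leu52 → H2A2, Met52 → H2A1).
* **Top-down quantification** — matching deconvoluted neutral-mass peaks to
  theoretical proteoforms (nearest mass within tolerance, deterministic
  tie-breaks) and relative abundance as intensity fractions:
  share(i) = 100 · I_i / Σ_j I_j over the peaks of one spectrum.
* **Bottom-up quantification** — in-silico propionylation + tryptic digest
  (cleave after Arg, never before Pro, never after propionylated Lys),
  discovery of the diagnostic Gly5–Arg12 peptide pair
  (GKQGGK**V**R for H2A.J vs GKQGGK**A**R for canonical H2A, Δm = 28.0313 Da
  = Val − Ala), and the variant fraction
  100 · A_variant / (A_variant + A_canonical) from chromatographic areas.
* **ChIP-seq tags** — stranded BED6 ingestion (5′ end = start+1 on +, end on
  −), duplicate removal, ENCODE-style blacklist filtering, and 51-bp
  box-smoothed RPM coverage tracks.
* **Strand cross-correlation** — the chromosome-weighted statistic
  c(δ) = Σ_{c∈C} (N_c/N) · P[n_c⁺(x), n_c⁻(x+δ)], where P is the Pearson
  correlation of the strand-specific 5′-end count vectors over the overlap
  x ∈ [1, L_c−δ]; its peak (with a phantom-peak guard around the read
  length) estimates the mean fragment length, and secondary maxima at
  nucleosome-repeat multiples report di-/tri-/tetra-nucleosome protection.
* **TSS metagenes** — tag counts in non-overlapping 60-bp windows around
  TSSs, strand-oriented, RPM-normalised, collapsed to log2(IP/Input)
  profiles, with expression-quantile stratification.
* **Seeded simulators** for every input type, each returning the generating
  truth so analyses can be validated by parameter recovery.

## Worked example

Top-down: build a registry (H2A.J from the tagged *H2AFJ* coding sequence
shipped with the package, plus two canonical comparators), simulate a
senescent-like H2A2-fraction spectrum at 10/70/20 % and quantify it:

```r
library(histvar)
reg <- c(list(Proteoform(h2ajSequence(), label = "H2A.J")),
         lapply(canonicalH2APanel()[c("H2A1C", "H2A1")], Proteoform))
tab <- theoreticalMasses(reg)
round(tab, 3)
#>    H2A.J    H2A1C     H2A1
#> 13879.89 13937.89 13995.91
sim <- simDeconvolutedSpectrum(tab, shares = c(10, 70, 20), seed = 4)
relativeAbundance(sim$spectrum, matchPeaks(sim$spectrum, tab))
#>        label     share
#> 1      H2A.J  9.631496
#> 2       H2A1 19.353003
#> 3      H2A1C 71.015501
#> 4 unassigned  0.000000
```

The recovered H2A.J share (9.6 %) sits within noise of the generating 10 % —
the regime of senescent fibroblasts, where H2A.J rises from ≈1 % to ≈10 % of
canonical H2A.

Bottom-up: the diagnostic peptide falls out of the digest, carrying two
Lys-propionyl groups plus the N-terminal one:

```r
dp <- diagnosticPeptide(h2ajSequence(), canonicalH2APanel()[["H2A1C"]])
dp$variant[, c("start", "end", "sequence", "lysPropionyl", "mass")]
#>   start end sequence lysPropionyl     mass
#> 2     5  12 GKQGGKVR            2 996.5716
variantFraction(120, 1080)
#> [1] 10
```

ChIP-seq: simulate a 50,000-tag library with N(150, 10) fragment lengths on
three 1-Mb chromosomes and recover the fragment length:

```r
sim <- simTagLibrary(nTags = 50000, fragMean = 150, fragSd = 10, seed = 1)
strandCrossCorrelation(sim$library)
#> CrossCorrelationProfile: shifts 0-400 bp, 3 chromosome(s)
#>   fragment-length peak: 150 bp (c = 0.08037)
```

A thin command-line front-end over the same functions is installed at
`system.file("scripts", "histvar", package = "histvar")`, with subcommands
`registry`, `topdown`, `bottomup`, `tags`, `cc`, `metagene` and `simulate`.

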