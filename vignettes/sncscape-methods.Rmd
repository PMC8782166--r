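---
title: "sncscape methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sncscape methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the analysis models, the generative model behind the synthetic libraries,
every tunable parameter that matters, and the numerical choices made where
the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# The analysis problem

Compartment-resolved small RNA-seq of neurons (whole-cell somatodendritic
fractions, isolated axons, released extracellular vesicles, and the
axoplasm of adult nerves) produces libraries whose composition differs
radically between compartments: whole-cell libraries are dominated by
22 nt mature miRNAs, while axonal and EV libraries are dominated by
30–33 nt tRNA halves, and adult axoplasm adds a large rRNA-fragment
component. Summarizing such data requires (i) attributing each read to
one ncRNA feature and biotype, (ii) classifying tRNA-derived reads by
their position on the parental tRNA, (iii) guarding the piRNA biotype
against database entries that duplicate other ncRNAs, (iv) normalizing
libraries whose count distributions are heavily skewed, and (v) putting
numbers on how *unequal* (few species carry most reads) and how
*heterogeneous* (replicates disagree in composition) each repertoire is.

# Reference model and coordinates

A `ReferenceSet` is a flat table of mature ncRNA sequences with biotype,
RFAM-like family, tRNA anticodon metadata and CCA status. A flat
annotation table (rather than GFF3/GTF with genome coordinates) is the
minimal faithful model at this scale: the metadata the pipeline actually
consumes is per-mature-sequence, and genome mapping is out of scope.
Conventions fixed once and used everywhere:

* all feature-internal coordinates are 0-based, half-open; printed
  reports render 1-based values;
* sequences are stored uppercase in the DNA alphabet; U is converted to T
  on input;
* tRNA sequences include the post-transcriptionally appended CCA tail;
  the "mature length" `L` used by the classifier is the pre-CCA length.

# Read assignment

Reads are cleaned the way a standard small RNA-seq pipeline would: an
exact 3' adapter-prefix match of at least 8 nt is removed, trailing bases
below Q20 are trimmed, and reads outside 18–50 nt are dropped (defaults
`min_q = 20`, `min_len = 18`, `max_len = 50`).

Assignment then finds the best *ungapped* placement of the read as a
substring of any reference feature with at most `max_mm = 2`
substitutions. Candidates are located with an exact 15-mer seed index and
extended; a placement therefore qualifies only if it contains at least
`seed_len = 15` consecutive exact matches, and this seed condition is part
of the documented contract (the brute-force oracle in the test suite
enforces the same rule). Ties are broken deterministically: fewest
mismatches, then a fixed biotype priority, then lexicographic feature id,
then smallest start — so results do not depend on reference record order.

The biotype priority places piRNA last. piRNA databases are known to
contain entries that are verbatim substrings of tRNAs, rRNAs and snoRNAs;
under this priority such reads are claimed by the host biotype, and the
dedicated piRNA filter (below) sees exactly the ambiguous entries.
Indels are not modelled: the generator injects none, small RNA inserts
are short, and a gapped search would add cost without testable behaviour.
Matching is sense-strand only, as small RNA libraries are stranded.

# tsRNA classification

With anticodon at offset `a` (0-based) and loop window
`W = [a - loop_halfwidth, a + 3 + loop_halfwidth]`, rules are applied in
order: 5'-anchored reads (start ≤ `tol5`) ending inside `W` at 29–50 nt
are 5' halves (tRH5); 5'-anchored reads ending below `W` at 14–30 nt are
5' fragments (tRF5); 3'-anchored reads (end ≥ L − `tol3`, possibly
through the CCA) starting inside `W` at 29–50 nt are 3' halves (tRH3);
3'-anchored 14–30 nt reads starting beyond `W` are tRF3, or tRF3CCA when
they cover at least one CCA base; everything else is tRFmisc.

Two deliberate choices: the tRH and tRF length bands overlap at
29–30 nt, so the anchored-end/loop condition — not length — is the
discriminator, and the rule order resolves the overlap in favour of
halves (loop cleavage is the defining signature of a half).
`loop_halfwidth = 4` approximates a 7–11 nt anticodon loop and is
configurable. 3'-CCA fragments are kept as their own class because
CCA-retaining 3' fragments track differently across compartments. The
classifier is a pure function of `(start, end, a, L)`, so every call can
be re-derived from the assignment table alone.

# piRNA disambiguation

A putative piRNA is excluded when its full sequence has an end-to-end,
ungapped placement inside any other-biotype sequence with at most
`max_mm = 2` substitutions *and* at least `seed_len = 16` consecutive
exact matches. This two-condition rule reproduces the intent of a
seeded, end-to-end alignment screen (0-mismatch seed of length 16)
without re-implementing an FM-index aligner; it is an approximation of
full alignment scoring, recorded as such. Whether the original screen
tolerated mismatches outside the seed is not documented anywhere we can
verify, so `max_mm` is exposed as a parameter; with `max_mm = 0` the
filter provably equals substring containment, which the tests exploit as
an oracle. Raising `max_mm` can only exclude more piRNAs (monotonicity,
also tested).

# Normalization and differential expression

Upper-quartile normalization computes, per sample, the 75th percentile
(type-7, linear interpolation) of nonzero counts divided by library
size; factors are rescaled to geometric mean 1 and multiply the library
size into an effective size; CPM are counts per million effective. The
detection filter keeps rows with CPM ≥ 1 in *every replicate of at least
one group* — a deliberately strict reading of "CPM ≥ 1 as cut-off",
chosen so that a feature cannot pass on scattered single-replicate
counts.

Differential expression uses an exact conditional test rather than a
quantile-adjusted likelihood machinery: counts are scaled to a common
effective size and rounded; a common NB dispersion φ is estimated by the
method of moments, `(s² − x̄)/x̄²` computed within each group and averaged
across rows and groups, truncated at zero. Within-group moments matter:
pooling across groups would absorb genuine expression differences into
φ and destroy power. The group-sum split of each row is then tested
two-sidedly conditional on the row total — exactly binomial in the
Poisson limit φ = 0 — and p-values are BH-adjusted. Flags use
|log₂FC| ≥ 1 (on CPM with a 0.5-CPM pseudocount) and FDR < 0.01. This
module's validation is property-based by design: power ≥ 90% and
empirical FDR ≤ 5% on a spiked simulation (50 rows at fold change 4
among 1000, 3 vs 3), and super-uniform null p-values; numeric identity
with any particular reference implementation is not a goal.

Z-score heatmap input standardizes rows of log₂(CPM + 1) with the sample
(n−1) standard deviation and orders rows/columns by Ward clustering on
Euclidean distances. Zero-variance rows are dropped with a message.

# Inequality and heterogeneity statistics

* **N80** — minimal k with the k largest shares summing to ≥ 80%;
  deterministic under ties.
* **Evenness factor e** — solve L(p) = 1 − p on the descending-sorted
  piecewise-linear Lorenz curve by interpolation on the bracketing
  segment; e ∈ (0, 50], with 50 for a uniform repertoire. A
  single-species vector returns the 100/n limit, flagged as degenerate.
* **Gini** — mean absolute pairwise difference over 2n²μ, computed with
  the O(n log n) sorted form (the tests compare it against the literal
  double loop).
* **χ² heterogeneity** — within a sample group, the sum of squared
  deviations of replicate compositions from the per-feature replicate
  mean, on within-biotype fractions; reported as fold change against a
  reference group (the whole-cell group in the default pipeline). The
  deviation-from-the-mean form was chosen over summing over replicate
  pairs; with both groups identical the fold change is exactly 1, and a
  zero-heterogeneity reference yields an infinite fold change with a
  warning rather than an error.

Abundance vectors enter these statistics after normalization and
within-biotype renormalization; note that N80, e and G are computed on
per-sample fractions, which per-sample scaling leaves unchanged.

# The synthetic-data generator

`build_toy_reference()` constructs a deterministic reference: 200 miRNAs
(22 nt), 40 parental tRNAs (73–76 nt + CCA, one locus per anticodon,
anticodon fixed at offset 32 so anticodon-mid cuts give 33 nt 5' halves),
20 snoRNAs, 10 snRNAs, 5 rRNA segments, 2 Y RNAs, 1 vault RNA, 5
protein-coding fragments, and 30 piRNAs of which exactly 10 are planted
verbatim 26–30 nt substrings of tRNA/rRNA/snoRNA records. No two
non-piRNA features share a 16-mer, so error-free reads ≥ 18 nt place
uniquely — which is what lets the tests treat assignment as exactly
recoverable.

`simulate_library()` draws, per read: biotype → feature → window.
tRNA reads draw a tsRNA class and are cut by the class rule; the half
cut sits at the anticodon middle plus a jitter drawn from a configurable
pmf over −2..+2 nt, peaked at 0 so the modal half length is 33 nt (a
uniform jitter would flatten the 31–35 nt band and leave no 33 nt mode;
the EV profile uses a bimodal jitter with modes at −3 and 0, producing
the 30/33 nt double peak). Stable-fragment biotypes (sno/sca/snRNA,
Y RNA, vault RNA) emit designated windows fixed at reference build —
modelling processed fragments, not random degradation — while rRNA and
protein-coding reads take internal windows with lengths from a generic
pmf. Substitution errors are injected at `error_rate = 0.001` per base
(a realistic post-filter Illumina rate; range 0–0.1), with constant Q37
qualities: the classifier tolerances, not the error model, are what the
package tests. All fragment-length models live within the 14–30 nt tRF
band but start at 18 nt, so the 18–50 nt cleaning gate does not distort
the class mixtures the profiles encode.

The default profiles are the study conditions the package models:

* **WC** — miRNA .68, tRNA .15, rRNA .08, sno .025, sn .015, YRNA .02,
  vtRNA .005, piRNA .005, protein-coding .02; tsRNA mix 70% tRH5.
* **AX** — tRNA .70, rRNA .10, miRNA .08, snRNA .06; 90% tRH5, 33 nt
  peak; parental-tRNA weights constructed so N80 = 15 (top shares
  Gly-GCC .30, Val-CAC .15, Val-AAC .12, then 12 anticodons at .02:
  top-14 = .79 < .80 ≤ top-15 = .81).
* **EV** — tRNA .90, miRNA .04; 90% tRH5 with the 30/33 nt bimodal
  model; snord104's 5' fragment carries ~60% of the sno+snRNA pool; the
  RNY1 5' arm is preferred (window weights .85/.15).
* **AXOPLASM** — rRNA .55, tRNA .41, miRNA .042 plus a small sRNA pool
  (0.8%, 95.5% of it snRNA with U2 .68 / U1 .12 / U6 .06) and Y RNA
  0.2%, renormalized; tsRNA mix shifted to the 3' side (tRH3 .40,
  tRF3 .25, tRF3CCA .12, tRH5 .15); parental tRNAs led by Lys-CTT .36,
  Ser-GCT .11, His-GTG .10; miRNA weights put .20 + .15 on
  mir-10a-5p/mir-10b-5p. The published shares for the three major
  biotypes already sum to ~100%, so the small sRNA/Y RNA pool needed for
  the sRNA-level statistics is added before renormalizing; the rRNA and
  miRNA shares move by less than half a percentage point. Two replicates
  by default (the motor/sensory nerve pair), versus three elsewhere.
* miRNA weights in WC/AX/EV are constructed so N80 = 30 (ranks 1–10 at
  .04, 11–30 at .02, the remaining 170 sharing .20).

Replicate r of a profile is seeded with `seed + r − 1`; a profile is
therefore a complete, byte-reproducible specification of its libraries.

What the generator deliberately does **not** emulate: adapter ligation
biases and adapter read-through (an optional fixed adapter append exists
only to exercise the trimmer), UMIs, indels, quality-score decay,
RNA-modification-induced misincorporation, and multi-mapping between
near-identical loci (the 16-mer uniqueness guarantee removes it).
Passing the recovery tests therefore shows that the pipeline's logic is
correct under its own stated model — not that it is robust to every
artefact of real libraries.

# Problem sizes and numerical choices

The acceptance computations simulate 3 × 200,000 reads for WC, AX and EV
and 2 × 200,000 for axoplasm — large enough that binomial sampling error
on a 68% share is ≈ 0.1 percentage points, comfortably inside the ±2
point recovery bands, while keeping the whole recomputation under a
minute. Unit tests use 1,000–30,000 reads. Other numerical choices:
type-7 quantiles everywhere; p-value ties in the exact test compared
with a 1 + 10⁻¹² relative slack; weight vectors validated to sum to 1
within 10⁻⁹; composition columns to 10⁻⁶; the Gini sorted form and the
Lorenz interpolation are exact (no iteration).

# Known limitations

* Ungapped, sense-strand assignment only; reads from features absent
  from the reference are unassigned rather than mis-assigned.
* The exact NB test uses one common dispersion; tagwise shrinkage and
  covariate designs are out of scope.
* The piRNA screen checks containment in individual features, not in a
  concatenated genome; cross-feature junctions do not exist at this
  scale.
* Fragment-peak arm labels use thirds of the feature length, a
  convention chosen here; real secondary structure is not consulted.
* The 23-style signature intersection collapses ids lexically; ids that
  do not follow miRBase-like naming collapse trivially to themselves.
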