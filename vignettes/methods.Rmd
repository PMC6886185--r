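---
title: "Models and methods behind ribofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribofate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribofate)
```

# The scientific question

Two mRNA-binding machines set the cytosolic fate of a message: the eIF4F
initiation complex (with the DEAD-box helicase eIF4A1) and the repressive
Ccr4-Not complex, whose scaffold CNOT1 recruits DEAD-box proteins such as
DDX6 and, as the analyses this package implements argue, eIF4A2. The
repressed state has a recognisable signature: mRNAs bound by eIF4A2 sit in
subpolysomal gradient fractions, carry fewer elongating ribosomes along the
CDS, accumulate footprints in the last ~50 nt of the 5'UTR, are enriched
for purine-rich tetramers directly upstream of the AUG, initiate more often
from upstream sites (uTIS/uORFs), are targets of conserved miRNA families,
and move into polysomes when CNOT1 is depleted. In vitro, eIF4A2 binds
(AG)-repeat RNA tightly and selectively, resembling chemically clamped
eIF4A1.

ribofate re-implements the downstream, desk-scale statistics of that
argument as a reusable pipeline, and ships a synthetic-data generator that
plants all of those effects with known ground truth so every stage can be
validated end to end. Nothing in the package touches raw reads: inputs are
post-alignment count tables, footprint position tables, sequences, peak
tables, target lists and titration tables.

# Stage models and their assumptions

## RIP enrichment (binding groups)

The published description of the enrichment call is too terse to
re-implement verbatim, so the package defines a transparent stand-in and
documents it as such: replicates are pooled per side and each gene is
tested one-sided with X ~ Binomial(c_ip + c_in, L_ip/(L_ip + L_in)) — the
exact conditional test of the null that reads split between IP and input
libraries in proportion to library size. Benjamini-Hochberg correction runs
across genes; a gene is *bound* when FDR < 0.05 **and** the (0.5
pseudocounted) log2 enrichment is positive — IP-depleted genes are never
"bound". Genes are then labelled with the set of proteins binding them
(eIF4A1 / eIF4A2 / DDX6 and intersections), a partition used by every
downstream group comparison.

The binomial conditioning is exact only when IP and input counts of a
replicate share the gene's realised abundance (both libraries come from one
lysate). The generator therefore draws a per-replicate Gamma multiplier per
gene and Poisson counts on each side, which leaves the *marginal* counts
negative-binomial at the stated dispersion (0.2 for RIP) while keeping the
conditional split binomial. Had the two sides been simulated as independent
NB draws, *no* exact count test could be calibrated — a point worth
remembering when applying the test to real data, where residual
IP-specific variability will inflate the false-discovery rate.

## Polysome association and CNOT1-knockdown shifts

The association score of a gene is mean polysomal CPM minus mean
subpolysomal CPM (replicates averaged after normalisation); low scores mark
initiation-repressed mRNAs. The published analysis alternates between CPM
and FPKM in different places; CPM is the default here and `unit = "fpkm"`
(CPM/length × 10³) reproduces the other variant. The knockdown shift test
is a per-fraction Welch t-test on log2(CPM + 0.5) with BH correction
(another documented stand-in for an external count-model tool, out of
scope), and a gene is *shifted* only when significant in **both**
fractions; the direction is `into_polysomes` when the polysomal fold change
is positive and the subpolysomal negative, `out_of_polysomes` when
reversed, otherwise `discordant`. Group-level shift comparisons use
Kruskal-Wallis plus Dunn's test with BH correction; what is compared is the
change in association score (knockdown − control) per gene — a plotted
alternative would be per-fraction fold changes, noted but not used.

CPM is compositional: if a large *unbalanced* set of genes moves between
fractions, library sizes change between conditions and apparent fold
changes leak into unshifted genes (we measured the shift test's sensitivity
collapsing from ~0.8 to ~0.01 in such a world). The test suite therefore
states a balanced world — some mRNAs in, an equal mass out — which is also
what a CNOT1 depletion looks like in the data this emulates.

## Ribosome occupancy

Footprints of 28–30 nt are kept per length only if, after applying the
fixed P-site offset of 13 nt, at least 60% of CDS-internal reads fall in
one frame (the threshold is configurable; the source analysis says only
that "periodic" lengths were retained). P-site vectors are
reads-per-million normalised, and occupancy is RPM divided by the
transcript's TPM (computed from matched total RNA), i.e. ribosome density
per mRNA copy. The CDS metagene sums the three in-frame nucleotides per
codon and averages across transcripts with **equal weight** (the
read-weighted alternative is a documented open choice) over 75 codons from
the AUG and 75 codons up to the STOP, for transcripts with ≥ 25 raw
footprints and CDS **strictly** longer than 300 nt. 5'UTR occupancy is the
all-frames mean over the first and last 50 nt of 5'UTRs strictly longer
than 100 nt.

One geometric subtlety matters for validation: with a 13-nt offset no
P-site can land on 5'UTR positions 0–12, so the first 50-nt window is
systematically truncated by ~26%. Within-transcript last/first ratios are
therefore biased upward, and the planted peak factor is recovered in the
tests as a group-versus-background ratio of last-window rates, where the
truncation cancels.

## Sequence features

The motif set is the eight purine tetramers (AAGA, AGAA, GAAA, GAGA, AGAG,
GGAA, AAAA, GAAG) associated with clamped eIF4A binding. Counting is
greedy, left-to-right and non-overlapping (the direction of non-overlap was
unspecified; left-to-right is deterministic and conventional), `N` never
matches, and per-nt frequency divides by region length. Positional profiles
report, per base of the first/last 50 nt of the 5'UTR, the fraction of
group sequences in which a motif occurrence *covers* that base (start
positions are exposed as an alternative mode), and enrichment is the ratio
to a background group, undefined where the background is zero. Rolling GC
uses a 6-nt window; Pumilio elements are TGTANATA, counted with the same
non-overlap convention for consistency. Group comparisons use Dunn's test
with Bonferroni correction, matching the source figure legends; the
miRNA-family comparison elsewhere uses BH, and both corrections are exposed
per analysis.

## Initiation sites and miRNA families

A transcript's initiation label is determined by exact coordinate equality
of an initiating-ribosome peak with the annotated start (`annotated_only`,
`utis_only`, `both`, `none`; downstream peaks are ignored), and an upstream
site is in frame iff its distance to the start is a multiple of 3. Group
proportions exclude `none` from the denominator (a documented choice — the
alternative would dilute all groups with undetected transcripts).
miRNA-family enrichment is a one-sided Fisher test of each family's targets
in each binding group against the gene universe, BH-corrected across
families within a group and binned (< 0.05, 0.05–0.1, 0.1–0.2, ns) for
heatmap display; the Targetscan-style PCT > 0.5 filter is applied on
ingest when a PCT column is present. The reference set of "miRNA targets in
these cells" (genes up after TNRC6 knockdown) is an ordinary column of the
table, not a special code path.

## Binding kinetics

Equilibrium titrations are fit by least squares to the Hill equation
y = baseline + amplitude·xʰ/(KDʰ + xʰ) with h bounded to [0.3, 4] (physical
plausibility and stability on sparse titrations) and five log-spaced KD
starts; the free-ligand approximation is implicit, as in the conventional
Prism-style analysis, and is safe in the emulated regime (10–25 nM labelled
RNA against micromolar KD). The convergence flag goes false when the
optimiser fails, hits a bound, the fitted KD falls outside the titrated
range, the amplitude is not positive, or the data are saturated
non-monotonically. Strand release is a single-exponential decay with
t½ = ln 2 / k reported by construction (the plateau is left free — whether
the original fits fixed it is unstated). The competition solver makes *no*
free-ligand approximation: free protein solves the exact mass balance by
bracketed root-finding polished to 10⁻¹² relative; apparent KDs at a given
competitor excess come from Hill fits of fraction bound and are
non-decreasing in excess.

# The synthetic world

`sim_params()` is the stated world, chosen once: 15% eIF4A1-only, 10%
eIF4A2-only, 10% DDX6-only, 15% bound by both eIF4A1 and eIF4A2, 50%
unbound; log-normal region lengths (medians ~160 nt 5'UTR, ~430 codons,
~700 nt 3'UTR) and expression (CV ~ 1.3); planted effects of 4× IP
enrichment, polysome fractions 0.35 (eIF4A2-like) vs 0.50 rising to 0.62
under knockdown (DDX6-like falling to 0.32), 0.4× CDS translation with a 3×
last-50-nt 5'UTR footprint peak, two purine tetramers planted per
eIF4A2-like 5'UTR end, a GC-rich (70%) last window for eIF4A1-like 5'UTRs,
a 2× excess of upstream-only initiation, and eight of forty miRNA families
biased 6× toward the repressed groups. Footprint depth (`rpf_depth = 0.3`
expected reads per codon at average expression) puts the median transcript
near 100 footprints, so the ≥ 25-read filter bites realistically. 5'UTR
footprints are deliberately *not* scaled by the translation factor:
scanning/uORF ribosomes are what remains when initiation at the main AUG is
blocked — that is precisely the phenotype the analyses look for.

What the generator does **not** emulate: isoform families (one transcript
per gene), sequencing error, UMI structure, rRNA contamination, positional
biases along the CDS (uniform per-codon rates), secondary structure, or
IP-specific background binding. A green suite therefore establishes that
the statistics recover what they claim from data obeying their assumptions
— not that those assumptions hold in any particular wet-lab dataset.

# Numerical and testing choices

* Coordinates are 0-based, half-open, transcript-relative; the internal
  alphabet is DNA with U→T on ingest; duplicate full sequences collapse to
  the first occurrence, and isoform ties break lexicographically — reruns
  are byte-identical under a fixed seed.
* Benjamini-Hochberg, Bonferroni, the one-sided Fisher test and the
  tie-corrected Dunn test are implemented in-package and validated against
  independent oracles (explicit binomial-coefficient sums for every
  contingency table with universe ≤ 30; 10⁵-draw permutation oracles for
  Dunn). The permutation law of a rank statistic at n ≤ 8 per group is
  discrete, so the normal-approximation Dunn p is validated against the
  Monte-Carlo-widened bracket [P(|Z|>|z|), P(|Z|≥|z|)]; exhaustive
  enumeration shows the normal tail leaves even that bracket beyond
  |z| ≈ 2.3 — an inherent property of the normal approximation, not an
  implementation defect, and the reason oracle tests use moderate |z|.
* The equilibrium solver's root is bracketed in [0, P_total] (the mass
  balance is monotone), polished by Newton steps, and required to conserve
  protein and both RNAs to 10⁻⁹ relative in the tests.
* Degenerate inputs have defined behaviour rather than NaNs: all-identical
  Dunn groups give z = 0, p = 1; zero-total-count genes give p = 1 and
  zero enrichment; zero-TPM transcripts are excluded with a report; flat or
  inverted titrations set the convergence flag false.

# Known limitations

The RIP and shift tests are stand-ins for an unspecified published
procedure and should not be read as its re-implementation; the binomial
test's calibration depends on the matched-lysate assumption discussed
above; Hill standard errors come from a local Jacobian and understate
uncertainty near bounds; and the pipeline assumes one representative
transcript per gene (chosen upstream by `most_abundant_isoform()`).
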