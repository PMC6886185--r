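# ribofate

Downstream analysis of mRNA fate at translation initiation — for
transcriptomicists who already have aligned, desk-scale tables (count
matrices, footprint positions, sequences, peak tables, target lists,
titrations) and want the statistics, not another aligner.

The package implements the quantitative pipeline by which
initiation-repressed, helicase-bound mRNAs are characterised:

* **RIP-Seq enrichment** — per gene, IP vs input by the exact conditional
  binomial test: with pooled counts c_ip, c_in and library sizes L_ip,
  L_in, p = P(X ≥ c_ip), X ~ Binomial(c_ip + c_in, L_ip/(L_ip + L_in));
  BH-corrected calls (FDR < 0.05, log2 enrichment > 0) partition genes
  into binding groups (eIF4A1 / eIF4A2 / DDX6 and intersections).
* **Polysome association** — score = mean CPM(polysomal) − mean
  CPM(subpolysomal); knockdown shifts require per-fraction Welch tests on
  log2(CPM + 0.5) to reach FDR < 0.05 in *both* fractions.
* **Ribosome occupancy** — P-site = footprint 5' end + 13 nt for periodic
  28–30-nt reads; occupancy = RPM / TPM; 75-codon CDS metagenes (≥ 25
  reads, CDS > 300 nt) and first/last-50-nt 5'UTR occupancy (5'UTR >
  100 nt).
* **Sequence features** — greedy non-overlapping counts of the eight
  purine tetramers (AAGA, AGAA, GAAA, GAGA, AGAG, GGAA, AAAA, GAAG),
  positional profiles over the 5'UTR ends, 6-nt rolling GC, Pumilio
  elements (TGTANATA).
* **Initiation usage & miRNA families** — uTIS classification from
  initiating-ribosome peaks; one-sided Fisher tests (hypergeometric
  tails) of family targets per binding group.
* **Binding kinetics** — Hill fits (y = b + a·xʰ/(KDʰ + xʰ)),
  single-exponential strand release (t½ = ln 2/k), and an exact
  mass-balance competition solver.
* **Statistics core** — Benjamini-Hochberg, Bonferroni, one-sided
  Fisher's exact test, and Kruskal-Wallis with tie-corrected Dunn post
  hoc z = (R̄ₐ − R̄ᵦ)/√(S²(1/nₐ + 1/nᵦ)), S² = N(N+1)/12 − Στ(t³−t)/(12(N−1)).
* **Synthetic data** — every input format generated with known ground
  truth (planted enrichment, shifts, 5'UTR peaks, motifs, uTIS excess,
  biased miRNA families, noisy binding curves), so each stage is
  validated end to end.

## Worked example

```r
library(ribofate)

sim <- simulate_dataset("demo", preset = "minimal", seed = 42)

cm  <- sim$counts$rip$eIF4A2
ipc <- cm$sample_meta$assay == "rip_ip"
rip <- enrichment_test(cm$counts[, ipc], cm$counts[, !ipc],
                       cm$library_sizes[ipc], cm$library_sizes[!ipc])
head(rip[order(rip$fdr), ], 5)
#>    gene_id log2_enrichment         p       fdr enriched
#> 28  g00028            1.40 4.80e-197 2.88e-195     TRUE
#> 8   g00008            1.41  5.01e-94  1.50e-92     TRUE
#> 34  g00034            1.41  6.81e-85  1.36e-83     TRUE
#> 14  g00014            1.44  1.48e-84  2.22e-83     TRUE
#> 38  g00038            1.43  1.09e-82  1.31e-81     TRUE

attr(assign_binding_groups(list(eIF4A2 = rip)), "counts")
#> eIF4A2   none
#>     14     46
```

The generator planted 4× IP enrichment in the eIF4A2-like genes
(log2 ≈ 1.4 after library-size normalisation, since enriched genes also
inflate the IP library); 14 of 60 genes are called bound, matching the
planted group.

```r
b   <- sim$binding
one <- subset(b$titration, protein == "eIF4A2" & rna == "AG")
fit_hill(one$conc_M, anisotropy_change(one$conc_M, one$signal))
#> binding_fit ( hill ), converged: TRUE
#>         kd     hill_h  amplitude   baseline
#>  3.017e-07  1.014e+00  1.175e-01 -2.437e-04
```

The fitted KD (0.30 µM) recovers the generating value (`b$truth$kd`,
3e-07 M) from triplicate titrations with 2% noise; `hill_h ≈ 1` matches
the non-cooperative generating model.

The whole pipeline runs in one call from a directory of input files
(layout as written by `simulate_dataset()`), producing per-stage TSVs and
a checksummed manifest:

```r
run_pipeline(pipeline_config("demo", "demo_out", seed = 42))
```

or from the command line:

```sh
Rscript inst/cli/ribofate.R simulate --preset paperlike --seed 1 --out data/
Rscript inst/cli/ribofate.R run --config config.yaml
```

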