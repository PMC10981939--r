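# cytosieve

Filtration-chromatography ("sieving") proteomics of cytoplasm, analyzed end
to end: how much of a proteome is organized in mesoscale, liquid-like
biomolecular condensates (BMCs), and which proteins are in them.

## The problem

Most cytoplasmic organization sits below the diffraction limit
(~10–1000 nm), where microscopy cannot resolve it. Spinning cytoplasm
through filter membranes with defined pore cutoffs and quantifying the
filtrate by multiplexed (TMT) proteomics turns assembly state into a
measurable signal: each protein's fold change `FC = c/c0` (filtrate over
input) across elution time windows, pore sizes and lysate dilutions.
Free proteins elute unhindered (`FC ~ 1`); rigid complexes and
membrane-bound organelles larger than the pores are retained; liquid-like
condensates *squeeze* through slowly — retained early, eluting late — and,
unlike complexes, dissolve under moderate dilution once their saturation
concentration is undercut.

`cytosieve` is for proteomics analysts working with such data (or wanting
to evaluate the approach): it implements the full downstream analysis and a
ground-truth forward simulator of a synthetic cytoplasm, so every stage is
testable without any deposited dataset.

## What it computes

* **Normalization** — per experiment, fold changes are divided by the
  pooled 0.95 quantile, anchoring unhindered flowthrough at `FC = 1`.
* **Squeezing score** — in the log2 scatter of late (T2) versus early (T1)
  permeation, the upper edge near the identity is fitted (OLS, then a refit
  through the top 4% of points in 20 bins along the line); a protein's
  score is its orthogonal distance below the edge `y = a + bx`:
  `s = (a + b*x - y) / sqrt(1 + b^2)`, positive = more squeezing.
* **Reference recall** — ROC/AUC (trapezoid over the tie-grouped ranking,
  equal to the Mann–Whitney statistic), two-sample KS tests, per-group
  ECDFs against reference sets (LLPS consensus level across curated
  databases, complexes, organelles, RNA-binding proteins).
* **Liquid-like behavior and FDR** — per experiment, an anchor line is fit
  through large complexes and transmembrane proteins; behavior is the mean
  vertical log2 shift from that line over the 30/100 nm filtrations and
  1.2x/1.44x dilutions. An empirical null (pooled residuals of replicate
  line fits, r > 0.8) drives a plug-in 2% FDR call
  `FDR(t) = N * S_null(t) / #(behavior >= t)`; the proteome is partitioned
  into membrane-bound organelle / BMC / small / unassigned fractions.
* **LLPS predictor** — 600 bagged ensembles of decision trees (min leaf 32,
  at most `floor(0.75 p)` splits) and ridge-regularized linear
  discriminants, trained on partitions (80% of class 1, 10% of class 2);
  per-protein median score over ensembles that never trained on it;
  experiment- and sequence-feature scores combined by Euclidean distance
  `d_i = sqrt((max s_exp - s_exp_i)^2 + (max s_seq - s_seq_i)^2)`.
* **Size-exclusion beads** — accessible volume `rho0` from dextran ratios,
  fill fractions `f = I_in/(I_out rho0)`, the step coefficient of variation
  across bead cutoffs (low CV = organization spread over the mesoscale),
  and Stokes–Einstein radii `r = kB T / (6 pi eta D)`.

## Worked example

One command simulates a 4000-species synthetic cytoplasm (12% free, 23%
complexes, 25% condensates, 40% membrane-bound organelles), runs filtration
at 30/100/200 nm, a dilution series, normalization, squeezing scores,
the noise model and the 2% FDR composition call:

```r
library(cytosieve)
cfg <- pipeline_config(seed = 7, classify = FALSE)
res <- run_pipeline(cfg)
round(res$composition$fractions, 3)
```

```
simulated proteome: 4000 species (complex=908, condensate=1036, free=496, membrane_organelle=1560)
simulated 14 conditions; 79 proteins at LLPS consensus >= 4
normalized 4 experiments to their pooled 0.95 quantile
squeezing scores from filt30: edge slope 0.673, 168 support proteins
squeezing AUC: LLPS reference 0.818, complexes 0.396
noise model: 16000 residuals from 4 replicate pairs; sd = 0.284
composition: membrane_bound_organelle=0.39, bmc=0.222, small=0.112, unassigned=0.275

membrane_bound_organelle                      bmc                    small
                   0.390                    0.222                    0.112
              unassigned
                   0.275
```

Reading the numbers: the squeezing score recalls the curated LLPS reference
strongly (AUC 0.82) while known complexes are *under*-represented (AUC
0.40 < 0.5) — the two modes of organization separate. The FDR call
recovers the planted composition: 22.2% called BMC against 25% planted
condensates (a lower bound — large, stiff, solid-cored condensates are
indistinguishable from complexes in every assay), 11.2% "small" against
12% planted free proteins, and the membrane fraction from annotation.
Setting `classify = TRUE` adds the cross-validated ensemble predictor
(AUC ~ 0.97 on these conditions, where disorder-correlated annotations
make the reference set learnable).

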