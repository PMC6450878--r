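# opticr

Quantification of fluorescent protein recruitment to micron-scale
clusters of chimeric CEACAM3–integrin receptors.

## The problem

Clustering chimeric receptors that carry an integrin β cytoplasmic tail
(with multivalent ligands such as CEACAM-binding bacteria or
antibody-coated beads) recruits cytosolic binding partners — talin,
kindlin, paxillin — to the attachment site. The readout is a per-cell
**recruitment ratio**

```
R = max(POI intensity over ROI2) / mean(POI intensity over ROI1)
```

where ROI1 is the whole-cell region (POI channel) and ROI2 the
clustered-receptor site (receptor channel). A cell is scored positive at
`R >= 2` (two-fold local enrichment over the mean cellular
distribution). Conditions are summarized as mean `R` with a 95%
confidence interval and percent-positive cells, and compared by one-way
ANOVA with Bonferroni post-hoc tests against a control.

`opticr` is for anyone who wants to run that quantification
reproducibly: it automates the two ROIs (Otsu-based cell segmentation,
quantile-based cluster detection), computes per-cell records, line-scan
profiles, condition summaries and the ANOVA/Bonferroni report, and ships

* a **synthetic field generator** with ground-truth masks (known
  enrichment factor `E`, PSF blur, Poisson + read noise) so the whole
  chain is testable without real microscopy data, and
* a **motif module** for the sequence logic behind recruitment: scanning
  integrin β tails for the membrane-proximal `NPx[Y/F]` (talin) and
  membrane-distal `Nxx[Y/F]` (kindlin) motifs in precursor numbering,
  and applying point mutations such as `Y783A`.

## Worked example

The packaged study cohort contrasts 3-fold enrichment with a
no-enrichment control, 60 cells each, fully automated ROIs:

```r
library(opticr)
cfg <- demo_config(n_cells = 60, seed = 7)
res <- run_pipeline(cfg, out_dir = "results/run")
res$summary
#>  condition  n   mean_R   ci_low  ci_high percent_positive
#>    control 60 1.417080 1.402792 1.431367                0
#>   enriched 60 2.339855 2.314789 2.364921              100
res$stats$F_statistic
#> [1] 4095.645
```

The control sits near `R ≈ 1.4` (the maximum of a noisy but unenriched
site always exceeds the cell mean a little), the enriched condition is
clearly separated, and the Bonferroni-adjusted contrast versus the
control is significant at `***` (adjusted p ≈ 1.8e-93). Mean `R` for the
enriched condition is below the generator's `E = 3` because the
point-spread blur attenuates the peak — which is why recovery is always
judged against a brute-force oracle (`recruitment_oracle()`, the same
max/mean arithmetic on the ground-truth masks) rather than against `E`.

The motif side of the story, in three lines:

```r
b1 <- optic_tail_fixtures()$ITGB1       # human beta-1 tail, E762-K798
find_motifs(b1)
#>         motif_class start end terminal_residue sequence
#> 1 membrane_proximal   780 783                Y     NPIY
#> 2   membrane_distal   792 795                Y     NPKY
find_motifs(apply_mutation(b1, "Y783A"))   # talin-site mutant
#>       motif_class start end terminal_residue sequence
#> 1 membrane_distal   792 795                Y     NPKY
```

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01` renders example fields to TIFF, `02` quantifies the
cohort into `results/records.csv`, `03` writes the condition summaries
and ANOVA report, `04` scans the packaged tails and the two point
mutants, `05` draws the dot plot, percent-positive bars and a line-scan
profile.

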