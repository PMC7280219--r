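# flimscore

Severity scoring of inflammatory skin conditions from two-photon
fluorescence-lifetime (FLIM) optical biopsies.

## What it does

Psoriasis severity is clinically graded with observer-based scores (PASI,
LIS) that are coarse and poorly reproducible. Volumetric two-photon FLIM
stacks of the epidermis contain objective structural and metabolic
correlates of the disease — epidermal thickening, perinuclear
mitochondrial clustering, and shifts in the NAD(P)H fluorescence
lifetimes — in both lesional and visually uninvolved ("pseudo-control")
skin. `flimscore` turns such stacks into a single severity score per
imaging site:

1. **Decay fitting** — per-pixel TCSPC histograms are spatially binned
   with a (2n+1)×(2n+1) moving window (default n = 4) and fitted with the
   two-component model f(t) = a₁e^(−t/τ₁) + a₂e^(−t/τ₂) by weighted
   least squares (Poisson weights, variable projection, deterministic
   initialisation), giving per-frame means and SDs of τ₁ and τ₂ and the
   component percentages.
2. **Texture features** — a *Fourier parameter* (mean FFT magnitude in a
   high-frequency annulus, 24–36 px, over a medium-frequency annulus,
   14–24 px, radii quoted for 512-px frames) as a proxy for sub-cellular
   puncta, and the mean local Shannon entropy under a radius-2 px disk.
3. **Depth features** — stratum granulosum (SG) imaging depth and the
   SG→SB optical distance (epidermal thickness), read from stack depth
   metadata.
4. **Severity scoring** — an 8-feature vector per site (condition
   analysis) or a 5-feature vector per psoriasis subject (PASI analysis,
   using inflamed / pseudo-control ratios) is z-scored (population SD)
   and decomposed by PCA; the oriented first principal component is the
   severity score. Group separation is quantified by silhouette widths,
   clinical agreement by the Pearson correlation of PC1 with PASI (or
   PASI + LIS).

Because clinical FLIM stacks of this kind are not publicly deposited, the
package includes a fully parameterised synthetic-cohort generator
(`generateCohort`) producing Poisson-correct decay cubes with cellular
texture, group-dependent effect sizes and per-subject ground truth, so
the whole pipeline is testable end to end. PASI arithmetic
(`regionSeverity`, `regionScore`, `pasiTotal`, `pasiBand`) and LIS
validation are included.

## A worked example

```r
library(flimscore)

cfg <- cohortConfig(frame_size = 128L, n_time_bins = 128L,
                    render = "layers", fit = list(stride = 4L))
cohort <- generateCohort(c(control = 5, psoriasis = 5), cfg, seed = 7)
res <- runSeverityPipeline(cohort, cfg)

round(res$condition$separation$pc1_group_means, 2)
#>        control pseudo_control      psoriasis
#>          -2.59          -0.47           3.06
res$condition$model
#> SeverityModel: 8 features, 8 components; PC1 explains 72.5% (sign -1)
#> features: fourier_SB, tau1_mean_SB, tau2_mean_SB, tau1_std_SB,
#>   tau2_std_SG, depth_SG_um, dist_SG_SB_um, entropy_SG
round(res$pasi$pearson_r_pasi, 2)
#> [1] 0.85
```

The three group means order control < pseudo-control < psoriasis along
the oriented severity axis: healthy skin scores lowest, visually
uninvolved skin of psoriasis patients sits in between (the systemic
signal), lesional skin scores highest. The PC1–PASI correlation at n = 5
is strongly positive but carries large sampling error; at the study scale
(n = 33 psoriasis subjects) it concentrates around the generator's
coupling target of 0.5.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/severity-pipeline.R` (subcommands `simulate` and `score`).

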