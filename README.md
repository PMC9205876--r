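# cmradiomics

Radiomic features computed from quantitative cardiac MR maps are only as
portable as the preprocessing behind them. `cmradiomics` quantifies how much
2D radiomic features estimated from single-slice myocardial **T1/T2 maps**
move when three preprocessing choices vary:

* **Effect A** — the resampling voxel size (1.8–2.4 mm, at fixed bin width),
* **Effect B** — the gray-level bin width (3.60–6.40 ms for T1,
  0.49–0.57 ms for T2, at fixed voxel size),
* **Effect C** — the spatial filter (four undecimated Daubechies-3 wavelet
  sub-bands, gradient magnitude, square, square root; at fixed voxel size
  and bin width).

It is aimed at imaging scientists designing or auditing radiomics studies on
parametric maps, and ships everything needed to run the analysis with no
data download: a seeded synthetic generator of ring-ROI cardiac maps, the
full 98-feature 2D engine (9 shape, 16 first-order, 73 texture features from
GLCM/GLRLM/GLSZM/GLDM/NGTDM, Chebyshev distance 1, direction-averaged), and
the robustness statistics.

Variability is expressed three ways. Relative variability per feature is the
intraclass correlation of the subjects × conditions matrix, two-way mixed
model, single rater, absolute agreement:

```
ICC = (MS_R − MS_E) / (MS_R + (k − 1) MS_E + (k/n)(MS_C − MS_E))
```

banded as high (≤ 0.5), considerable (≤ 0.75), moderate (≤ 0.9) or low
(≤ 1) variability. Absolute variability is the per-subject coefficient of
variation, `100 · SD/|mean|`, across the varied conditions. Linear trend is
the repeated-measures correlation (ANCOVA with subject factor and common
slope, `r_rm = sign(b)·√(SS_x/(SS_x + SS_e))`), Bonferroni-corrected per
modality × effect family.

Intensities are discretized with a **fixed bin width** (bin edges at
integer multiples of the width), the recommended scheme for quantitative
maps; the study bin-width grids keep the gray-level count of a typical ROI
(range 265 ms T1 / 26 ms T2) within 30–130 levels.

## Worked example

```r
library(cmradiomics)
library(dplyr)

co <- generate_cohort(cohort_spec(n_subjects = 8, modality = "T1", seed = 42))
co
#> # A tibble: 8 × 4
#>   subject_id spacing_mm map        mask
#>   <chr>           <dbl> <list>     <list>
#> 1 sub001           2.29 <quant_mp> <roi_mask>
#> 2 sub002           2.12 <quant_mp> <roi_mask>
#> # …

# one preprocessing coordinate: resample to 2.1 mm, discretize at 5 ms
extract_at(co$map[[1]], co$mask[[1]], voxel_size_mm = 2.1, bin_width_ms = 5)
#> # A tibble: 98 × 8
#>   subject_id modality voxel_size_mm bin_width_ms filter   feature_class …
#> 1 sub001     T1                 2.1            5 original shape

# effect B at one fixed voxel size: nine bin widths as "raters"
design <- default_designs("T1")$B
design$voxel_sizes_mm <- 2.1
feats <- run_effect(co, design)
ana <- analyze_effect(feats, design)

ana$icc |>
  filter(feature_name %in% c("Sphericity", "Mean", "Entropy", "Contrast"))
#>   feature_class feature_name voxel_size_mm   icc band     degenerate n k
#> 1 firstorder    Entropy                2.1 0.541 conside… FALSE      8 9
#> 2 firstorder    Mean                   2.1 1     low      FALSE      8 9
#> 3 glcm          Contrast               2.1 0.614 conside… FALSE      8 9
#> 4 ngtdm         Contrast               2.1 0.751 moderate FALSE      8 9
#> 5 shape         Sphericity             2.1 1     low      FALSE      8 9

ana$cv_summary |> filter(feature_class == "glcm") |>
  arrange(desc(median_cv)) |> head(4)
#>   feature_class feature_name      median_cv n_records
#> 1 glcm          ClusterProminence      79.6         8
#> 2 glcm          ClusterShade           59.8         8
#> 3 glcm          ClusterTendency       40.1          8
#> 4 glcm          SumSquares            40.1          8
```

Read: shape features and pre-discretization first-order statistics (`Mean`,
`Sphericity`) have ICC exactly 1 and CV 0 % under bin-width variation —
they are computed before discretization, so the bin width cannot touch them
— while histogram and texture features (`Entropy`, GLCM `Contrast`, cluster
moments) shift substantially, with median CVs up to ~80 % for the most
bin-sensitive GLCM moments.

`autoplot(ana)` draws the ICC band heatmap (features × fixed condition);
`plot_cv_distribution(ana, "glcm")` shows per-subject CV boxplots;
`autoplot(co$map[[1]], co$mask[[1]])` displays a map with its ROI.

A command-line front end covers the same pipeline:

```sh
Rscript inst/scripts/radiomap.R run-all --n-subjects 26 --seed 1 --out results/
```

writing feature tables, ICC/CV/rmcorr tables and a run manifest per
modality and effect.

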