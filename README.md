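# cogstruct

Bottom-up latent-structure analysis of multi-task cognitive batteries:
does behavior on a dozen cognitive tasks decompose into a few latent
abilities, and does task-evoked brain activity decompose the same way?
`cogstruct` is aimed at cognitive neuroscientists and psychometricians
who want that question answered with a fully inspectable pipeline —
every stage is testable against synthetic data with known ground truth.

## What it computes

**Exploratory factor analysis, from scratch.** For a correlation matrix
`R` of `p` standardized indicators and `m` factors, the common-factor
model is `Σ = ΛΦΛ′ + Ψ`. Maximum-likelihood extraction minimizes

```
F(Ψ) = log|Σ| + tr(RΣ⁻¹) − log|R| − p
```

profiling `Λ` out through the eigendecomposition of `Ψ^(−1/2) R Ψ^(−1/2)`,
with uniquenesses box-constrained (Heywood solutions are flagged, never
hidden). Geomin (oblique) rotation minimizes
`q(Λ) = Σᵢ (Πₖ (λᵢₖ² + ε))^(1/m)` by gradient projection with random
restarts. Fit is reported as `χ² = (n−1)·F_min` with
`df = ((p−m)² − (p+m))/2`, plus CFI, TLI,
`RMSEA = √(max(χ²−df,0)/(df(n−1)))` and SRMR against the independence
baseline.

**Task-map spatial similarity.** Each task's group z-map is thresholded
at z > 2.3 (strict); every task pair is correlated over the intersection
of the two positive activation masks. Twelve tasks give 66 pair
correlations — with the 12 unit self-correlations, the 78 distinct cells
of the similarity matrix — which is repaired to positive definiteness if
the pairwise masks made it indefinite, then factor-analyzed with the
same engine.

**Brain–behavior coupling.** Per latent domain, subjects' betas are
averaged over the domain's conjunction mask (voxelwise AND of its three
task masks) and across its three tasks, then correlated with the
standardized three-task behavioral composite (reaction-time tasks
sign-reflected so higher = better). Subjects beyond 4 group-SDs are
reported as outliers and the correlation is recomputed without them.

**Synthetic ground truth.** `cognitive_battery_spec()` plants a 4-domain
oblique factor model in 12 task scores (9 accuracies, 3 reaction times);
`network_template_spec()` plants shared + domain-specific activation
templates in task z-maps and subject beta maps, with a closed-form
`calibrate_coupling()` that converts a target brain–behavior correlation
into the generative coupling weight.

## Worked example

```r
library(cogstruct)

spec     <- cognitive_battery_spec(seed = 2026)          # N = 114, 4 domains
behavior <- generate_behavioral(spec, missing_pattern = "session")
mc       <- run_behavioral_efa(behavior, seed = 2026)
mc
#> EFA model comparison (behavioral data, n_effective = 92)
#>  m n_parameters chi_square df  p_value    cfi    tli  rmsea    srmr heywood
#>  3           57      63.72 33 0.001041 0.9074 0.8148 0.1011 0.06838   FALSE
#>  4           66      21.45 24 0.611929 1.0000 1.0211 0.0000 0.03070    TRUE
#>  5           74      11.64 16 0.768387 1.0000 1.0542 0.0000 0.02048    TRUE
#> Selected m = 4
#> smallest m with RMSEA <= 0.06 and SRMR <= 0.08. Candidates: m=3 (RMSEA 0.101,
#> SRMR 0.068); m=4 (RMSEA 0.000, SRMR 0.031, qualifies); m=5 (RMSEA 0.000,
#> SRMR 0.020, qualifies).
```

The planted 4-factor model is selected: the 3-factor fit fails the RMSEA
rule, the 4-factor fit is essentially perfect (χ²(24) = 21.45 < df, so
RMSEA = 0 and CFI = 1), and 5 factors add parameters without need. The
`heywood` flag marks a uniqueness on its lower bound — common at this
sample size when a true loading is as high as .903, and reported rather
than hidden. Task membership, labeled by each factor's modal a-priori
domain:

```r
nets <- network_template_spec(seed = 2026)
nets$coupling["memory"] <- as.numeric(calibrate_coupling(nets, spec, "memory", 0.31))
asg  <- assign_membership(mc$models[["4"]], task_domain = nets$task_domain)
asg
#> Task-to-factor assignment (max_loading rule):
#>   vocabulary: synonyms, antonyms, picture_naming
#>   speed: pattern_comparison, letter_comparison, digit_symbol
#>   reasoning: matrix_reasoning, letter_sets, paper_folding
#>   memory: word_order, paired_associates, logical_memory
```

The imaging arm — pairwise masked spatial correlations, neural EFA, and
domain conjunction masks — recovers the same partition
(`assign_membership` on the neural 4-factor model groups the identical
task triplets), and the planted memory-domain coupling of r = 0.31 comes
back in the brain–behavior stage:

```r
maps  <- generate_task_maps(nets)
pcm   <- pairwise_matrix(maps, z = 2.3)         # 78 distinct values
masks <- lapply(asg$factors, function(tasks)
  domain_conjunction_mask(lapply(maps[tasks], threshold_mask, z = 2.3)))
betas <- generate_subject_betas(nets, behavior$factor_scores, seed = 2026)
brain_behavior(betas, masks, behavior, asg)
#> Brain-behavior coupling (outlier rule: 4.0 SD):
#>      domain   n       r       p n_outliers r_without_outliers p_without_outliers
#>  vocabulary 111  0.0898 0.34888          0             0.0898            0.34888
#>       speed 100 -0.0904 0.37120          0            -0.0904            0.37120
#>   reasoning 103  0.2051 0.03767          0             0.2051            0.03767
#>      memory 104  0.3027 0.00179          0             0.3027            0.00179
```

Only the memory domain was coupled (planted r = 0.31, recovered 0.303,
p = .0018). The smaller reasoning correlation is spillover: the memory
network template overlaps the reasoning conjunction mask, so memory
coupling leaks into the reasoning mask mean — overlapping networks do
this in real data too. Vocabulary and speed sit in the null band.

See `vignettes/latent-structure.Rmd` for the model details, every
tunable parameter, and what the synthetic generator does and does not
emulate.

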