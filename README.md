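# occufit

Single-season site-occupancy modelling for replicated
detection/non-detection surveys, built around the workflow used to map an
invasive marsupial (the common brushtail possum, *Trichosurus vulpecula*)
across five urban habitat types: forest fragments, amenity space and three
residential classes, each surveyed with three bite-mark detectors
("WaxTags") acting as exchangeable repeat surveys within one visit.

## Who this is for

Ecologists and biostatisticians analysing presence/absence surveys where
the species can be present but missed. The naive estimate — the fraction
of sites with at least one detection — underestimates occupancy whenever
per-replicate detection probability p < 1; the site-occupancy model
corrects for that.

## The model

Each site has a latent occupancy state `z ~ Bernoulli(ψ)`; given
occupancy, each replicate is detected with probability `p`. Marginalising
`z` gives the zero-inflated binomial site likelihood

```
detected ≥ once:   ψ · Π_j p^y_j (1 − p)^(1 − y_j)
never detected:    ψ · Π_j (1 − p)  +  (1 − ψ)
```

with `logit(ψ) = x'β` over site covariates (habitat cell means, a binary
supplementary-food indicator, proportion of forest fragment within a
buffer) and `logit(p) = w'α` (constant in all study models). Around the
likelihood the package provides:

- maximum-likelihood fitting with box constraints (±15 logit) so complete
  separation yields flagged boundary estimates instead of divergence;
- AICc model ranking (`AICc = deviance + 2K + 2K(K+1)/(n−K−1)`, n = sites)
  with Δi, Akaike weights and model likelihoods;
- naive occupancy, rank-based (Mann–Whitney) ROC AUC, and occupied-area
  projection `ψ̂ × hectares` per habitat;
- a synthetic survey generator whose defaults reproduce the study design
  (150 sites = 5 habitats × 30, 3 replicates, habitat-specific ψ, shared
  p = 0.49), for power and parameter-recovery studies.

## Worked example

Simulate a survey at the study design and run the whole-city analysis —
the two-model comparison (constant ψ vs habitat-dependent ψ), estimates,
area projection and AUC:

```r
library(occufit)
d <- simulate_occu(default_config(), seed = 42,
                   habitat_areas = study_habitat_areas())
report <- run_all_habitats_analysis(d)
print(report)
```

```
occupancy analysis (all_habitats): 150 sites, 3 replicates

model comparison (AICc):
            Model   AICc delta weight model_likelihood K deviance
 psi(Habitat)p(.) 330.27  0.00   1.00           1.0000 6   317.69
       psi(.)p(.) 372.68 42.41   0.00           0.0000 2   368.60

top model: psi(Habitat)p(.) 
 habitat  psi   se    p p_se
  Forest 0.85 0.09 0.55 0.05
 Amenity 0.37 0.10 0.55 0.05
    Res1 0.29 0.09 0.55 0.05
    Res2 0.22 0.08 0.55 0.05
    Res3 0.00 0.00 0.55 0.05

occupied-area projection:
 habitat area_ha  psi occupied_ha
  Forest     145 0.85       122.6
 Amenity     919 0.37       337.8
    Res1     302 0.29        88.8
    Res2    1921 0.22       423.7
    Res3     381 0.00         0.0
   Total    3668   NA       972.9

in-sample AUC of top model: 0.810
```

Reading it: the habitat model carries all the AICc weight, so occupancy
clearly varies by habitat. For this simulated survey ψ̂ runs from 0.85 in
forest down to a boundary-flagged 0.00 in the densest residential class
(SE 0 marks the boundary), detection per replicate is 0.55, and
multiplying ψ̂ by each habitat's extent projects 972.9 occupied hectares
of the 3668 surveyed. The AUC of 0.81 says a detected site outranks an
undetected one 81% of the time. `run_residential_analysis()` runs the
eight-model covariate comparison (residential class, food, forest area)
on the 90 residential sites the same way.

A thin command-line wrapper over the same functions is installed at
`inst/cli/occu.R` (`simulate`, `fit`, `analyze-all-habitats`,
`analyze-residential`).

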