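# qmnase

Quantitative analysis of MNase digestion time courses: kinetic modelling
that separates **nucleosome occupancy** from **chromatin accessibility**.

## The problem

Micrococcal nuclease (MNase) releases nucleosomes from chromatin and, if
digestion continues, destroys the released particles. The mononucleosome
count at a locus therefore depends on *when you stop digesting*, not just
on how many cells carry a nucleosome there — A/T-rich, accessible loci
peak early and are destroyed first; G/C-rich, less accessible loci appear
only late. A single MNase-seq sample confounds these effects, and the
conventional within-sample normalization destroys the absolute yields
needed to compare digestion levels.

`qmnase` is for chromatin biologists and computational genomicists who run
spike-in calibrated MNase digestion time courses (q-MNase-seq) and want
per-nucleosome occupancy and rate estimates instead of digestion-dependent
coverage.

## The model

Digestion at a locus is a consecutive first-order chain B → N → ∅ in the
digestion level d = [E]·t:

    B(d) = C·O·exp(-k1 d)
    N(d) = C·O·k1/(k1 - k2) · (exp(-k2 d) - exp(-k1 d))

with O the fraction of cells carrying a nucleosome, k1 the release rate
(accessibility), and k2 the over-digestion decay rate. N(d)/C — the
"apparent occupancy" — rises to a maximum at d\* = log(k1/k2)/(k1−k2) and
then decays as exp(−k2 d). Counting fragments at several digestion times
(default 1, 2, 5, 15, 40, 60 min), calibrating them with a constant
spike-in (normalized to 10,000 per sample), and least-squares fitting N(d)
recovers (O, k1, k2) per nucleosome. Typical nucleosomes have k1 ≈ 1/min;
fitted k1 > 10 flags fragile, weakly protecting complexes.

The package provides the full workflow: fragment reading/filtering
(100–200 bp), spike-in normalization, dyad/coverage tracks, cluster-median
nucleosome calling, per-locus fitting and classification (six time
classes, nine occupancy bins, fragile flag), fragment-length × A/T-content
2D occupancy summaries, a ground-truth digestion simulator, and an
end-to-end pipeline driver (`run_pipeline()`, or the thin
`inst/scripts/qnuc.R` CLI).

## A worked example

Fit one locus's noisy time course (Poisson counts, peak expectation 1,000,
truth O = 0.8, k1 = 1, k2 = 0.05 — O is recovered in count units):

```r
library(qmnase)
tt <- c(1, 2, 5, 15, 40, 60)
set.seed(42)
y <- simulate_counts(digestion_params(O = 0.8, k1 = 1, k2 = 0.05), tt, 1000)$counts
#> counts: 793 978 1001 584 173 59
summary(digestion_fit(tt, y))
#> Digestion kinetics fit (B -> N -> 0)
#>   O  = 1215 (occupancy, count units / scale)
#>   k1 = 1.076 /min (release), k2 = 0.0509 /min (decay)
#>   rss = 1385 over 6 points; converged: TRUE
#>   class: typical nucleosome (k1 <= 10); strongest signal at time point 3 (5 min)
#>   model peak at d* = 2.977 min, height 1044
```

The rates come back within ~8% and the curve peaks near 3 min, between
the 2- and 5-min samples — which is also why the locus lands in time
class 3. End to end, on a simulated 50 kb genome with known truth:

```r
recovery_harness(sim_config(genome_length = 5e4, seed = 11))
#> Digestion-simulation recovery report
#>   planted positions matched within tolerance: 100.0% (250 planted, 250 called)
#>   fits converged: 98.8%
#>   median relative errors: O 5.90%, k1 19.30%, k2 11.58%
#>   fragile classification: sensitivity 0.6666667, specificity 0.9754098
```

All 250 planted nucleosomes are called within 20 bp and the kinetic
parameters are recovered to ~5–20% at this sequencing depth. Fragile
sensitivity is limited by the time design, not the fitter: once
k1·t_min ≫ 3 the data only bound k1 from below (see the methods vignette,
`vignettes/digestion-kinetics.Rmd`).

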