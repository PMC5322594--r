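# mosqcomp

Detecting and quantifying asymmetric interspecific larval competition between
*Aedes albopictus* and *Culex pipiens* from adult-female trap-count time
series.

## The problem

The two most widespread urban mosquitoes of temperate Europe share larval
habitats, and laboratory experiments show a one-sided interaction there:
*Ae. albopictus* larvae raise the mortality of co-occurring *Cx. pipiens*
larvae while being essentially unaffected themselves. In trap data this
competition shows up only indirectly — as an early-season decline of
*Cx. pipiens* coinciding with the rise of *Ae. albopictus* — and is easily
confounded with a "temporal niche" effect: the species' abundance peaks can
separate simply because their thermal optima differ. `mosqcomp` separates
the two mechanisms mechanistically, for ecologists and vector-surveillance
analysts working with paired capture series.

## What the package does

For each site-year of paired capture data the pipeline:

1. simulates daily stage-structured dynamics (eggs, larvae, pupae, adult
   females, plus species-appropriate overwintering stages) of both species,
   driven by temperature and photoperiod, with intraspecific larval crowding
   (`rho_s L_s`) and the asymmetric competition term

   `mu_comp = c * L_alb * 1{T >= 15 °C}`

   acting on *Cx. pipiens* larvae only;
2. calibrates the five free parameters (two capture rates `alpha`, two
   crowding factors `rho`, competition coefficient `c`) by random-walk
   Metropolis–Hastings against a Poisson likelihood of the session counts,
   with mean `alpha_s * A_s(t)`;
3. fits the same model with `c = 0` (independent populations) and selects
   between the two by DIC — competition is called only when
   `DIC_indep - DIC_comp > 4`;
4. computes the interspecific delay `T = argmax_tau sum_t X[t] Y[t+tau]`
   (raw cross-correlation of the weekly *Cx. pipiens* and *Ae. albopictus*
   series; positive `T` = albopictus later);
5. quantifies competition counterfactually from the posterior: the relative
   reduction of mean *Cx. pipiens* abundance against a `c = 0` twin
   simulation, and the onset date at which the relative difference first
   exceeds 10%.

A synthetic-data module generates seasonal temperature (sinusoid + AR(1)
noise, cool 20.6 °C or warm 25.5 °C July–September means), biweekly 24-h
trap sessions and Poisson counts with known ground truth, so the whole
pipeline is testable end to end without any external data. See
`vignettes/mosqcomp-methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(mosqcomp)

# a small synthetic study: 4 warm-year site-years, 2 with strong competition
study    <- generate_study(4, 0.5,
                           template = scenario_config(summer_mean = 25.5, seed = 42),
                           c_range  = c(7.5e-3, 7.5e-3))
datasets <- lapply(study$sites, `[[`, "dataset")

res <- analyze_study(datasets, seed = 1, n_effect_draws = 50)
print(build_report(res, datasets))
```

```
Study report
============

Classification (DIC rule):
     group n competition competition_pct independent independent_pct
 All years 4           2              50           2              50
      2015 4           2              50           2              50

Interspecific delay by year (days):
 group n mean  q2.5  q25 median q75 q97.5
   all 4   49 15.05 24.5   52.5  77    77
  2015 4   49 15.05 24.5   52.5  77    77

Interspecific delay by selected model (days):
       group n mean  q2.5  q25 median  q75 q97.5
         all 4   49 15.05 24.5   52.5 77.0 77.00
 competition 2   77 77.00 77.0   77.0 77.0 77.00
 independent 2   21 14.35 17.5   21.0 24.5 27.65

Competition effects (competition-classified sites):
 site year reduction_median reduction_q2.5 reduction_q97.5 onset_date
  S01 2015         0.556804      0.3088522       0.7188276 2015-05-29
  S02 2015         0.501541      0.2650374       0.7363753 2015-05-29
```

Both competition sites (true `c = 7.5e-3`) are recovered, both independent
sites are kept independent, delays are much larger at competition sites
(77 vs 21 days on average), and the posterior counterfactual estimates a
50–56% median suppression of *Cx. pipiens* with onset in late May — the
signature the method is designed to detect.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mosqcomp.R simulate --n-sites 10 --fraction 0.5 --seed 1 --out-dir study
Rscript inst/cli/mosqcomp.R analyze  --captures study/captures.csv \
    --temperature study/temperature.csv --seed 1 --out-dir results
```

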