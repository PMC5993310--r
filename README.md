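# hwclust

Fast maximum-likelihood genetic clustering for co-dominant markers
(SNPs, microsatellites): assignment of individual multilocus genotypes to
panmictic populations, detection of hybrid classes between two parental
populations, and information-criterion guidance for the number of clusters —
together with a Balding–Nichols population simulator and the evaluation
metrics needed to benchmark the whole pipeline without external data.

## Who this is for

Population geneticists, molecular ecologists and conservation biologists who
need STRUCTURE-style membership probabilities — genuine probabilities under
an explicit population-genetic model, not geometric proximities — but at the
speed of geometric clustering, e.g. when scanning many values of K,
bootstrapping, or running simulation studies.

## The model

Individuals `i = 1..N` carry allele-count vectors `x_ij` at loci `j = 1..J`
(ploidy `π` copies per locus). Given a partition `g` of individuals into `K`
groups with within-group allele frequencies `f_kj`, Hardy–Weinberg random
mating makes each genotype a multinomial draw:

    p(x_ij | g(i)=k) = M(x_ij; f_kj, π)

Loci are treated as independent, so the classification log-likelihood of a
clustering solution is

    LL(g) = Σ_i Σ_j log M(x_ij; f_{g(i),j}, π)

`hwclust()` maximises `LL(g)` with a hard-assignment (classification) EM
algorithm: re-estimate `f` as within-group relative allele frequencies
(E step), compute standardised-likelihood membership probabilities and
re-assign every individual to its most likely group (M step), until the
log-likelihood changes by less than `tol = 1e-10`. Starting points come from
Ward clustering (default, deterministic), K-means on PCA scores, or a
50-replicate random multi-start.

For hybrid detection between parental populations A and B, a class with
hybridisation coefficient `w` (the genome fraction inherited from A) has
mixture frequencies `f_H = w f_A + (1 − w) f_B`; F1 ↔ `w = 0.5`, first and
second backcrosses ↔ `0.25/0.75` and `0.125/0.875`. Only the two parental
frequency sets are free parameters.

Model comparison across K uses penalised deviances with `k = K(P − J)` free
parameters (`P` = total alleles): `AIC = −2L' + 2k`,
`AICc = −2L' + 2kN/(N−k−1)`, `BIC = −2L' + ln(N) k`,
`KIC = −2L' + 3(k+1)`.

## Worked example

```r
library(hwclust)

toy <- read_genepop(system.file("extdata", "toy_sim.gen", package = "hwclust"))
fit <- hwclust(toy, k = 2)
fit
#> hwclust fit: K = 2 groups, 32 individuals, 12 loci
#>   log-likelihood L' = -223.4812  (24 free parameters)
#>   3 EM iterations, converged: TRUE, init: ward
#>   group sizes:  1=17, 2=15

pairwise_tpr_tnr(attr(toy, "pop"), fit$assignment)[c("tpr", "tnr")]
#> $tpr [1] 0.9375   $tnr [1] 0.9375
```

`fit$memberships` holds the N×K membership probabilities; `plot(fit)` draws
the STRUCTURE-style composition barplot. With only 12 loci the two simulated
populations are recovered up to a couple of borderline individuals (TPR =
TNR = 0.94); accuracy rises quickly with marker number.

Hybrid detection on a simulated cross (two parents at Fst ≈ 0.4, 300 SNPs,
10 individuals per hybrid class):

```r
sim <- build_hybrid_dataset(n_loci = 300, fst = 0.4, seed = 1)
hyb <- hwclust(sim$genotypes, hybrids = hybrid_scheme(c(0.5, 0.25, 0.125)),
               seed = 1)
round(correct_assignment(sim$labels, hyb)$per_class, 2)
#>     P1     P2     F1 BC1-P1 BC1-P2 BC2-P1 BC2-P2
#>   1.00   0.99   1.00   1.00   0.90   1.00   1.00
```

Choosing the number of clusters on three simulated populations
(Fst ≈ 0.5, 200 SNPs):

```r
sim3 <- simulate_populations(3, 100, 200, fst = 0.5, seed = 1)
choose_k(sim3$genotypes, k_range = 1:5, seed = 1)
#>  K loglik n_params converged   AIC  AICc   BIC   KIC  d_AIC ...
#>  1 -49367      200      TRUE 99134 99946 99874 99337     NA
#>  2 -37028      400      TRUE 74856 71680 76338 75259 -24277
#>  3 -27021      600      TRUE 55242 52846 57464 55845 -19615
#>  4 -26858      800      TRUE 55317 52759 58280 56120     75
#>  5 -26708     1000      TRUE 55416 52560 59120 56419     99
#> criterion minima:  AIC at K=3, AICc at K=5, BIC at K=3, KIC at K=3
```

The sharp drop of all criteria up to K = 3 and the flat tail beyond is the
signature of three real clusters. (Here the AICc correction is outside its
validity domain — more free parameters than individuals for K ≥ 2 — and its
argmin is not meaningful; see the methods vignette.)

A command-line wrapper with `fit`, `choose-k`, `hybrids`, `simulate` and
`evaluate` subcommands is installed under `inst/cli/hwclust-cli`.

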