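---
title: "Likelihood-based genetic clustering with hwclust: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based genetic clustering with hwclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hwclust)
```

## The clustering model

`hwclust` treats a genetic cluster as a panmictic population. For diploid
(or, generally, ploidy-$\pi$) individuals genotyped at $J$ co-dominant loci,
the genotype of individual $i$ at locus $j$ is an allele-count vector
$x_{ij}$ summing to $\pi$. Under Hardy–Weinberg random mating within group
$k$, $x_{ij}$ is a multinomial draw of $\pi$ allele copies from the group's
allele-frequency vector $f_{kj}$:

$$p(x_{ij} \mid g(i)=k) = M(x_{ij};\, f_{kj}, \pi)
  = \frac{\pi!}{\prod_a x_{ija}!} \prod_a f_{kja}^{\,x_{ija}}.$$

Loci are assumed independent (no linkage disequilibrium) and individuals are
independent given their group, so the *classification log-likelihood* of a
partition $g$ is $LL(g) = \sum_i \sum_j \log M(x_{ij}; f_{g(i)j}, \pi)$.
The multinomial coefficient is included so that every term is a true
log-probability; it is constant across groups and across $K$, so membership
probabilities and all criterion *differences* are unaffected by this
convention. Membership probabilities are standardised likelihoods,
$p(g(i)=k) = p(x_i \mid f_k)/\sum_q p(x_i \mid f_q)$, computed in the log
domain with a log-sum-exp normalisation.

Missing genotypes (the `00`/`000` Genepop code, STRUCTURE's `-9`, VCF
`./.`) contribute nothing: they are excluded from every likelihood sum and
from the numerator and denominator of frequency estimation
(missing-at-random maximum likelihood, no imputation). The one exception is
the geometric initialisers, which need complete profiles and mean-impute
missing entries — the EM itself never sees imputed data.

## The hard-assignment EM

`hwclust()` alternates

1. *expectation*: re-estimate $f_{kj}$ as the relative allele frequencies
   among individuals currently in group $k$ (their ML estimate), and compute
   all membership probabilities;
2. *maximisation*: re-assign every individual to its most likely group;

until $|\Delta LL| <$ `tol` (default $10^{-10}$) or the assignment is
stable (a fixed point, at which the next $LL$ cannot change), up to
`max_iter = 100` iterations. Both steps are monotone in $LL(g)$, so the
trace never decreases in plain clustering mode; the tests assert this on
every fit.

Numerical safeguards, all of which concern situations the basic algorithm
leaves undefined:

* **Frequency smoothing** (`alpha`, default $10^{-6}$): a pseudo-count added
  to every allele count during estimation. Without it, a group that loses an
  allele gives $-\infty$ log-likelihoods to every carrier of that allele and
  the fit can collapse. $10^{-6}$ of an allele copy is far below the
  resolution of any realistic sample and leaves reported frequencies
  unchanged to ~6 decimals.
* **Empty-group repair**: if a re-assignment empties a group, the group is
  re-seeded with the individual least certain of its current assignment
  (lowest maximum membership). This keeps $K$ fixed; repairs are counted in
  the result (`n_repairs`).
* **Best-of-trace**: hard assignment can in principle cycle on near-ties;
  the returned state is the iteration with the highest $LL$ seen, not
  necessarily the last.
* **Tie-breaking**: argmax ties go to the lowest group index,
  deterministically across platforms.

### Starting points

The EM is deterministic given its start, and can be trapped in local maxima.
Three initialisations are provided:

* `ward` (default): Ward-linkage hierarchical clustering (`hclust`,
  `ward.D2`) on Euclidean distances between individual allele-frequency
  profiles (counts$/\pi$), tree cut at $K$. Fully deterministic. The input
  space for Ward is a genuine design choice — raw counts, scaled
  frequencies and PCA scores are all defensible; frequency profiles were
  chosen so that loci with many alleles do not dominate purely by count
  scale.
* `kmeans`: K-means (10 restarts) on principal-component scores retaining
  `var_retained = 0.9` of the total variance.
* `random`: the brute-force strategy — `n_start = 50` uniform random
  partitions (each group guaranteed non-empty), keeping the best final
  likelihood.

On the simulated data used in the tests the three give equivalent results;
`ward` is the default because it is fast and reproducible without a seed.
All randomness in a fit flows from the single `seed` argument, and the
caller's RNG state is restored afterwards.

## Hybrid classes

With `hybrids = hybrid_scheme(...)` the model becomes: two free parental
populations A and B plus derived classes whose frequencies are the mixtures
$f_H(w) = w f_A + (1-w) f_B$, where $w$ is the fraction of the class's
genome inherited from A. `hybrid_scheme(c(0.5, 0.25, 0.125))` with
complement expansion (the default) yields the seven-class ladder A, BC2-A,
BC1-A, F1, BC1-B, BC2-B, B. The EM is unchanged except that only $f_A$ and
$f_B$ are re-estimated — from the individuals currently assigned to the
parental classes only. Letting hybrid-assigned individuals contribute
$w$-weighted counts to the parental estimates would also be defensible and
could matter when hybrids greatly outnumber parents; the simpler rule was
chosen because it is exactly ML for the parental subsample and keeps the
parameter count transparent. A consequence worth knowing: the parental
update is not a full joint-ML step (hybrid-class likelihoods also depend on
$f_A, f_B$), so in hybrid mode strict monotonicity of the trace is not
guaranteed — in practice the trace is monotone on all tested datasets, and
best-of-trace semantics cover the exception.

Class labels attach to $w$ values, not to data order; "A" is whichever
parental pole the initial two-group split labels first. The evaluation
helpers (`correct_assignment()`, `mean_support()`) therefore re-orient the
fit's poles against the truth by majority vote among truth-parental
individuals before scoring.

## Choosing the number of clusters

Each of the $K$ groups contributes $P - J$ free allele frequencies ($P$ =
total alleles), so $k = K(P-J)$ parameters in plain mode and $2(P-J)$ in
hybrid mode (derived classes add none). Four penalised deviances are
reported by `choose_k()`: AIC, AICc, BIC, KIC (formulas in the README).
`choose_k()` deliberately reports rather than auto-selects: the reliable
signature of the supported $K$ is a sharp drop followed by a flat tail
(surfaced as the first-difference columns), not the literal argmin.

Two caveats, both visible in the package's own tests:

* **AICc domain.** The small-sample correction divides by $N - k - 1$. With
  dense SNP panels $k$ routinely exceeds $N$ (e.g. 200 biallelic loci,
  $K = 2$, $N = 300$ gives $k = 400$), the denominator flips sign and the
  "penalty" decreases with model size, dragging the argmin to the largest
  $K$ scanned. The implementation follows the printed formula (erroring only
  at the exact singularity $N = k + 1$ and warning outside the domain),
  because the formula is what the field's reference implementation computes;
  but AICc should simply not be used for model choice when $k \ge N - 1$.
* **Argmin overfitting at large $N$.** The classification EM's likelihood
  gain from splitting a true cluster grows roughly linearly with $N$ while
  the AIC/KIC penalties are constant in $N$, so for large samples their
  strict argmin drifts above the true $K$ even when the drop-then-flat
  elbow remains unambiguous. BIC's $\ln(N)$ penalty is the most robust of
  the four in this regime.

## The simulator

`simulate_populations()` emulates the observable that clustering performance
is usually conditioned on — the realized $F_{st}$ between populations —
rather than any particular forward-in-time demography. Ancestral biallelic
frequencies are uniform on $[\texttt{maf\_floor}, 1-\texttt{maf\_floor}]$
(default floor 0.05), population frequencies follow the Balding–Nichols
Beta distribution with divergence parameter set to `fst`, and genotypes are
HW multinomial draws. Under the island model all populations diverge
independently from the ancestor; under the 1-D stepping-stone model each
population is a Balding–Nichols step (divergence `fst/2`) from its
neighbour, giving spatially autocorrelated frequencies. The mapping from
`fst` to the mean realized multilocus Weir–Cockerham $\theta$ is ~1:1 over
the range 0.05–0.6 and monotone (property-tested), so simulation scenarios
are specified directly by their target differentiation. Default sizes (100
diploids per population, 2–15 populations, 20–500 loci) mirror the standard
simulation designs for this problem class.

What the surrogate deliberately does not reproduce: mutation processes,
selection, linkage, overlapping generations, drift dynamics over time, and
any specific dispersal-rate calibration. Tests passing on these simulations
show that the estimator recovers structure of a given strength under HW
equilibrium and free recombination — not that it is robust to LD, null
alleles, or genotyping error in real data.

`hybridize()` draws each hybrid gamete from the *empirical allele
frequencies* of the parental pool (population-level gamete sampling), not
by Mendelian segregation within tracked parent pairs; chaining calls
produces backcrosses (`BC1 = hybridize(F1, P1)`, etc.). This matches the
construction used for hybrid-detection benchmarks in this literature;
individual-level pedigree simulation would add within-family correlation
that the population-level model ignores anyway.
`build_hybrid_dataset()` assembles the standard benchmark: 100 + 100
parents and 10 individuals per hybrid class (250 in total) by default.

## Evaluation metrics

For unlabelled clusterings, `pairwise_tpr_tnr()` scores all $N(N-1)/2$
pairs exactly from the truth × prediction contingency table: TPR = fraction
of same-population pairs clustered together; TNR = fraction of
different-population pairs kept apart. Both are invariant to cluster
relabelling, and TPR + TNR is proportional to the Rand index. Exact
counting is $O(K^2)$, so no pair subsampling is needed at any realistic
size. For labelled hybrid fits, `correct_assignment()` and `mean_support()`
give per-class correct-assignment rates and mean membership probability of
the true class, after the majority-vote pole matching described above.

## Problem sizes used by the test suite

The packaged checks run, per invocation: 20-replicate TPR curves for two
populations of 100 at $F_{st}$ 0.1/0.6 with 50 and 500 loci; a pooled grid
of $F_{st} \in \{0.1, 0.2, 0.4, 0.6\} \times$ loci $\in \{50, 150, 500\}
\times$ 2–6 populations with 3 seeds per cell (108 fits); 20 hybrid
benchmarks at $F_{st} = 0.4$ with 300 loci; 100 exhaustive-search
comparisons at $N \le 8$ (where the global optimum is enumerable); and
10-seed criterion scans at 3 × 100 individuals × 200 loci. These sizes were
chosen as the smallest at which the quantities of interest are stable
across seeds.

## Known limitations

* One constant ploidy across individuals and loci (the likelihood extends
  naturally to varying ploidy, but the containers currently do not).
* Hard assignment: admixed individuals cannot be represented except through
  explicit mixture classes (the hybrid model); there is no per-individual
  admixture proportion.
* Two parental populations at most in hybrid mode.
* No uncertainty measure on membership probabilities; bootstrap over loci is
  the natural add-on.
* Independence between loci is assumed; dense panels with strong LD violate
  it and the likelihood becomes an approximation.
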