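---
title: "Modelling geographical parthenogenesis under sexual conflict: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographical parthenogenesis under sexual conflict: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoparth)
```

## The question and the model

Obligately asexual animals tend to occupy more marginal, less productive
parts of a range than their sexual relatives — *geographical
parthenogenesis*. geoparth implements an individual-based model asking
whether the same spatial patterning can arise within a single **facultatively
parthenogenetic** metapopulation, driven by the interaction of sexual
conflict over mating frequency with a core-to-edge gradient in environmental
productivity.

The world is a chain of eight habitats at distances $d = 0$ (productive
core) to $d = 7$ (edge), each an $n \times n$ grid of patches holding at
most one adult, so the local carrying capacity is $N = n^2$ (default
$n = 20$, $N = 400$). Generations are discrete and non-overlapping. Each
individual carries 21 diploid, biallelic, unlinked autosomal loci:

* 10 **coercion** loci — the male-limited phenotype is the allele sum
  $\mu_m \in [0, 20]$;
* 10 **resistance** loci — the female-limited phenotype is the allele sum
  $\omega_f \in [0, 20]$;
* 1 **reproductive-mode** locus with alleles $p$ (wild type) and $P$, a
  dominant, female-limited mutant that lets *virgin* females produce
  daughters asexually.

Each generation runs, in fixed order: **mating** → **reproduction** →
**dispersal** → **recruitment**.

**Mating.** Males court the up-to-8 females in the Moore neighbourhood of
their patch. An attempt proceeds only if $\mu_m \ge \omega_f$, and succeeds
with probability $J = 1 - \xi \mu_m q$ (clamped to $[0,1]$), where $q$ is
the male's running mating tally — a trade-off that makes coercion costly.
Successful sperm enters the female's sperm pool; a female's mating number
$x$ is bounded by her male neighbourhood size $h \le 8$.

**Female fitness.** Fitness is piecewise in $x$, multiplied throughout by
the cost of resistance $\Phi = 1 - \zeta \omega_f h$ (clamped to $[0,1]$):

$$
W_{\text{wild type}} =
\begin{cases}
0 & x = 0\\
\max\!\big(0,\, a - m(x-1) - d\kappa\big)\,\Phi & 1 \le x \le 8
\end{cases}
\qquad
W_{\text{mutant}} =
\begin{cases}
\max\!\big(0,\, \varepsilon a - d\kappa\big)\,\Phi & x = 0\\
\max\!\big(0,\, a - m(x-1) - d\kappa\big)\,\Phi & 1 \le x \le 8
\end{cases}
$$

$a$ is the fecundity maximum at a single mating, $m$ the fecundity loss per
additional mating (the intensity of sexual conflict), $\varepsilon$ the
fecundity of parthenogenesis relative to $a$, and $v = d\kappa$ the
ecocline penalty. The two definitions differ only in the virgin piece:
mutant virgins reproduce parthenogenetically, with fecundity equal to a
once-mated female's when $\varepsilon = 1$, so mating once is never costly
for any female. Mated mutants behave exactly like mated wild types (they
forgo parthenogenesis once inseminated).

**Reproduction.** A female produces $W$ offspring rounded to the nearest
integer (halves up). Mated females draw *one* partner from their sperm pool
to sire the whole brood (sperm from a single mating suffices for all eggs);
offspring are sons or daughters with equal probability, inheriting one
uniformly chosen allele per locus from each parent. Virgin mutant females
produce daughters only, each inheriting, at every locus, *two draws with
replacement* from the mother's two alleles — automixis, which lets
heterozygous mothers produce homozygous daughters (including $pp$ daughters
of $pP$ mothers) while never breaking up a homozygous locus.

**Dispersal and recruitment.** Each offspring disperses with probability
$\gamma$ to a uniformly chosen adjacent habitat (the chain has explicit
ends). If the offspring pool of a habitat exceeds $N$, a uniform random
excess dies; survivors settle on distinct random patches and mature.

**Schedule.** Runs start with every habitable habitat full of $pp$ adults
of random sex, with the 20 antagonistic loci drawn i.i.d. from
$U\{0,1\}$ — standing genetic variation on which sexually antagonistic
coevolution acts during a 50-generation burn-in. Refuge scenarios make only
the core (small), the four core-most habitats (large), or all habitats
(none) initially habitable. At the start of generation `burn_in` two things
happen at once, mimicking post-glacial invasion: all habitats become
habitable, and a single mutation event converts a quarter of the core
habitat's adults (both sexes; males transmit $P$ too) to mutants, half
$pP$, half $PP$.

## Parameters, defaults, and why

| parameter | meaning (units) | default | rationale |
|---|---|---|---|
| `a` | fecundity maximum at $x=1$ (offspring) | 6 | makes the $\kappa=0.7$ edge an immigration-fed sink for parthenogens ($\varepsilon a - 7\kappa \approx 0.5 < 1$, so edge density stays low but non-zero) while the $\kappa=0.4$ edge remains viable ($\varepsilon a - 2.8 \approx 2.6$); larger $a$ (e.g. 8) makes all-female edge populations self-sustaining, and they then fill to carrying capacity and drag the whole metapopulation to male extinction even under a steep ecocline |
| `m` | fecundity loss per extra mating (offspring) | 1.5 | the intense-conflict setting used in the epistasis scenario |
| `epsilon` | relative parthenogenetic fecundity | 0.9 | inside the invasion range, below the male-extinction-everywhere regime |
| `kappa` | ecocline steepness (offspring per habitat step) | 0 | flat baseline; 0.4/0.7 used as shallow/steep gradients |
| `zeta` | resistance-cost slope | 0.005 | keeps $\Phi \ge 0.2$ even at $\omega_f=20, h=8$ |
| `xi` | coercion trade-off slope | 0.01 | a maximally coercive male's second attempt still succeeds at $J=0.8$ |
| `gamma` | offspring dispersal probability | 0.1 | moderate stepping-stone coupling: a habitat exchanges ~10% of offspring with neighbours |
| `n` | habitat side ($N=n^2$) | 20 | full-scale carrying capacity 400 |
| `generations` / `burn_in` | schedule | 500 / 50 | coevolution approaches equilibrium before the pulse |
| `pulse_fraction` | fraction of core adults mutated | 0.25 | minimises drift on the fate of $P$; a 1% all-heterozygote variant is available (`pulse_zygosity = "het"`) |

All are validated by `sim_config()`; YAML files (`load_config()`) and the
CLI (`inst/cli/geoparth.R`) expose the same names.

## Design choices where the design was open

* **Ecocline application.** With $\kappa$ up to 0.7 and $d$ up to 7 the
  penalty reaches 4.9, so a naive multiplier $(1 - v)$ would go negative.
  The default applies $v$ *subtractively* with a clamp at zero;
  `ecocline_mode = "multiplicative"` applies a clamped multiplier
  $\max(0, 1-v)$ instead. In both modes $\varepsilon$ scales $a$ alone, so
  the $\varepsilon = 1$ virgin/once-mated equivalence holds exactly.
* **Automixis as draws with replacement.** Two independent draws per locus
  from the mother's pair reproduce partial recombination (heterozygous
  mothers yield homozygous daughters at rate 1/2); sampling *without*
  replacement would make parthenogenesis clonal. Allele state is stored as
  two explicit slots per locus, not a dosage, because the two
  representations differ under replacement sampling.
* **Pulse rounding.** The mutant count is `round(fraction * N_core)`
  (halves up); an odd count splits as $\lceil k/2 \rceil$ $pP$ and
  $\lfloor k/2 \rfloor$ $PP$ — deterministic given the sampled set.
* **Mating order.** Males act serially in uniform random order (avoiding
  positional bias), each attempting every neighbouring female exactly once
  in shuffled order; $q$ is read live, so a male's earlier successes lower
  his later odds within the same generation. $h$ (in $\Phi$) counts
  neighbouring males before any outcomes, so even females who repel every
  attempt pay the cost of resisting them.
* **Glaciated terrain is lethal** to dispersers by default (the uniform
  choice among geometric neighbours is preserved);
  `dispersal_lethal = FALSE` switches to choosing among habitable
  neighbours only.
* **Mutation variant.** The 1%-mutation variant is implemented as a
  one-time pulse by default; `pulse_recurrent = TRUE` instead mutates
  wild-type core adults at the given per-generation rate from the end of
  the burn-in onwards — an interpretation toggle, since only the pulse
  variant is fully pinned down.
* **Rounding of $W$** is half-up, the `round` convention of most
  agent-based modelling platforms, so e.g. $W = 2.5$ yields 3 offspring.

## Analysis procedures

`run_replicates()` runs seeds `seed_base .. seed_base + R - 1`;
`grid_experiment()` crosses $\kappa \times m \times \varepsilon$ with
disjoint seed blocks per cell and reports across-replicate medians per
habitat plus a male-extinction flag (majority of runs with zero males
metapopulation-wide). `robustness_experiment()` re-runs a baseline with
single assumptions removed (coevolution, either cost, productivity shifted)
and scores each perturbation with the **Vargha–Delaney A-test**
($A = [\#(x>y) + \tfrac12\#(x=y)]/nm$, computed via the rank-sum identity);
$A \ge 0.8$ or $\le 0.2$ marks a qualitatively large, i.e. non-robust,
change. `sensitivity_experiment()` draws Latin-hypercube parameter sets
(each parameter's range cut into one bin per set, every bin used exactly
once) over $\kappa \in [0, 0.7]$, $m \in [0, 2]$,
$\varepsilon \in [0.7, 1]$, $\gamma \in [0, 0.5]$, and scores each
parameter with **Spearman partial rank correlations** against median
responses. Partial correlations are computed by correlating the residuals
of rank-regressions (defined even when a response is an exact monotone
function of one parameter, where the precision-matrix route is singular);
ties get average ranks; p-values use the t approximation with
$df = n - 2 - g$.

`epistasis_diagnostics()` tabulates mean realised female fitness by
(resistance allele count) × (reproductive-mode genotype) × (mating status)
from per-female snapshots (`diagnose_at`), plus the covariance between $P$
dosage and $\omega_f$ — the linkage-disequilibrium summary behind
female-biased cores. `preset_config("fig5")` is the canonical snapshot
scenario (small refuge, $\kappa = 0.7$, $m = 1.5$, $\varepsilon = 0.9$).

## What the simulated data do and do not emulate

All data are generated internally; there is no empirical input. The
generator emulates a closed metapopulation with discrete generations,
hard-ceiling local density regulation, nearest-neighbour dispersal, purely
additive unlinked genetics, and deterministic phenotype-fitness maps with
all stochasticity in Bernoulli/uniform draws. It does **not** emulate
overlapping generations, age or condition structure, environmental
stochasticity, sex-biased or long-range dispersal, linkage or mutation at
the antagonistic loci, or realistic automixis variants (central/terminal
fusion). Passing tests therefore demonstrate internal consistency of this
idealised system, not predictions for any particular natural population.

## Numerical and degenerate-input conventions

$J$, $\Phi$ and all fitness pieces are clamped before use, so every
probability lies in $[0,1]$ and $W \ge 0$ under any admissible parameters.
Empty habitats persist (local extinction is possible and meaningful);
empty samples are rejected by the A-test; constant columns are rejected by
`spearman_partial` (ranks undefined); a degenerate Latin-hypercube range is
an error. `generations = 0` returns the initial census only. A single root
seed drives everything; replicate and grid seeds are derived by the
documented counter scheme, so any replicate is reproducible in isolation
and identical configurations are bitwise identical.

## Problem sizes used in the shipped analyses

The package's own experiments are desk-scale reductions chosen once: the
invasion-threshold sweep uses $n = 10$, 200 generations, 10 replicates per
$\varepsilon$; the spatial-pattern comparisons keep the full 500-generation
horizon (spatial gradients take long to settle) at reduced spatial scale
$n = 10$, with 8 replicates per condition and medians across replicates.
The full-scale setting of record remains $n = 20$, 500 generations and 50
replicates.

## Known limitations

Small-$N$ reductions exaggerate drift: metapopulation-wide male extinction
absorbs runs that at $N = 400$ would retain males at the core, and complete
fixation of $P$ near its invasion threshold can outlast a shortened
horizon, so the desk-scale invasion threshold is resolved no finer than one
grid step in $\varepsilon$. The equation constants $a$, $\zeta$, $\xi$,
$\gamma$ are package defaults (documented above), not published values;
conclusions that hinge on their exact magnitudes should be re-derived with
`sensitivity_experiment()`. One known sensitivity: under a steep ecocline
the all-female edge is colonized by automictic lineages whose resistance
alleles hitchhike with $P$, so with the default costs the core-to-edge
gradient in pooled resistance/coercion frequencies comes out flat to
slightly edge-high rather than core-high; the sex-ratio and density
gradients are unaffected.
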