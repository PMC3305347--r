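---
title: "Neurogenic restructuring of a bulbar network: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurogenic restructuring of a bulbar network: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulbgenesis)
```

## The model

`bulbgenesis` simulates structural plasticity in the recurrent network formed
by the principal mitral cells and the inhibitory granule cells of the
olfactory bulb. The neurons themselves are treated minimally, as firing-rate
units whose activities relax quickly to a steady state for each odor; the
dynamics of interest is the much slower evolution of the *connectivity*
driven by adult neurogenesis and activity-dependent apoptosis.

**Steady-state activities.** Each odor stimulus $\mu$ delivers a nonnegative
glomerular drive $S_i^\mu$ to mitral cell $i$, which also has a spontaneous
activity $s_0$. Granule cell $j$ is excited (weight 1) by the set of mitral
cells it connects to, and, through the reciprocal dendrodendritic synapses,
inhibits the same cells with weight $w$. At the threshold-linear steady
state,

$$
m_i = \Big[ S_i^\mu + s_0 - \sum_j w_{ji}\, g_j \Big]_+ , \qquad
g_j = \Big[ \textstyle\sum_{i \in \text{sources}(j)} m_i \Big]_+ ,
$$

with $[x]_+ = \max(x, 0)$. When the spontaneous activity keeps all
activities positive, the rectifiers are inactive and the mitral steady state
collapses to a single linear solve per stimulus,
$(\mathbb{1} + W)\,\mathbf{m} = \mathbf{S}^\mu + s_0$, where
$W_{ik} = \sum_j w_{ji}\,c_{jk}$ is the *effective connectivity*: the total
disynaptic inhibition from mitral cell $k$ onto mitral cell $i$ mediated by
shared granule cells. Under full reciprocity and uniform weights $W$ is $w$
times a Gram matrix of shared-granule counts — symmetric and positive
semi-definite. `solve_steady_state()` implements both modes; the linear mode
is the default, and the package verifies the algebraic reduction against
damped fixed-point iteration of the coupled equations in its test suite.

Because excitation is nonnegative, the granule rectifier can never bind once
the mitral activities are clipped at zero, so the rectified steady state is
exactly a linear complementarity problem in $\mathbf{m}$. It is solved by
active-set iteration with a damped-iteration fallback whose step size is
bounded through the largest row sum of $W$ (a Gershgorin bound on the
inhibitory spectrum).

**Turnover.** Time advances in survival-assessment intervals. In each step,
`influx` new granule cells are added, each wired to $K$ distinct,
uniformly chosen mitral cells (no cell connects to any mitral cell twice).
Every granule cell's *resilience* is its thresholded activity summed over
the stimulus ensemble,

$$ R_j = \sum_{\mu} \big[ g_j^\mu - \theta_R \big]_+ , $$

and it survives the step with probability
$T(R) = \big(1 + e^{-k (R - \theta_S)}\big)^{-1}$ — a sigmoid with soft
threshold $\theta_S$ and steepness $k$. Removal draws are independent across
cells; newly added cells are assessed in the same step they arrive (they
experience the full ensemble within their first assessment interval).

The rectifier in $R$ is the model's co-activity detector: at fixed total
activity it makes the resilience concave in the activity profile, so a cell
with a few strong responses (one connected to mitral cells that are strongly
co-active in some stimulus) outlives a cell with many intermediate responses
(one whose partners are strong only in *different* stimuli — an
"interfering" cell). The surviving connectivity therefore concentrates
lateral inhibition between co-active mitral cells, which is precisely what
decorrelates highly similar stimulus pairs.

## Parameters

| Parameter | Symbol | Default | Meaning |
|---|---|---|---|
| `connections` | $K$ | 8 (2 in mean-field work, 1 as control) | mitral cells per granule cell |
| `inh_weight` | $w$ | 0.02 | inhibitory synaptic weight (activity units per granule rate) |
| `spontaneous` | $s_0$ | 0.1 | mitral activity without stimulus or inhibition |
| `resilience_threshold` | $\theta_R$ | 0.15 | per-stimulus activity threshold in $R$ |
| `survival_threshold` | $\theta_S$ | 0.15 | soft threshold of the survival sigmoid |
| `steepness` | $k$ | 50 | survival-sigmoid slope (units of $1/R$) |
| `influx` | — | 40 cells/step | newborn granule cells per assessment interval |

All activities are in the arbitrary units of the stimulus amplitudes
(peak glomerular activation 1 by default). The defaults place the
full-size model (96 channels) in a regime where the granule population
self-regulates to a few hundred cells, output amplitudes are strongly
reduced, and similar input pairs (Pearson $\approx 0.97$) decorrelate to
$\approx 0.65$–$0.75$ while a $\theta_R = 0$ control leaves them above
$0.9$ — the within-pair benefit of the resilience threshold.

The survival sigmoid is stated only as "sigmoidal with a threshold and a
slope"; we adopt the centered logistic (midpoint exactly at $\theta_S$,
saturating at 1). This is a design choice: a biophysical survival pathway
may saturate below 1, which would rescale the effective influx but not
change the fixed-point structure.

## Synthetic stimuli

Real glomerular activation maps are focal: an odorant activates a few
hot-spots on the glomerular surface. `generate_odor_set()` emulates this
with sums of narrow Gaussian foci on a 1-D channel axis (96 channels, 2 foci
of width 0.4 channels per odor, amplitudes in [0.6, 1]), including two
"enantiomer-like" pairs — identical focus locations with slightly exchanged
amplitudes (`pair_contrast = 0.12`, within-pair Pearson $\approx 0.97$) —
plus four mutually dissimilar background odors. `downsample_max()` reduces
2-D activation maps to channel vectors by blockwise maxima (averaging would
blur exactly the focal structure that matters; trailing rows/columns that do
not fill a block are cropped). Mixtures are linear combinations of component
patterns (`mix_patterns()`).

What the generator does *not* emulate: graded multi-scale structure of real
uptake maps, channel-correlated noise, concentration series, and any
receptor-level nonlinearity. Passing tests therefore demonstrate the
network-level mechanism — co-activity-based survival producing targeted
lateral inhibition — under focal, linearly mixing inputs, not a quantitative
fit to any measured map.

Near-single-channel foci are a deliberate choice: granule cells connecting
two channels *within* one broad focus would suppress the within-pair
difference mode without the cancellation that protects it in the reciprocal
architecture, weakening decorrelation for reasons unrelated to the survival
rule under study.

## Mean-field population model

For two-connection networks ($K = 2$) in the weak-coupling limit (small $w$,
large populations), granule cells sharing the same unordered mitral pair
$(i,j)$ form a population whose mean size $n_{ij}$ follows

$$ \frac{dn_{ij}}{dt} = \alpha - r\!\big(R_{ij}(\mathbf{n})\big)\, n_{ij},
   \qquad r(R) = -\log T(R), $$

with the resilience evaluated on the steady-state activities of the network
implied by the current means ($g_{ij} = m_i + m_j$,
$W$ assembled from the populations). `population_rhs()` implements the
right-hand side; `integrate_population()` (via deSolve) and
`fixed_point_population()` (damped Newton, tolerance $10^{-12}$) provide
trajectories and fixed points for any ensemble.

**The symmetric four-glomerulus caricature.** Two highly similar stimulus
pairs on four channels, $(a, qa, b, b)$ / $(qa, a, b, b)$ and their mirror
images under the channel swap $(1 2 3 4) \to (3 4 1 2)$, leave only two
distinguished populations: co-active ($n_C$, pairs $\{1,2\}$ and $\{3,4\}$)
and interfering ($n_I$, the four cross pairs). Training at $q = 1$ and
writing $\sigma = m_s + m_w$, $\delta = m_s - m_w$ for the strong/weak
channel activities, the steep-sigmoid nullclines $R = \theta_S$ give closed
forms (`fixed_point_symmetric4(method = "closed_form")`):

* interior regime: $1 + 2 w n_C = 4 (a - b) / \theta_S$ and
  $1 + 2 w (n_C + 2 n_I) = (a + b + 2 s_0)/(\theta_R + \theta_S/4)$;
* boundary regime ($n_I = 0$):
  $1 + 2 w n_C = 2 (a + s_0) / (\theta_R + \theta_S / 2)$;
* a uniform regime ($n_C = n_I$) when the rectifier never clips
  ($4(a-b) \le \theta_S$ or $\theta_R$ below a lower bound).

The regimes meet continuously at the critical threshold

$$ \theta_R^{*} = \theta_S\,\frac{a + b + 2 s_0}{4 (a - b)} -
   \frac{\theta_S}{4}, $$

returned by `optimal_threshold()`: the smallest resilience threshold at
which interference vanishes, and — because the within-pair output
correlation decreases with $n_C$ and increases with $n_I$ — the threshold at
which that correlation is minimal. For test stimuli of similarity $q$, the
eigenmodes of $W$ give the exact within-pair correlation

$$ r = \frac{2 B^2 - D^2}{2 B^2 + D^2}, \qquad
   B = \frac{u - b}{2 (1 + 2 w n_C)}, \quad
   D = \frac{d}{1 + 2 w n_I}, $$

with $u = a (1+q)/2$, $d = a (1-q)/2$
(`correlation_expansion()`, which also offers the leading-order expansion
$r \approx 1 - (D/B)^2$ valid near $q = 1$).

At finite steepness the fixed point shifts by $O(\log(n/\alpha) / k)$
relative to these closed forms, so the `"exact"` method solves the
finite-steepness equations by Newton iteration (initialized from the closed
forms) and is the quantity compared against forward ODE integration; the
closed forms serve as steep-limit cross-checks. The mean-field description
itself carries $O(\alpha / n)$ discretization and fluctuation corrections
relative to the discrete simulator — the equivalence tests therefore run in
the weak-coupling regime ($w = 0.00125$, populations of order $10^3$) where
those corrections sit inside the Monte-Carlo error of 16 seeds.

**Enrichment protocols.** The protocols are compared under an
equal-total-drive matching condition: each glomerular channel receives the
same total stimulation per assessment interval under both protocols, so any
difference between them reflects co-activation, not amplitude. In the
caricature this means four presentations of the 50:50 mixture
(every channel at $(a+b)/2$) against the four alternating stimuli; the
"mixed" cells then have the same total resilience in both protocols, the
mixture-protocol population satisfies $3 n_{\text{mix}} = n_C + 2 n_I$, and
hence $n_I < n_{\text{mix}} < n_C$ (`mixture_comparison()`): the mixture
protocol recruits strictly more cross-component inhibition. In the
discrete-model experiment (`run_enrichment_protocols()`) the same matching
is achieved by presenting the mixture once at the full concentration of
each component (fractions 1:1), replacing the two pure stimuli. This also
makes the $K = 1$ control exactly protocol-symmetric: without lateral
inhibition only per-channel drive matters, and per-channel drive is
identical under both protocols.

## Scripted experiments and their conditions

All experiments embed the resolved configuration and seed in their reports;
multi-run averages use consecutive seeds from the base seed. Problem sizes
are chosen so the full suite runs in minutes: the package's claims are about
mechanisms and orderings, which stabilize at these sizes.

* **Decorrelation** (`run_decorrelation()`): 96 channels, 8 odors, 800
  steps from an empty network. Plateau detection fits a trailing-window
  least-squares slope (`detect_plateau()`, default window half the record,
  relative slope tolerance $5\times10^{-4}$ per step) — the model states
  only that a statistical steady state is reached, so the criterion is a
  design choice.
* **Reciprocity** (`run_reciprocity_study()`): the rewiring sweep runs in
  the weak-coupling regime ($w = 0.005$, populations of several thousand
  cells, 800 steps so that selection spans enough cell generations).
  Two considerations force this choice. First, rewired inhibition is
  decoupled from the survival signal, so the population self-limits only
  through global suppression and grows several-fold; with a large synaptic
  weight the resulting random, asymmetric effective connectivity can cross
  the stability boundary of the linearized dynamics, whereas with many
  weakly weighted synapses it concentrates around its uniform mean and
  stays stable across the entire sweep. Second, uniform inhibition leaves
  Pearson correlations exactly invariant under the linear coupling, which
  is the mechanism behind the fully-rewired network "not decorrelating at
  all" — a statement about the regime in which the linear description is
  valid. Weight heterogeneity (two-point, up to $\delta = w$) reports the
  Frobenius asymmetry ratio of $W$; the norm is unspecified in the
  underlying analysis, and Frobenius is adopted. Self/lateral rebalancing
  multiplies the diagonal of $W$ by $\gamma$ and rescales each row's
  off-diagonal entries to preserve the row sum exactly.
* **Novelty** (`run_novelty()`): train on 7 of the 8 odors, mark cells
  integrated during a 20-step window at the plateau, follow for 80 steps.
  A marked cell "responds" to a stimulus if its activity exceeds
  $\theta_{\text{IEG}}$; the readout
  $\rho = f(\text{final}) / f(\text{end of marking})$ falls below 1 for the
  held-out (novel) odor and stays near or above 1 for familiar odors when
  $\theta_{\text{IEG}} \approx \theta_R$ and the survival sigmoid is not
  too steep. Extinct cohorts raise an explicit error rather than a silent
  0/0.
* **Perceptual learning** (`run_perceptual_learning()`): background-only
  training, then enrichment with the similar test pair (related), with a
  disjoint-support pair (unrelated), or with the related pair but the
  influx cut to zero. Relatedness is reported as the Pearson overlap
  between enrichment and test patterns.
* **Enrichment protocols** (`run_enrichment_protocols()`): components X
  and Y with disjoint focal support; test stimuli are their 35:65 and
  65:35 mixtures; cross-component inhibition is summed over the
  off-diagonal blocks of $W$ restricted to the X/Y support channels.

## Numerical choices and degenerate inputs

* Linear solves use dense LU on the $M \times M$ system; singularity raises
  an error naming the steady-state system.
* The Newton iteration for fixed points uses a numerical Jacobian, step
  halving, and projection onto the nonnegative orthant.
* Removal rates are computed on the log scale
  (`plogis(..., log.p = TRUE)`), so steep sigmoids far below threshold give
  $r \approx k (\theta_S - R)$ instead of overflowing.
* Zero-variance activity vectors have no defined Pearson correlation; the
  metrics return a flagged `NA` with a warning, and ensemble means exclude
  undefined pairs. Spontaneous activity makes this rare in practice.
* An all-zero stimulus with $s_0 = 0$ yields the zero steady state, whose
  correlations then follow the zero-variance policy.
* Stability analysis adopts leaky rate dynamics with unit relaxation; only
  the signs of the real parts are asserted, which are invariant to the time
  constant. The spectrum is computed by the algebraic reduction
  $\lambda = -1 \pm \sqrt{-\mu}$ over eigenvalues $\mu$ of $W$ (validated
  against the full Jacobian in the tests).
* Rewiring counts per cell are `round(fraction * K)`; replacement targets
  are drawn jointly and uniformly from the non-kept mitral cells, so full
  rewiring yields a uniform $K$-subset independent of the excitatory
  sources.

## Known limitations

* No synaptic weight plasticity, spiking, or dendritic compartments: the
  model isolates the structural (turnover) channel of plasticity.
* The mean-field description is derived for $K = 2$ only and requires
  large mean populations; small populations deviate visibly (and the
  boundary fixed point $n_I = 0$ is only approached, never attained, at
  finite steepness and influx).
* The toy three-channel stimulus pair has exactly symmetric strong
  channels, which makes its Pearson correlation degenerate ($\pm 1$); the
  decorrelation mechanism it illustrates is asserted on amplitude
  suppression and on slightly asymmetric variants.
* The optional image loader reads grayscale PNG/TIFF maps as-is; any
  amplitude convention of the source archive is the user's responsibility.
* Conclusions about real odor maps require real activation patterns; all
  quantitative statements in the test suite are about the synthetic study
  conditions stated above.

## A worked mean-field example

```{r example, eval = FALSE}
pp <- symmetric4_population_params(
  influx = 2, inh_weight = 0.01, resilience_threshold = 0.05,
  survival_threshold = 0.4, steepness = 2000)

optimal_threshold(pp)                    # 0.075
fixed_point_symmetric4(pp, "exact")      # coactive ~ 347, interfering ~ 34
mixture_comparison(pp)$ordering_holds    # TRUE

scan <- run_population_analysis()
scan$argmin                              # 0.08 on the 0.01-step grid
```
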