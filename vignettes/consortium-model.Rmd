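---
title: "A coarse-grained model of a producer-cleaner E. coli consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of a producer-cleaner E. coli consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system and the model

`coculture` models a synthetic co-culture of two *Escherichia coli* strains
in a well-stirred bioreactor. A **producer** strain grows on glucose,
diverts a fraction $Y_h$ of its biomass synthesis into a heterologous
protein, and secretes acetate when glucose uptake runs above the overflow
threshold. A **cleaner** strain (ptsG deletion plus Acs overexpression)
grows preferentially on that acetate, removing a metabolite that inhibits
the producer's growth. The state is
$x = (G, A, B_P, H, B_C)$: glucose and acetate concentrations
[g L$^{-1}$], producer autocatalytic biomass, heterologous protein, and
cleaner biomass [gDW L$^{-1}$]; the total producer biomass is
$B_{totP} = B_P + H$.

Specific rates per strain [g gDW$^{-1}$ h$^{-1}$]:

$$r_{up,g} = k_g \frac{G}{G+K_g}\,\frac{\Theta_a^n}{A^n+\Theta_a^n},\qquad
  r_{up,a} = k_a \frac{A}{A+K_a}\,\frac{\Theta_g^m}{r_{up,g}^m+\Theta_g^m},\qquad
  r_{over,a} = k_{over}\,\max(0,\,r_{up,g}-l).$$

The first factor of each uptake law is a Monod term; the second factors
encode acetate growth inhibition (constant $\Theta_a$) and carbon
catabolite repression (CCR, constant $\Theta_g$, driven by the glucose
uptake rate itself). The cleaner replaces $k_g$ by the residual
post-deletion rate $k_{\Delta PTS}$ and gains an Acs uptake term
$k_{Acs} A/(A+K_{Acs})$ that escapes CCR. Mass balances in a chemostat
with dilution rate $D$ and inflow glucose $G_{in}$:

$$\begin{aligned}
\dot G &= -r_{up,Pg}B_P - r_{up,Cg}B_C + D(G_{in}-G),\\
\dot A &= (r_{over,Pa}-r_{up,Pa})B_P + (r_{over,Ca}-r_{up,Ca})B_C - DA,\\
\dot B_P &= (1-Y_h)\,r_P B_P - (k_{deg}+D)B_P,\\
\dot H &= Y_h\,r_P B_P - (k_{deg}+D)H,\\
\dot B_C &= r_C B_C - (k_{deg}+D)B_C,
\end{aligned}$$

with the net specific biomass production rates
$r_P = Y_g r_{up,Pg} + Y_a (r_{up,Pa}-r_{over,Pa})$ and analogously $r_C$.
Setting $B_C = 0$ recovers the producer-only model exactly. The growth
rate of a strain is $\mu = r\,B/B_{tot} - k_{deg}$, and at any steady
state with both $B_P, H > 0$ the composition locks to
$H^*/B_{totP}^* = Y_h$, so $\mu^* = (1-Y_h)r^* - k_{deg}$.

Units are fixed package-wide (h, g L$^{-1}$, gDW L$^{-1}$,
g gDW$^{-1}$ h$^{-1}$); there is no unit-conversion layer.

## Parameters

The packaged default file `inst/extdata/default_params.toml` carries the
calibrated wild-type constants and the cleaner design constants:

| symbol | value | meaning |
|---|---|---|
| $k_g$ | 1.53 g gDW$^{-1}$ h$^{-1}$ | maximal glucose uptake |
| $K_g$ | 0.09 g L$^{-1}$ | glucose half-saturation |
| $\Theta_a$ | 0.52 g L$^{-1}$ | acetate inhibition constant (low-pH conditions) |
| $n$ | 1 | acetate-inhibition exponent |
| $k_{over}$ | 0.17 | overflow proportionality |
| $l$ | 0.7 g gDW$^{-1}$ h$^{-1}$ | overflow threshold |
| $k_a$ | 0.97 g gDW$^{-1}$ h$^{-1}$ | maximal acetate uptake |
| $K_a$ | 0.5 g L$^{-1}$ | acetate half-saturation |
| $\Theta_g$ | 0.25 g gDW$^{-1}$ h$^{-1}$ | CCR constant |
| $m$ | 1 | CCR exponent |
| $Y_g$ | 0.44 gDW g$^{-1}$ | glucose biomass yield |
| $Y_a$ | 0.298 gDW g$^{-1}$ | acetate biomass yield |
| $Y_h$ | 0.2 | product yield fraction (default burden) |
| $k_{deg}$ | 0.0044 h$^{-1}$ | biomass degradation ($= C_m Y_g$) |
| $k_{\Delta PTS}$ | 0.38 g gDW$^{-1}$ h$^{-1}$ | cleaner residual glucose uptake ($\approx k_g/4$) |
| $k_{Acs}$ | 1.46 g gDW$^{-1}$ h$^{-1}$ | cleaner Acs acetate uptake ($1.5\,k_a$) |
| $K_{Acs}$ | 0.012 g L$^{-1}$ | Acs half-saturation |

The exponents $n$ and $m$ are treated as real-valued parameters (their
calibrated values happen to be 1); the rate laws guard the $A = 0$ and
$r_{up,g} = 0$ limits by continuous extension, so no $0/0$ arises. The
overflow kink $\max(0,\cdot)$ is kept exact rather than smoothed: the
piecewise structure is what partitions the state space into the four
overflow branches used by the root finder, and smoothing would displace
the overflow onset that much of the analysis is about.

## Numerical choices

**Integration.** `simulate_consortium()` uses `deSolve::lsoda` with
`rtol = 1e-8`, `atol = 1e-10`; these tight tolerances resolve the
non-smooth right-hand side at the overflow threshold and at glucose
exhaustion. Trial steps may undershoot 0 slightly; the right-hand side is
evaluated on the clipped state, and returned trajectories abort if any
component falls below $-10^{-7}$ — an order of magnitude below the
$10^{-6}$ gDW L$^{-1}$ presence threshold used for regime classification,
and comfortably above what the solver tolerances can produce for a
legitimate solution.

**Steady states by integration.** `steady_state_by_integration()`
integrates in chunks of growing length until
$\lVert f(x)\rVert_\infty < 10^{-9}$, capped at $10^6$ h. The default
initial condition is $(0, 0, 0.01, 0, 0.01)$: a small positive inoculum of
both strains in an empty reactor. A zero-biomass start would be invariant
(washout is always an equilibrium), so "start from the empty reactor"
is operationalized as the smallest inoculum that makes every reachable
population attractor attainable. Dilution-rate sweeps warm-start each
solve from the previous equilibrium with the inoculum floor restored to
both strains; since the steady state is unique for positive initial
biomasses (confirmed against root finding and random restarts in the test
suite), continuation changes only speed, not the answer.

**Steady states by root finding.** The piecewise-linear overflow terms
partition the state space into four branches on which the right-hand side
is smooth. `steady_state_by_rootfinding()` enumerates candidates in three
families — the closed-form washout state, single-strain equilibria, and
interior coexistence equilibria — per branch, using a damped Newton
iteration with numerical Jacobians and Latin-hypercube multi-starts in
log-scaled state space (32 per family and branch by default). Equilibria
of a strain growing below overflow lie on the boundary $A^* = 0$ where
Newton cannot converge from the interior; those are added in closed form
(the growth balance fixes $r_{up,g}^*$ and hence $G^*$, the glucose
balance fixes the biomass). Candidates violating nonnegativity or their
branch's rate inequality are discarded, survivors are deduplicated at
$10^{-6}$ relative distance, and stability is decided by the eigenvalues
of the analytic Jacobian (one-sided derivatives on the kink itself). This
replaces exhaustive multinomial root enumeration — the exact elimination
produces polynomials of very high order — with a numerical equivalent
whose completeness is cross-checked against the integration route on a
$(D, G_{in})$ grid in the acceptance tests.

**Regime boundaries.** `coexistence_boundaries()` scans $D$ in steps of
0.005 h$^{-1}$ and refines each regime transition by bisection to
$10^{-3}$ h$^{-1}$, using the presence threshold $10^{-6}$ gDW L$^{-1}$.
Two distinct onsets are reported deliberately: the closed-form
overflow-onset dilution rate $D = (1-Y_h)Y_g l - k_{deg}$, at which
steady-state glucose uptake reaches the threshold $l$, and the slightly
larger coexistence onset, at which the overflow becomes sufficient to
sustain a cleaner population growing at rate $D$. Conflating the two
would misplace the band's lower edge by a few times $10^{-2}$ h$^{-1}$.

**Fed-batch.** Holding the reactor glucose constant is implemented
structurally ($\dot G \equiv 0$, $D = 0$), not through a feedback
controller — input design is out of scope, and the structural form makes
the implied feed flux $r_{up,Pg}B_P + r_{up,Cg}B_C$ available exactly.
The exponential window is the largest terminal stretch where the per-step
second difference of $\log H$ stays below $10^{-6}$, required to span at
least 5 h; slopes of $\log H$ and $\log B_{totP}$ come from least squares
on the window, and the instantaneous yield
$\dot H / (r_{up,Pg}B_P + r_{up,Cg}B_C)$ is averaged over it. The default
60 h horizon leaves a window of roughly 40 h.

## Performance measures

In chemostat, productivity is the steady-state product outflow $DH^*$
[g L$^{-1}$ h$^{-1}$] and the process yield is product outflow per
substrate inflow, $DH^*/(DG_{in}) = H^*/G_{in}$, which by the composition
identity equals $Y_h B_{totP}^*/G_{in}$. Productivity maxima over $D$ are
located on the 0.005-step grid and refined by golden-section search to
$10^{-3}$ h$^{-1}$; the consortium's gain is reported as
$(\max_{cons} - \max_{prod})/\max_{prod}$ in percent. In fed-batch the
productivity index is the exponential rate of increase of $H$ and the
efficiency index is the constant exponential-regime yield.

## Calibration

The producer model is calibrated from exponential-growth rate
measurements ($\mu^+$, $r^+_{up,g}$, net acetate exchange
$r^+_{up,a}-r^+_{over,a}$) in three condition classes, with
$K_g, K_a, l, k_{deg}$ fixed from the literature.

*Step 1 (closed forms).* Acetate-only records ($G = 0$: no overflow, CCR
factor 1) invert to $k_a$ and $Y_a$; glucose-only records with overflow
($A = 0$: inhibition factor 1, CCR suppresses acetate uptake, so the
measured net exchange is pure secretion) invert to $k_g$, $k_{over}$ and
$Y_g$. Multiple records are averaged after per-record inversion — the
simplest aggregation consistent with multiplicative error of a few
percent.

*Step 2.* $\Theta_a, n, \Theta_g, m$ are estimated from the mixed
glucose+acetate gradient by minimizing the pooled, unweighted sum of
squared errors of the three observables. The observables share a numeric
scale of roughly 0.1–1.5, so no per-observable weighting is applied. The
optimizer is `stats::optim(method = "L-BFGS-B")` with box bounds
($\Theta_a \in (0,10]$, $n \in [0.5,4]$, $\Theta_g \in (0,5]$,
$m \in [0.5,4]$) and 8 starts spread over the box: the objective is smooth
in these four parameters, so a quasi-Newton bounded search is preferred
over derivative-free simplex variants; multi-starts guard against local
minima. Estimates pinned at a bound, non-convergence, and designs with no
acetate gradient (which leave $\Theta_a, n$ unidentifiable) are flagged.

*Bootstrap.* Identifiability is assessed by case resampling with
replacement, stratified by condition class, refitting step 2 per replicate
from the point estimate with a single start (the replicate objective is a
perturbation of the original, so the point estimate is an excellent
start and multi-starting 200 replicates would add cost, not information).
Percentile 95% intervals are reported; runs are deterministic under a
fixed seed, and the session RNG state is restored.

## The synthetic-data generator

`generate_rate_dataset()` emulates the *structure* of the calibration
data: one glucose-only condition (3.6 g L$^{-1}$, well above $K_g$ and
above the overflow threshold), acetate-only conditions at
$A \in \{0.5, 1, 2, 4\}$ g L$^{-1}$, and a mixed gradient
$A \in \{0, 0.25, 0.5, 1, 2, 4\}$ g L$^{-1}$ at high glucose — spanning
the inhibition constant $\Theta_a = 0.52$ from both sides. Noise is
multiplicative lognormal with mean-one factors, applied to the magnitude
of each observable so that net secretion keeps its sign; the default CV
of 5% and 3 replicates per condition are modelling choices reflecting
typical relative error of physiological rate measurements — the true
error structure of the source data is unknown. With `noise_cv = 0` the
generator is a pure function of parameters and design.

What passing the calibration tests shows is therefore *internal*
consistency: the estimation pipeline recovers the parameters that
generated data of this design and noise model. It does not validate the
rate laws against real measurements, nor does it emulate within-experiment
autocorrelation or instrument-specific error; the printed goodness-of-fit
of the original calibration against real data is not reproducible from
this package and no attempt is made.

## Problem sizes

The shipped analyses use: 0.005-step dilution sweeps on $[0, 0.7]$
h$^{-1}$ at $G_{in} = 20$ g L$^{-1}$ with bisection-refined edges; a
coarser $(D, G_{in})$ phase-diagram grid ($\Delta D = 0.02$,
$G_{in} \in \{0,1,2,5,10,20\}$) for the regime map; 50 replicate datasets
for noise sensitivity; and 20 outer replicates with 200 bootstrap
resamples each for CI coverage. These sizes keep every driver script in
the minutes range on a single core while leaving the refined quantities
grid-independent to well within the bisection tolerance.

## Known limitations

- The acetate growth law is monotone by design; non-monotone variants
  (growth maxima at intermediate acetate) reported elsewhere can produce
  multistability that this model intentionally excludes.
- Fed-batch assumes perfectly held glucose and constant volume; no feed
  controller is synthesized.
- Root finding is multi-start local search, not a certified global
  enumeration; its completeness is established empirically against the
  integration route.
- The boundary refinement inherits the presence threshold: band edges are
  where a biomass crosses $10^{-6}$ gDW L$^{-1}$, which for transcritical
  transitions sits marginally inside the true bifurcation point.
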