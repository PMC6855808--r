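---
title: "Methods: lipid binding and gating modulation analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid binding and gating modulation analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgating)
```

This vignette documents the models behind each analysis, the choices that
were genuinely open and how they were resolved, what the synthetic-data
generators do and do not emulate, and the numerical details that matter for
reproducibility.

## Binomial equal-affinity binding (native MS)

Native MS of an intact pentamer resolves peaks for the channel with
0, 1, 2, ... bound lipids; deconvoluted peak heights $I_n$ are treated as
proportional to the mole fractions of the bound species. The average bound
count is $\sum_n n I_n / \sum_n I_n$, and a titration is modelled with $N$
equivalent, independent sites of dissociation constant $K$ (μM): per-site
occupancy $p = [A]/([A]+K)$ and

$$B(q) = \binom{N}{q} p^q (1-p)^{N-q}, \qquad \mathbb{E}[q] = Np .$$

Notes on this model:

* **Exponent placement.** We use the standard binomial form above, under
  which the mean is $Np$ and rises with concentration. The alternative
  placement $p^{N-q}(1-p)^q$ would make the mean $N(1-p)$, contradicting the
  definition of $p$ as per-site occupancy, and is therefore not implemented.
* **Objective.** The default fit minimizes summed squared residuals between
  per-concentration mole-fraction histograms (each peak set normalized to
  unit total intensity) and $B(q)$, jointly across concentrations with equal
  weights; an average-bound-curve objective is available via
  `fitted_on = "avg_bound"`. Equal weighting is the natural choice absent
  per-point variance estimates.
* **One parameter at a time.** `fit_K` treats $N$ as known (e.g. the annular
  site count from simulations) and minimizes over $K$ on a log grid of 241
  points spanning $10^{-4}$–$10^{7}$ μM followed by golden-section
  refinement — the coarse scan is needed because the objective plateaus far
  from the optimum. `fit_N` treats $K$ as known and searches the integer
  grid $1..64$; $N$ is a site count, so a continuous fit would be
  meaningless.
* **Charge states.** Bound-lipid counts are biased at high charge states,
  so `filter_charge_states()` drops charges above 26+ (configurable) and
  sums the remainder per bound count before analysis.
* Intensities are arbitrary-unit peak heights; isotope or adduct correction
  belongs to upstream deconvolution and is out of scope.

## Hill stability fit and the binding–stability coupling

The thermal stabilizing effect of a lipid is the pentamer peak height after
heating with lipid divided by the heated no-lipid control, so the zero-lipid
effect is 1 by construction and the baseline is fixed there:

$$\mathrm{effect}(c) = 1 + (E_{\max} - 1)\frac{c^n}{c^n + \mathrm{EC}_{50}^n}.$$

$E_{\max}$ is floated because the assay saturates at an unknown ceiling; the
*fractional* effect $c^n/(c^n+\mathrm{EC}_{50}^n)$ — the fraction of maximal
stabilization above baseline — is what downstream coupling uses, which makes
the result invariant to $E_{\max}$.

`couple_binding_to_stability()` answers "how much of the stabilization do
$m$ bound lipids provide?" by eliminating concentration: invert the binding
curve at $m$, then evaluate the fractional effect at that concentration.
Within the measured range the binding curve is interpolated piecewise
linearly through the origin. Beyond the last measured point two
extrapolations are offered:

* **linear** (default): continue the line through the origin and the last
  measured point. Binding is far from saturation over the measurable range,
  so the low-concentration regime is approximately linear; this is also the
  only extrapolation under which a saturating site count (e.g. 32 bound of
  32 sites) is reachable at finite concentration.
* **model**: invert a binomial `binding_model`; requests at or above $N$
  bound are domain errors because the model saturates.

With the measured anchor of 2.9 bound at 12 μM, the linear inversion puts 32
bound lipids at $32 \times 12 / 2.9 \approx 132$ μM, where the fractional
effect of the fitted stability curve (EC50 52 μM, $n$ 1.7) is ≈0.83 — the
number the acceptance script recomputes.

## Boundary lipids and polar density maps

A lipid is a *boundary* (annular) lipid when the minimum distance between
any of its beads and any transmembrane-domain (TMD) protein bead is ≤ 6 Å,
evaluated under the minimum-image convention in the periodic box dimensions.
All lipid beads are tested (the criterion is "the lipid is within 6 Å of the
TMD", not "the headgroup is"), and the comparison is inclusive.

The enrichment metric for species $i$ is, per frame,
$B_i = (b_i/b_\mathrm{tot})(1/x_i) - 1$, averaged over frames and replicas,
where $x_i$ is the bulk mole fraction from the full lipid census of the
same frame. The sign convention is $B>0$ = enrichment, $B=0$ = random
mixing, $B<0$ = depletion. (Two sign conventions circulate for this metric;
we adopt the one under which preferential binding gives positive values, and
all tests are written against it.) Frames with no boundary lipids carry no
information about the boundary composition and are skipped with a warning
rather than counted as zero. A useful invariant checked in the tests: within
one frame, $\sum_i x_i B_i = 0$ exactly.

Density maps bin the phosphate beads of one species, one leaflet, into polar
bins around the TMD center of mass projected onto the membrane plane:
radial width 4 Å out to 40 Å, angular width $\pi/15$ (10 × 30 bins), mean
per-bin area density over the frame window. Leaflets are assigned by
phosphate $z$ relative to the instantaneous median phosphate $z$. Density
maps default to the last half of the trajectory (the equilibrated window);
enrichment averages use all supplied frames. Both windows are configurable,
and the per-bin counts integrate exactly to the mean in-range phosphate
count (conservation is a test).

## Stopped-flow flux pipeline

Sequential mixing exposes proteoliposomes to agonist for a controlled delay
$t$, then to Tl⁺; quenching of the encapsulated fluorophore reports the open
channel fraction at that delay. The pipeline is:

1. **Stretched-exponential fit per repeat:**
   $F(t) = F_\infty + (F_0-F_\infty)e^{-(t/\tau)^\beta}$ with
   $\beta \in (0,1]$ — heterogeneity across the liposome population makes
   the quench non-exponential; $\beta > 1$ (compressed exponentials) is
   unphysical here and excluded. Traces whose fitted amplitude is below six
   times the noise floor (estimated from first differences), or whose decay
   completed before the first sample, are flagged `no_flux` and assigned
   rate 0 rather than treated as errors: a desensitized or empty liposome
   population is a valid observation.
2. **Initial rate at 2 ms:** $k = (\beta/\tau)(t_\mathrm{eval}/\tau)^{\beta-1}$
   with $t_\mathrm{eval} = 2$ ms (exposed as a flag, fixed by convention).
3. **Repeat screening:** by-eye outlier removal is replaced with a
   deterministic rule — reject a repeat when its rate deviates from the
   per-delay median by more than 3 scaled MADs (floored at 0.1% of the
   median so a gross outlier among otherwise identical repeats is caught)
   or its rmse exceeds 3× the median. With fewer than three repeats nothing
   is rejected. Thresholds are configurable; rejections are reported in the
   aggregated table.
4. **Rate-course decomposition:**
   $K(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ with signed amplitudes
   (the rise-then-decay shape requires one negative amplitude). Components
   are ordered $\tau_1 < \tau_2$; $\tau_1$ is activation, $\tau_2$
   desensitization — assignment is by time-constant order, not amplitude
   sign. The fit multi-starts from a small grid of initializations keyed to
   the delay of the rate maximum; if no second component is resolvable
   (ratio of taus < 1.05 or a vanishing amplitude) the fit falls back to a
   single component and is flagged. An optional constant offset can absorb
   delay-independent leak flux; the default is the offset-free form, which
   matches a leak-free preparation.

The synthetic generator couples an irreversible resting → open →
desensitized scheme (rates $a$, $d$) to traces through the same two
formulas run backwards: open probability
$O(t) = \frac{a}{a-d}(e^{-dt} - e^{-at})$ (confluent limit $a t e^{-at}$ at
$a=d$), target rate $k = k_\mathrm{leak} + k_\mathrm{max} O(t)$, and
$\tau = (\beta\, t_\mathrm{eval}^{\beta-1}/k)^{1/\beta}$. Because generation
inverts the analysis formulas rather than reusing the fitting code, pipeline
recovery is a genuine inverse problem. Generator defaults: 16
logarithmically spaced delays over 10 ms–25 s (the experimental delay
range), 8 repeats per delay (the stated minimum), 150 log-spaced samples
over 0.5 ms–1 s per trace (the recorded quench window), $F_0 = 1$,
$F_\infty = 0.2$, $k_\mathrm{max} = 50\,\mathrm{s^{-1}}$, $\beta = 0.65$,
$k_\mathrm{leak} = 0$ (leak-free, consistent with flux-free control traces
and the offset-free rate-course form), noise SD 5% of the quench amplitude.

## Patch-clamp kinetics

Activation: single-exponential fit $A(1-e^{-t/\tau})$ over the 10–90% rise
window from agonist onset to peak; a rise faster than the sampling interval
is flagged rather than reported as a fitted constant. Desensitization: from
the peak sample onward, both $C + A e^{-t/\tau}$ and
$C + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ are fitted with a free plateau
$C$ (currents decay to a non-zero level), and the model is selected by
small-sample-corrected AIC — "best fit" needs an explicit criterion, and
AICc is the standard one at these sample sizes; both scores are retained in
the result. Summaries follow the field's conventions: the
amplitude-weighted time constant $(A_1\tau_1+A_2\tau_2)/(A_1+A_2)$ (the tau
itself for single fits; both kinds pool in `combine_weighted_taus()`, with
an SD of 0 and a flag for $n=1$), and the extent of desensitization as the
current 20 s after agonist *onset* normalized to peak. Dose-response fits
fix the Hill coefficient at 2. Group comparisons: one-way ANOVA with Tukey
HSD for all-pairs designs; Welch t-tests against a reference with Bonferroni
adjustment for reference-versus-mutant designs.

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its seed and embeds its ground truth
as an attribute, so recovery can be scored automatically.

* **Peak sets**: exact binomial mole fractions × scale × log-normal
  multiplicative noise (positive, heteroscedastic — the right first-order
  model for peak heights), truncated where the exact fraction falls below
  $10^{-4}$. Not emulated: charge-state structure, detergent adducts,
  baseline noise of real spectra.
* **Stability curves**: Hill evaluation plus additive Gaussian noise floored
  at 0; triplicate measurements per concentration mirror the assay design.
* **Membrane frames**: 2-D per leaflet — the enrichment metric and the
  density maps depend only on in-plane positions and leaflet labels, so the
  generator places single-bead lipids at fixed leaflet heights and models
  the TMD as a bead ring (radius 22 Å) replicated at both leaflet planes.
  At the simulated density (~60 Å² per lipid, 3000 lipids in a 30 × 30 nm
  box) the 6 Å shell holds ≈32 boundary lipids, matching the annular census
  of a pentameric TMD. Species in the shell are drawn with probability
  ∝ bias × composition, giving the closed-form expected enrichment
  $B_i = w_i/\sum_j w_j x_j - 1$. Not emulated: lipid internal structure,
  correlated diffusion, frame-to-frame correlation (frames are
  independent), membrane curvature, protein shape beyond a circular
  footprint.
* **Flux experiments** and **current traces**: as described above. Not
  emulated: instrument dead time, photobleaching, series-resistance and
  leak artifacts.

Passing tests on these inputs therefore demonstrates that the estimators
invert the assumed statistical models at realistic noise and sample sizes —
not that real data satisfy those models.

## Numerical choices and limitations

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with explicit
  bounds and data-driven starts; the rate-course and dose-response fits
  multi-start and keep the best SSR. Fit failures raise errors that name the
  initial guesses; degenerate inputs (all-apo peaks, flat stability data,
  non-decaying currents) are rejected with specific messages.
* The binomial pmf, ANOVA/Tukey, and Bonferroni adjustments are delegated to
  base R (`dbinom`, `aov`/`TukeyHSD`, `p.adjust`).
* Monte-Carlo scales used by the test suite — 100-replicate parameter
  recoveries, 50-experiment pipeline sweeps, 50-frame enrichment runs,
  500–1000-replicate null simulations — were chosen to give stable
  pass/fail behaviour at interactive runtimes.
* The null-mixing enrichment estimate over 50 independent frames has a
  Monte-Carlo SE of ≈0.075 (≈32 boundary lipids per frame, 10% minority
  species): its mean is unbiased at 0 but individual 50-frame runs scatter
  accordingly.
* Known limitations: `fit_N` assumes the true site count is ≤ 64; the
  boundary search is $O(\text{beads} \times \text{TMD beads})$ per frame
  (fine at coarse-grained sizes; no cell lists); the GRO reader handles
  single-frame files only; and the desensitization fitter assumes a single
  peak after onset.
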