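# lipidgating

Quantitative analysis of how anionic phospholipids bind to and modulate a
pentameric ligand-gated ion channel (pLGIC). The package was built around the
measurements one makes when asking whether a lipid such as POPG acts on a
channel like ELIC by direct binding: native mass-spectrometry titrations of
intact channel–lipid complexes, thermal-stability assays, coarse-grained
membrane simulations, stopped-flow flux assays, and patch-clamp recordings.
Each assay gets a small, fully tested analysis pipeline, and a synthetic-data
module generates every input class with known ground truth so the pipelines
can be validated end to end.

## Models implemented

**Binomial equal-affinity binding (native MS).** Deconvoluted peak heights
I_n of the channel with n bound lipids give the average bound count
Σ n·I_n / Σ I_n. A titration is fitted with N equivalent sites of
dissociation constant K: per-site occupancy p = [A]/([A]+K), mole fraction of
the q-bound species B(q) = C(N,q) p^q (1−p)^(N−q), mean N·p. Either K is
fitted with N fixed (`fit_K`) or N is selected on an integer grid with K
fixed (`fit_N`).

**Hill stability coupling.** The thermal stabilizing effect (pentamer peak
height with lipid relative to the heated control) versus concentration is
fitted with effect(c) = 1 + (E_max − 1)·c^n/(c^n + EC50^n). Eliminating
concentration between the (linearly extrapolated) binding curve and the Hill
curve expresses the fractional effect as a function of bound-lipid count.

**Boundary-lipid enrichment.** In membrane frames a lipid is a boundary
(annular) lipid when any of its beads lies within 6 Å of a transmembrane-domain
bead (minimum-image convention). The enrichment metric
B_i = ⟨(b_i/b_tot)·(1/x_i)⟩ − 1 compares the boundary fraction of species i
to its bulk mole fraction: B > 0 is enrichment, 0 is random mixing.
Leaflet-resolved polar density maps (radial bins of 4 Å to 40 Å, angular bins
of π/15) localize the headgroup density.

**Stopped-flow flux kinetics.** Each Tl⁺-quench repeat is fitted with a
stretched exponential F(t) = F_∞ + (F_0 − F_∞)·exp(−(t/τ)^β), the influx
rate is evaluated at 2 ms as k = (β/τ)·(t/τ)^(β−1), repeats are screened with
a 3-MAD outlier rule, and the mean rate versus agonist delay is decomposed as
K(t) = A1·e^(−t/τ1) + A2·e^(−t/τ2); the fast component is activation, the
slow one desensitization.

**Patch-clamp kinetics.** Activation is a single-exponential rise fit;
desensitization is fitted with single and double exponentials (free plateau)
and selected by AICc; summaries are the amplitude-weighted τ,
(A1·τ1 + A2·τ2)/(A1 + A2), and the current remaining 20 s after agonist
onset. Dose-response curves use a Hill fit with n fixed at 2. Group
comparisons use one-way ANOVA with Tukey HSD, or reference-versus-mutant
t-tests with Bonferroni correction.

## Worked example

```r
library(lipidgating)

# native-MS titration: recover K from a synthetic 32-site channel
model <- binding_model(n_sites = 32, k_d = 120)
peaks <- gen_peaksets(model, c(3, 6, 12, 24, 36, 72), sigma = 0.05, seed = 1)
fit <- fit_binding(peaks, mode = "fit_K", n_sites = 32)
fit
#> <binding_fit> POPG, mode fit_K (mole_fractions): N = 32, K = 120.5 uM, SSR = 0.000868

# how many bound lipids does the stabilizing effect correspond to?
anchor <- binding_curve(12, 2.9)        # measured: 2.9 bound at 12 uM
hill   <- hill_curve(52, 1.7, e_max = 4)
couple_binding_to_stability(anchor, hill, n_bound = 32)
#>   n_bound concentration fractional_effect
#> 1      32      132.4138         0.8304711

# stopped-flow pipeline: activation and desensitization from quench traces
scheme <- kinetic_scheme(a = 1 / 0.013, d = 1 / 9.2)
traces <- gen_flux_experiment(scheme, seed = 12, condition = "POPC:POPE:POPG")
flux_pipeline(traces)$fit
#> <rate_course_fit> activation tau1 = 0.01071 s (A1 = -60.5), desensitization tau2 = 9.13 s (A2 = 49.5)
```

The binding fit recovers the generating K (120 μM) within 1%; the coupling
says that driving the binding curve to 32 bound lipids (at ~132 μM) yields
83% of the maximal thermal stabilization; and the flux pipeline recovers the
generating desensitization time constant (9.2 s) within a few percent from
noisy traces, alongside the fast ~13 ms activation component.

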