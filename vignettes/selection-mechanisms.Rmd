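---
title: "Low-rank network models of contextual selection: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank network models of contextual selection: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowrankCDM)
```

## The scientific problem

In context-dependent decision-making (CDM), a subject accumulates evidence
from the currently relevant of two stimulus features (here: the location and
the frequency of auditory pulses) and ignores the other. In linearized
dynamical-systems language, a network that solves this task relaxes onto a
*line attractor*: the transition matrix of the dynamics around the slow point
has one near-zero eigenvalue (the choice axis, right eigenvector `rho`) with
all other modes decaying. Only the component of an input along the left
eigenvector of that near-zero mode — the *selection vector* `s` — is
integrated. Contextual selection can then be implemented two ways:

* **input modulation** — the context changes how an input is represented
  (`Itilde = G I` changes; `s` is fixed), or
* **selection-vector modulation** — the context changes `s` itself while the
  input representation stays put.

Given integrated evidence `Itilde . s` in each context, the
relevant-minus-irrelevant difference splits exactly into
`Delta(Itilde . s) = Delta(Itilde) . s_bar + Itilde_bar . Delta(s)`,
the two terms being the two mechanisms. This package implements (i) that
classical decomposition by reverse-engineering (slow points, linearization,
eigenvectors), and (ii) an explicit *pathway* account for low-rank networks
that tells you, from connectivity alone, where the modulation lives.

## Model

Rate networks `tau dx/dt = -x + J phi(x) + sum_s I_s u_s + sum_c I_c^ctx
u_c^ctx + eps`, `z = mean(w * phi(x))`, integrated by forward Euler with
`dt = 20` ms, `tau = 100` ms, `phi = tanh` (softplus optional). The
connectivity is either a full matrix or low-rank,
`J = sum_r m_r n_r^T / N`: each component reads the population state through
its input-selection vector `n_r` and writes along its output vector `m_r`.
All couplings between task variables use the population overlap
`<a, b> = mean(a * b)`.

Process noise `eps` defaults to zero everywhere: the analyses are
deterministic functions of the parameters, and adding unspecified noise
would only blur the quantities being measured. A `noise_std` argument exists
on `simulate_network()` and `train_config()` for robustness experiments.

Trials start at `x(0) = Ictx` of the trial's context. This is the
initialization under which the low-rank state exactly decomposes as
`x(t) = Ictx + sum_r k_r m_r + sum_s k_s I_s`, making the latent
(task-variable) description `simulate_latent()` an exact reparameterization
of the full simulation on the same Euler grid — a property the test suite
checks to 1e-10.

## Task generator

`sample_trials()` generates the pulse-based CDM task: per 20 ms stimulus
step the pulse count is Poisson with mean 0.8 (40 Hz); each pulse is
independently "right" with per-trial probability `p` and "high" with
probability `p_high`, both drawn from {39, 35, 25, 15, 5, 1}/40; the two
evidence channels carry 0.1 x (signed count differences); context channels
are binary and complementary. Targets are the sign of the relevant
modality's strength `2p - 1`; the admissible set excludes 1/2, so targets
are never ambiguous (the constructor rejects probability 1/2). Pulses occur
only during the 800 ms stimulus period — fixation input is zero — and the
context cue is on from trial start, reflecting its role as a standing cue.
A trial is 51 steps: 10 fixation, 40 stimulus, 1 decision.

The generator emulates the *statistics* of the pulse task, not its
embodiment: no reaction times, no reward or feedback, no sensory
transduction noise, no session structure. Passing tests therefore validate
the selection-mechanism analyses on networks driven by matched input
statistics; they say nothing about fits to measured neural data.

## Training

`train_network()` trains all embeddings, the recurrent parameters (the
vectors `m_r, n_r` under a rank constraint, or the full matrix), and the
readout by backpropagation through time with Adam (moment decays 0.9/0.99,
learning rate 1e-3), 5000 steps of 256 fresh trials by default, squared
output error at the single decision step plus an L2 penalty on the recurrent
parameters (`w_reg`). The error term is implemented as *squared* error — the
standard choice consistent with minimization. Initialization is Gaussian
with variance 1/N^2 (a 1/N variant is available). The training inner loop
evaluates `tanh` through a rational/exponential approximation with maximum
absolute error below 3e-12 — orders of magnitude below the
stochastic-gradient noise — while all simulation and analysis paths use the
exact `tanh`.

`accept_network()` implements the line-attractor filter: the leading
eigenvalue of the activity transition matrix `M = -E + G J` must lie in the
closed interval [-0.05, 0.05] in both contexts (a 1e-10 grace absorbs
floating-point rounding at the boundary). As in the reference training
pipeline, a substantial fraction of trained networks fails this filter
(converging instead to discrete attractors, leading eigenvalue > 0.05, or to
leaky integration, < -0.05); analyses of trained networks condition on
acceptance.

## Linearization and the classical decomposition

`find_slow_point()` minimizes the squared speed of the input-free dynamics
(L-BFGS-B, analytic gradient, default start at `Ictx`, optional multi-start
list). The optimizer, starts, and tolerance are this package's choices, as
no standard exists: the tolerance is on the per-neuron RMS speed, default
1e-3. Well-trained networks reach 1e-5 to 1e-4; large *constructed* networks
have an irreducible residual from finite-size overlap noise, of order
1/sqrt(N/3), which this default accommodates at N = 30000.

`linearize()` eigendecomposes `M = -E + G J` with `G = diag(phi'(x*))`. For
low-rank networks the nontrivial spectrum lives in an R-dimensional
subspace, so the eigenproblem reduces to the R x R overlap matrix
`O[r, q] = <G m_r, n_q>` (everything else sits at -1); this is what makes
the analysis exact at N = 30000 without ever forming an N x N matrix. The
near-zero mode is the *essentially real* eigenvalue closest to zero —
complex pairs are rotational modes, never line-attractor candidates; the
call errors if a second real eigenvalue also lies inside the +/-0.05 band
(a genuinely ambiguous line attractor) or if the closest candidate is
farther than 0.3 from zero (no line attractor). Selecting the closest eigenvalue rather than requiring
band membership tolerates the finite-size jitter of desk-scale constructed
networks; the acceptance filter, not `linearize()`, enforces the band.

Conventions: `rho` has unit norm and non-negative overlap with the
decision-variable representation direction (low-rank) or the readout
(full-rank), so directions are comparable across contexts; `s` is scaled so
`s . rho = 1`; context differences are *relevant minus irrelevant* (context
1 - context 2 for input 1, the reverse for input 2). The decomposition
`classical_modulation()` reports per-input components, their
`proportion_sv = mod_sel / (mod_inp + mod_sel)` (undefined and reported as
`NA` when the total modulation is ~0), and the combined proportion from the
summed components.

## Pathway analysis

For a low-rank network linearized at the context embedding (its construction
point; a slow-point option exists for trained networks), the effective
coupling from task variable `a` to internal variable `b` is
`E_{a->b} = <G rep_a, n_b>`, with `rep_a` the input embedding or the output
vector. `flow_graph()` arranges the task variables as a DAG (inputs,
intermediate variables, decision variable with a self-loop);
`total_effective_coupling()` sums edge-weight products over all forward
paths; `pathway_selection_vector()` forms
`n_tol = n_dv + sum_paths (prod of downstream couplings) n_{iv_first}`,
the connectivity-level selection vector. Two identities make it meaningful:
`M^T n_tol ~ 0` and `<G m_dv, n_tol> ~ 1` (checked at N = 30000 to within
the finite-size tolerance 0.05), so `n_tol` is, up to scale, the classical
selection vector — but now every term is attributable to a connectivity
pathway.

`pathway_modulation()` decomposes the contextual change of the total
coupling path by path: with each path weight written as (first edge) x
(rest), `Delta(xy) = Delta(x) y_bar + x_bar Delta(y)` assigns the first-edge
term (whose sender is the input) to input modulation and the remainder to
selection-vector modulation. For the three-variable circuit this reduces to
input modulation `Delta E_inp->dv + Delta E_inp->iv E_bar_iv->dv` and
selection-vector modulation `E_bar_inp->iv Delta E_iv->dv`. The closed-form
pulse response of a chain (`pulse_response()`) is a sum over paths of
regularized incomplete-gamma saturation curves
`K_j P(j, t/tau)`, converging to the total effective coupling; the
fine-step integrator `integrate_flow_ode()` (forward Euler, plus an RK4
oracle mode for high-accuracy checks, the package's only non-Euler
integrator) verifies it numerically. Forward Euler at dt = tau/100 carries
a truncation error of order 1e-3 on these curves, so sub-1e-4 agreement
checks use the RK4 oracle mode.

## Mean-field constructors

The handcrafted networks draw each neuron's connectivity components from a
three-population Gaussian mixture. A population receiving a unit-variance
context embedding has average gain `g = gaussian_gain(activation, 1)`
(Gaussian-weighted quadrature of `phi'`); ungated populations have gain 1.
The `build_rank3_family(alpha, beta, eta)` recipe then realizes, by
construction, couplings `E_inp->iv = beta`, `E_inp->dv = alpha`,
`E_iv->dv = eta` in the relevant context and 0 in the irrelevant one, with
unit decision-variable self-coupling — so input modulation is `alpha`,
selection-vector modulation `beta * eta`, and any mixture is dialable.
`build_rank3_pure_sv()` is the special case `alpha = 0, beta = 10/3,
eta = (1 - g^2)/3`. Finite-size accuracy of every overlap scales as
1/sqrt(N/3); the reference size is N = 30000 and tests at N = 3000-6000
widen tolerances accordingly. One family-parameter naming note: where a
figure-level description samples a third parameter named differently, the
intermediate-to-decision coupling is taken to be `eta` throughout, matching
the construction recipe.

`build_counterexample_pair()` constructs two networks sharing all
connectivity vectors except `n_dv`, routed so that one implements pure input
modulation and the other a half selection-vector mixture, while inducing
identical latent dynamics *in the mean-field limit*. Populations 1-2 (two
thirds of the neurons) have exactly identical activity; the decision
population integrates the overlap `<n_dv, phi(x)>`, whose finite-N
fluctuations (O(1/sqrt(N/3)), different between the two `n_dv` choices)
accumulate along the marginal decision mode. Per-neuron agreement is
therefore exact only as N -> infinity; at N = 30000 the decision-population
traces differ at the 1e-1 level over a trial while the decomposition
difference is robust. Because the rerouted modality is input 1, the
decomposition contrast between the pair is reported for input 1 (the
combined two-input share differs by exactly 1/2 in theory, which a
finite-sample test cannot resolve against a strict > 0.5 bound).

`build_redundant()` doubles a full-rank network with a disconnected second
population: matched input-embedding scales, within-population random
weights calibrated by simulation (bisection on the weight scale) until the
two populations' mean sum-of-square activity agrees within 10%, zero
readout. Because the readout here is `mean(w * phi(x))`, doubling N would
halve the output; the first population's readout weights are doubled so the
augmented network's output equals the original's exactly.

## Activity-level signatures

* `effective_dimension()` — the stable rank `sum sigma_i^2 / sigma_1^2` of
  the connectivity matrix.
* `tdr_axes()` — per-time regression of each neuron's activity on choice,
  the two signed strengths, and context; peak-norm time selection; QR
  orthogonalization in the order choice, input 1, input 2, context; and
  condition-averaged trajectories projected on the choice/input-1 axes.
* `fit_response_kernels()` — the pulse-regression model: per-time choice,
  context and time coefficients plus a 40-step convolution kernel per input
  per context (7 blocks x 40 = 280 coefficients per neuron), fitted by
  ridge regression over the stimulus period of (by default) 1000 trials.
  The design matrix is shared across neurons, so a single SVD solves every
  neuron; the ridge strength defaults to generalized cross-validation over
  a log-spaced grid (the selected value is recorded in the result), since
  no reference value exists.
* `kernel_modes()` / `pev_extra_modes()` — SVD of the 40 x 2N kernel matrix
  for one input across both contexts; the first left singular vector is the
  persistent (choice) mode, the rest are transient modes with normalized
  explained variance `sigma_{r+1}^2 / sum_{i>=2} sigma_i^2`. The
  selection-vector signature is the accumulated PEV of the *second and
  subsequent* transient modes: summing from the first transient mode would
  be identically 1 under this normalization, so the literal all-transient
  sum exists only behind `from_mode = 1`. A network whose kernels are
  spanned by the decision-variable and sensory profiles needs one transient
  mode; activity in extra dimensions — the dynamical fingerprint of
  selection-vector modulation — loads the second and later modes.

## Lesion analysis

`irrelevant_subspace()` searches for an r-dimensional activity subspace
whose removal (`J' = J(E - QQ^T)`) leaves the pulse response of the output
unchanged while capturing as much pulse-driven activity variance as
possible: loss `lambda (z_T - z_T_hat)^2 / z_T_hat^2 + (1 - ||f_hat Q||^2 /
||f_hat||^2)` with `lambda = 10`, Adam at learning rate 1e-5 for 2000
steps. `Q` is the first r columns of the Cayley transform
`(E + S)(E - S)^{-1}`, `S = A - A^T` (any fixed column choice is equivalent
under reparameterization), so orthonormality is exact throughout; gradients
flow through the 40-step simulation (BPTT) and through the matrix inverse
analytically. The pulse protocol is a unit pulse on input 1 at stimulus
onset in context 1 with no other stimulus input. `pev_irrelevant_activity()`
is the maximum captured variance over iterates whose output deviation stays
below 1e-3 (0, flagged, if none is feasible). Trained networks carry little
task-irrelevant variance and score low; redundant augmentations score
higher — the paired comparison is the meaningful readout.

## Problem sizes in the test suite

The reference analyses (mean-field identities, decomposition equivalence,
counterexample) run at the construction size N = 30000, where they are
fast because everything is vector algebra. Training-based checks are run at
smoke scale, chosen for a single-CPU run of the whole suite: one rank-1
network at the full reference setting (N = 512, 5000 steps, batch 256);
supporting rank-1 fixtures at N = 128 with 2500 steps; a full-rank ensemble
at N = 128, 3000 steps, batch 64 across three regularization values; ten
lesion pairs built on quickly trained 64-neuron networks.
Correlation checks across the ensemble use every network with an
unambiguous linearization and an in-range modulation proportion rather than
only band-accepted ones, since small ensembles would otherwise be decimated
by the filter. These smoke ensembles are substantially less converged than
the reference protocol (5000 steps, batch 256), and the
dimensionality-versus-mechanism correlation and the paired lesion contrast
are properties of converged, band-filtered populations; at smoke scale
those two checks are expected to be unreliable, and the full-scale sweeps
remain available through `train_ensemble()` and
`run_experiment("ensemble-fig7")` / `run_experiment("lesion")` with the
reference hyperparameters.

## Known limitations

* At the suite's training scale, gradient-trained networks reliably reach
  the line-attractor regime and the rank-1 selection-vector theorems, but
  contextual *gating* is only partial: the relevant input controls the
  choice while suppression of the irrelevant input remains incomplete
  (conflict trials sit near chance). Full gating requires longer training
  and/or selection across many seeds than a single-CPU suite run performs;
  the reference protocol is available through `train_network()` /
  `train_ensemble()` for full-scale runs.

* The pathway decomposition is defined for low-rank/constructed networks;
  for trained full-rank networks the modulation proportion comes from the
  classical decomposition. An SVD-truncated low-rank surrogate for trained
  networks is untested and deliberately not a default.
* Information-flow graphs assume feedforward routing between intermediate
  variables (a DAG plus the decision self-loop); recurrent coupling among
  intermediates is out of scope.
* The activity-level indices are diagnostic, not definitive: the
  counterexample pair shows that activity alone cannot separate the
  mechanisms in principle, and the lesion analysis explains when the indices
  work (little task-irrelevant variance).
* Euler integration at the task grid is the model definition, not an
  approximation to be refined; the RK4 mode exists only as an oracle for
  closed-form checks.
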