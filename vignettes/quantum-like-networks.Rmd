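---
title: "Quantum-like states of oscillatory networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-like states of oscillatory networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlnet)
```

## The model

`qlnet` treats a network of oscillatory node-circuits as a source of
zero-mean complex random signals $z = (z_1, \dots, z_N) \in \mathbb{C}^N$,
one complex amplitude per circuit.  All quantum-like (QL) structure is read
off the second-moment matrix

$$ C = (c_{km}), \qquad c_{km} = \mathbb{E}\,[z_k \bar z_m], $$

which is Hermitian and positive semidefinite by construction.  Its trace
normalization

$$ \rho = C / \operatorname{Tr} C $$

is a density matrix: the QL state generated by the network.  The map is
deliberately lossy in two ways — many signal distributions share a
covariance, and the overall activity scale is divided out — so a QL state
is a coarse, scale-free summary of the correlation structure, not a
reconstruction of the signals.

Observables enter the same way.  A Hermitian matrix $A$ corresponds to the
quadratic form $Q_A(z) = \langle Az, z\rangle$ of the signals, and the
identity

$$ \mathbb{E}_z[Q_A] = \operatorname{Tr}(C A) $$

is exact linear algebra, not an asymptotic statement: `quadratic_form_average()`
and `born_average()` agree to numerical precision on any finite sample,
provided the same (uncentered) covariance estimate is used on both sides.
Dividing by $\operatorname{Tr} C$ turns this into the Born rule
$\langle A\rangle_\rho = \operatorname{Tr}(\rho A)$.  Projective
measurements, state updates (Lüders rule), sequential joint probabilities
and the resulting order-effect asymmetries are implemented exactly as in
finite-dimensional quantum theory; no POVMs or detector models are
included.

Two conventions are fixed package-wide and recorded in every pipeline
report: the inner product conjugates the *first* argument
($\langle v|w\rangle = \sum_j \bar v_j w_j$, so $c_{km}=\mathbb{E}[z_k\bar z_m]$
is Hermitian), and the covariance divisor is $n$, matching the
time-average definition $\tfrac1T\sum_t x(t)\bar y(t)$.

### Ensemble versus time averages

Covariances may be estimated across independent realizations (`mode =
"ensemble"`) or along a single stationary recording (`mode =
"timeseries"`).  Equality of the two is an ergodicity assumption that the
package can only test for its own synthetic stationary processes (it
holds there by construction); for real recordings it is an assumption the
user makes, and the averaging-window length is a free parameter with no
privileged default.  Centering is on by default: the framework assumes
zero-mean signals, and `estimate_covariance(center = TRUE)` enforces that
rather than trusting the recording.

## Oscillator dynamics and the Schrödinger picture

A quadratic, symplectically invariant Hamiltonian
$H(q,p) = \tfrac12[(Rp,p) + 2(Tp,q) + (Rq,q)]$ with $R^\top = R$ and
$T^\top = -T$ generates the linear phase flow $\dot x = Ax$,
$A = \begin{pmatrix} -T & R\\ -R & -T\end{pmatrix}$ on
$x = (q, p) \in \mathbb{R}^{2N}$.  Complexifying with $\psi = q + ip$
turns this flow into $i\dot\psi = H\psi$ with the Hermitian matrix

$$ H = R - iT. $$

The sign convention is chosen so that the complexified equation reproduces
the drift matrix $A$ exactly; the spectral correspondence
$\mathrm{eig}(A) = \{\pm i\,\mathrm{eig}(H)\}$ is property-tested over
random $(R, T)$ pairs.  Eliminating $p$ gives the coupled-oscillator form
$\ddot q + C_v\dot q + Kq = 0$ with $C_v = T + RTR^{-1}$ and
$K = R^2 + RTR^{-1}T$ (`second_order_matrices()`; requires invertible $R$).

```{r dynamics}
spec <- hamiltonian_spec(R = diag(c(1, 4)),
                         T = matrix(c(0, -0.5, 0.5, 0), 2, 2, byrow = TRUE))
mode_frequencies(spec)
second_order_matrices(spec)
```

Propagation uses eigendecomposition-based matrix exponentials — for these
linear flows that is exact up to eigensolver precision, and an independent
ODE integration (deSolve) cross-checks it in the test suite only.  Time
grids are user-supplied; the package claims no default step.  Indefinite
Hamiltonians propagate fine (the flow is still linear) but are rejected by
`mode_frequencies()`, since "the positive frequencies" of an indefinite
quadratic form are not well defined.  Unitarity of the induced von Neumann
evolution $\rho(t) = U\rho_0U^\dagger$ (trace, spectrum, purity, entropy
all conserved) is asserted rather than assumed.

A remark on the complexification scale: mapping phase-space data to
complex amplitudes via $z = (q+ip)/\sqrt2$ or $z = q+ip$ changes $C$ by a
constant factor only, which the trace normalization absorbs.  QL states,
probabilities and all entanglement measures are therefore independent of
this constant; the dynamics functions use $\psi = q + ip$ so that the
phase-flow/Schrödinger equivalence is an identity without bookkeeping
factors.

## Compound networks and entanglement

A compound network over factor networks of sizes $N_1$ and $N_2$ lives on
$N_1N_2$ channels indexed row-major, $k = (i-1)N_2 + j$.  Every tensor
operation — Kronecker products, the tensor basis induced by two commuting
degenerate observables, partial traces, partial transposes, Schmidt
reshaping, concurrence conjugation — uses this single index convention,
which is also written into pipeline reports.  The concurrence depends on
the basis in which the complex conjugate of the state is taken, so the
declared product basis is part of the call contract.

The quantification layer is standard mixed-state machinery: negativity
$N(\rho) = (\lVert\rho^{T_B}\rVert_1 - 1)/2$ (computed from the
eigenvalues of the Hermitian partial transpose, not an SVD), logarithmic
negativity $\log_2(2N+1)$, two-qubit concurrence, base-2 von Neumann
entropies, mutual information, and the CHSH combination
$S = \langle AB\rangle + \langle AB'\rangle + \langle A'B\rangle -
\langle A'B'\rangle$.  PPT is reported as conclusive for separability only
in the $2\times2$ and $2\times3$ cases, where the Horodecki theorem
guarantees it; in higher dimensions a positive partial transpose yields
the verdict `"undetermined"` — mixed-state separability is genuinely hard
and no stronger criterion is implemented.

CHSH settings are user inputs.  As a convenience (an extension, not part
of the core construction), `chsh_optimal_settings()` returns the planar
settings $A(\theta) = \cos\theta\,\sigma_z + \sin\theta\,\sigma_x$ at
angles $(0, \pi/2)$ and $(5\pi/4, 3\pi/4)$, for which the singlet attains
$S = 2\sqrt2$ under the combination above.

### Why the product construction cannot entangle — and what does

The simplest compound-signal construction multiplies paired factor
signals, $Z_{ij} = z_{1,i}\,z_{2,j}$.  Its population covariance is

$$ \mathbb{E}[ZZ^\dagger]
   = \mathbb{E}\bigl[(z_1z_1^\dagger)\otimes(z_2z_2^\dagger)\bigr], $$

a mixture of product states with positive weights — which is precisely the
definition of a *separable* state.  This holds for **any** joint
distribution of $(z_1, z_2)$, however strongly the two networks are
correlated: statistical coupling between the factor signals shows up in
the compound covariance (the Gaussian Wick expansion adds rank-one
coherence terms) but can never push the state across the PPT boundary.
The package asserts this as a test (maximally cross-correlated Gaussian
networks come out separable) rather than hiding it.

Entangled compound states therefore require compound circuits that carry
*their own* signal, beyond the product of their parents — physically, the
signaling channels that create a compound circuit contribute to its
activity.  `channel_coupled_ensemble()` implements the minimal such
generator: on top of the product background of two independent
unit-variance factor networks, a shared channel amplitude $e$ enters the
$(1,2)$ and $(2,1)$ compound circuits with opposite signs and gain $g$,
reproducing at the compound level the perfect anti-correlation that makes
the singlet.  The population state is then the Werner-type mixture
$\rho \propto I_4 + 2g^2P_{\psi^-}$ with negativity
$(g^2-1)/(4+2g^2)$: NPT exactly when $g > 1$.  The default $g = 2$
(population negativity $0.25$) is the package's strong-coupling reference
condition, chosen once as a point comfortably inside the NPT region; the
sub-threshold regime is exercised with $g = 0.5$.

```{r entangle}
rho <- normalize_to_density(
  estimate_covariance(channel_coupled_ensemble(5e4, seed = 1, gain = 2)),
  dims = c(2, 2))
entanglement_report(rho)
```

The perfectly anti-correlated pair itself is generated directly by
`singlet_ensemble()`: one Gaussian amplitude written with opposite signs
to two circuits, silent elsewhere.  Its estimated QL state is exactly
rank-1 for every sample size (all draws are proportional to one vector),
so the sampled singlet passes every entanglement detector at any $n$; the
$n$-dependence in the tests is in the covariance scale, not the state.

One caveat the package makes explicit: the marginal states obtained by
partial tracing a compound state are *marginals* of the compound
correlation structure.  They are not the states the factor networks would
have in the absence of coupling — nothing in the compound covariance
determines those — and no function claims otherwise.

## Synthetic data: what it emulates and what it does not

All generators draw circularly symmetric complex Gaussians
($\mathbb{E}[z_kz_m] = 0$; only the Hermitian second moment is
controlled).  Circularity is a modeling choice: the QL construction only
constrains $\mathbb{E}[z\bar z^\top]$, and circularity makes the
fourth-moment (Wick) factorization of compound covariances exact, which
is what the product/Kronecker tests rely on.  Non-Gaussian or
non-circular signals would change compound fourth moments while leaving
every single-network QL state identical — a reminder that passing tests
on these generators validates the estimators and the algebra, not any
claim about real recordings.  Real EEG/MEG data additionally carry
non-stationarity, volume conduction, reference effects and artifacts,
none of which are modeled; the functional-connectivity module's robust
metrics address zero-lag mixing statistically but do not reconstruct
sources.

Rank-deficient target covariances are factored by eigendecomposition with
eigenvalues below $10^{-10}\cdot\max(\lambda)$ clipped to exactly zero,
so degenerate targets produce draws exactly inside the intended subspace.
Every generator is bit-reproducible from its seed.

## Classical connectivity baselines

For side-by-side comparison with the QL measures, the package implements
the standard functional-connectivity estimators: time-domain covariance
and Pearson correlation (divisor $T$), magnitude-squared coherence
$|S_{xy}|^2/(S_{xx}S_{yy})$ from Welch-averaged spectra, the
phase-locking value from Hilbert analytic-signal phases, and the zero-lag
robust pair — imaginary coherency and wPLI.  Choices, each configurable:

* **Welch estimator**: Hann window, 50% overlap, segment length a
  parameter defaulting to one eighth of the recording (at least 16
  samples).  Welch was chosen over multitaper for determinism and
  dependency economy; at least two segments are required, since a
  single-segment coherence is identically 1.  As a rule of thumb the
  segment should cover 5–10 cycles of the slowest rhythm of interest
  (frequency resolution is $f_s/\text{seg\_len}$).
* **PLV edge trimming**: 10% of samples per side are discarded after the
  analytic-signal construction to suppress FFT edge artifacts.
* **wPLI**: the weighted phase-lag index
  $|\overline{\Im S^{(k)}_{xy}}| \,/\, \overline{|\Im S^{(k)}_{xy}|}$
  over Welch segments $k$.  Its formula (and imaginary coherency's) come
  from the standard signal-processing literature; the Welch machinery,
  analytic signal and wPLI are implemented in-package.

Surrogate controls (trial shuffling via `shuffle_surrogate()`) are the
recommended null: they preserve marginal statistics while destroying
cross dependence, and the tests verify that locked signals collapse to
null levels under them.

The analogy between the two families is structural, not quantitative:
covariances play the role of density-matrix entries and phase synchrony
the role of off-diagonal coherences, and on the synthetic singlet the
classical cross-covariance is maximal exactly where the QL state's
off-diagonal coherences are — but no unit-for-unit equivalence is implied.

## Numerical choices

* Hermitization $(M + M^\dagger)/2$ precedes every eigen-analysis.
* Density-matrix eigenvalues in $[-10^{-10}, 0)$ are clipped to zero with
  trace renormalization; anything more negative is an error, never
  silently repaired.
* Trace-normalization refuses covariances with
  $\operatorname{Tr} C \le 10^{-12}N$ (an all-inactive network has no QL
  state) instead of emitting non-finite entries.
* Degenerate eigenvalues are merged into one projector when closer than
  $10^{-8}\cdot\max(1, \max|M|)$, user-overridable — the tensor-basis
  construction depends on recognizing exact degeneracy patterns.
* Zero-probability measurement outcomes raise an error: the conditional
  state is undefined, and returning anything would be wrong.
* Entropies use $0\log 0 = 0$ and drop eigenvalues below $10^{-15}$.

## Problem sizes

The shipped tests run networks of 2–6 channels with ensembles of
$10^2$–$10^5$ draws, 50 random oscillator systems of dimension up to 5 on
100-point grids, and recordings of 2048–4096 samples for the spectral
estimators — sizes at which every statistical tolerance (set at 3–6
standard errors) is comfortably resolved while the whole suite runs in
seconds.  Larger problems only change runtimes: all algorithms are dense
linear algebra with at most $O(N^3 + nN^2)$ cost.

## Limitations

* Strictly linear (quadratic-Hamiltonian) dynamics: no dissipation, no
  nonlinearity, no biophysical neuron models.
* Bipartite entanglement only; no multipartite measures, no entanglement
  witnesses beyond PPT/negativity, no entanglement of formation beyond
  the two-qubit concurrence correspondence.
* Projective measurements only.
* File formats are plain text (CSV/JSON/YAML); no EDF/FIF ingestion or
  artifact rejection — preprocessing of real recordings is out of scope.
* The reconstruction of which signals generated a given covariance is
  impossible in principle (the map is many-to-one), and the package does
  not attempt it.
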