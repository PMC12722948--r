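# qlnet

Quantum-like (QL) representation of oscillatory network activity in R.

## The problem

Coupled oscillatory circuits — neuronal populations recorded by EEG/MEG,
or any network of noisy oscillators — generate correlated zero-mean
complex signals `z = (z_1, …, z_N)`.  Quantum-like modeling summarizes
such a network not by its wiring but by the second-moment structure of
its signals: the covariance matrix

    C = (c_km),   c_km = E[ z_k · conj(z_m) ]

is Hermitian and positive semidefinite, and its trace normalization

    ρ = C / Tr C

is a *density matrix* — a QL state.  Hermitian matrices `A` act as
observables through their quadratic forms `Q_A(z) = ⟨Az, z⟩`, with the
exact identity `E[Q_A] = Tr(C A)` linking classical signal averages to
the Born rule `⟨A⟩_ρ = Tr(ρ A)`.  On this substrate the package provides:

* **State space** — covariance estimation (ensemble or time average,
  divisor `n`), trace normalization, pure states, purity diagnostics.
* **Dynamics** — quadratic-Hamiltonian phase flows `ẋ = Ax` with
  `A = [[−T, R], [−R, −T]]`, their complexification to the Schrödinger
  equation `i dψ/dt = (R − iT) ψ` for `ψ = q + ip`, the second-order
  coupled-oscillator form `q̈ + (T + RTR⁻¹) q̇ + (R² + RTR⁻¹T) q = 0`,
  and unitary von Neumann evolution of QL states.
* **Observables** — spectral decomposition, Born probabilities, Lüders
  state updates, sequential joint probabilities and question-order
  asymmetries, compatible-observable correlations.
* **Entanglement** — compound networks on `N1·N2` channels (row-major
  index `k = (i−1)N2 + j`), tensor bases from commuting observable
  algebras, Schmidt analysis, partial trace/transpose, negativity and
  logarithmic negativity, two-qubit concurrence, von Neumann entropies,
  mutual information, PPT verdicts, CHSH expectations.
* **Connectivity baselines** — covariance/Pearson, Welch coherence,
  phase-locking value, imaginary coherency, wPLI, pairwise FC matrices,
  trial-shuffled surrogates.
* **Synthetic generators** — seeded circular complex Gaussian ensembles,
  the perfectly anti-correlated (singlet) pair, independent and
  cross-correlated factor networks, channel-coupled entangling compound
  networks, propagated oscillator ensembles.

Audience: researchers exploring quantum-like analyses of multichannel
oscillatory recordings, and anyone needing a compact, well-tested R
toolbox for density-matrix construction and mixed-state entanglement
measures on small systems.

## Worked example

Two coupled oscillators with stiffness block `R = diag(1, 4)` and
gyroscopic coupling `T = [[0, −0.5], [0.5, 0]]`:

```r
library(qlnet)
spec <- hamiltonian_spec(R = diag(c(1, 4)),
                         T = matrix(c(0, -0.5, 0.5, 0), 2, 2, byrow = TRUE))
mode_frequencies(spec)
#> [1] 0.9188612 4.0811388
```

These are the magnitudes of the purely imaginary drift-matrix eigenvalue
pairs and, identically, the eigenvalues of the Hermitian Hamiltonian
`R − iT`: the network oscillates at two frequencies, ≈ 0.9189 and
≈ 4.0811.

An entangled compound network: two independent 2-channel factor networks
whose compound circuits also carry a shared anti-correlated channel
signal (gain 2), sampled 100 000 times with a fixed seed:

```r
e   <- channel_coupled_ensemble(n = 1e5, seed = 42, gain = 2)
rho <- normalize_to_density(estimate_covariance(e), dims = c(2, 2))
entanglement_report(rho)
#> <ql_entanglement_report> bipartition 2 x 2
#>   negativity      0.249818   log-negativity 0.584613
#>   concurrence     0.49964
#>   S = 1.208, S_A = 1, S_B = 1, I(A:B) = 0.7919 bits
#>   PPT verdict: entangled
```

The estimated negativity ≈ 0.25 matches the population value
`(gain² − 1)/(4 + 2·gain²) = 0.25` of this generator; a positive
negativity certifies that the compound QL state is NPT, i.e. entangled.
Replacing the channel-coupled generator with `product_networks()` (no
channel signal) drives the negativity to 0 and the verdict to
`separable` — product-signal compounds are separable for *any* coupling
between the factor networks, a structural fact the test suite asserts.

A command-line front end with `synth`, `simulate`, `estimate`, `measure`,
`entangle`, `connectivity` and `pipeline` subcommands lives at
`inst/scripts/qlnet.R`:

```sh
Rscript inst/scripts/qlnet.R synth --kind channel --n 20000 --seed 5 --out chan.csv
Rscript inst/scripts/qlnet.R pipeline --signals chan.csv --region1 "1 2 3 4" \
        --compound direct --dims "2 2" --report report.json
```

See `vignettes/quantum-like-networks.Rmd` for the model, conventions,
design decisions and limitations.

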