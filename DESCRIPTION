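Package: qlnet
Title: Quantum-Like Representation of Oscillatory Network Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantum-like (QL) states from the second-moment structure of
    multichannel oscillatory signals, in the tradition of prequantum classical
    statistical field theory: covariance matrices of zero-mean complex random
    oscillations are trace-normalized into density matrices, quadratic-form
    observables become Hermitian operators with Born-rule statistics, and
    coupled-harmonic-oscillator phase flows are complexified into Schrodinger
    dynamics. Provides compound-network tensor constructions, mixed-state
    entanglement quantification (partial trace/transpose, negativity,
    concurrence, von Neumann entropies, mutual information, PPT verdicts, CHSH
    expectations), sequential projective measurements and order-effect
    asymmetries, classical functional-connectivity baselines (covariance,
    Pearson, Welch coherence, phase-locking value, imaginary coherency, wPLI),
    and seeded synthetic generators for every statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
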