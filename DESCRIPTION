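Package: auxqmmm
Title: Auxiliary Density-Functional QM/MM with Asymptotic Far-Field Integral Expansions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale QM/MM engine built around auxiliary density
    functional theory (ADFT). Provides exact molecular integrals over
    contracted Cartesian Gaussians and primitive Hermite auxiliary
    functions, near/far-field classification of embedding point charges
    with multipolar asymptotic expansions of nuclear-attraction and
    three-center repulsion integrals, a variationally density-fitted
    Kohn-Sham SCF with LDA exchange-correlation on the fitted density and
    conventional/direct/mixed integral schemes, a classical force field
    with Drude polarizable sites, additive and subtractive (ONIOM) QM/MM
    coupling with link atoms and FIRES flexible solvent boundaries, and
    Born-Oppenheimer molecular dynamics with dual-topology free energy
    perturbation and Hamiltonian replica exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
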