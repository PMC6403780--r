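Package: leip
Type: Package
Title: Local Effective Interaction Parameters for Charge Regulation in Linear Weak Polyelectrolytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transfer-matrix machinery for the site-binding (SB), rotational
    isomeric state (RIS) and combined SBRIS models of linear weak
    polyelectrolytes, together with the Local Effective Interaction Parameters
    (LEIP) variational treatment of screened Debye-Hueckel long-range
    electrostatics. Long-range interactions are folded into pH- and ionic
    strength dependent effective short-range parameters (effective pK and
    effective gauche energies) obtained from the Gibbs-Bogoliubov principle,
    so that titration curves and bond-conformer populations of flexible weak
    polyelectrolytes can be computed in seconds. A bundled constant-pH
    (semi-grand canonical) Metropolis Monte Carlo simulator with explicit
    three-dimensional chain geometry and brute-force enumeration oracles are
    provided for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
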