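Package: zurlink
Title: Linked Zinc and DNA Binding Equilibria of the Zur Metalloregulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Thermodynamic analysis of the zinc uptake regulator (Zur) of
    Streptomyces coelicolor: simulation and nonlinear fitting of integrated
    isothermal titration calorimetry isotherms (single-class, three-site,
    chelator-competition and protein-DNA oligomer models) with the
    apparent-to-intrinsic chelator-competition correction; a statistical-
    thermodynamic model coupling the six regulatory zinc sites of the Zur
    dimer to oligomeric binding on znuA and zitB promoter DNA; estimation
    of oligomeric DNA-binding constants from electrophoretic mobility
    shift band fractions; and a coarse-grained two-tier simulation of the
    biphasic zinc-dependent activation of the zitB gene. Includes
    deterministic synthetic-data generators matching the published
    experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
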