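Package: bundlegate
Title: Continuum Mechanics and Spin-Label EPR Analysis of the MscL
    C-Terminal Helical Bundle
Version: 0.1.0
Authors@R:
    person("Bundlegate", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained finite-element modelling of the gating of the
    bacterial mechanosensitive channel of large conductance (MscL), focused
    on the cytoplasmic C-terminal five-helix bundle.  Alpha-helices are
    represented as elastic rods, the lipid bilayer as an elastic
    (membrane + bending) plate, and the inter-subunit interaction belts of
    the bundle as nonlinear connector elements whose force-displacement
    tables are derived from Debye-Hueckel screened electrostatics and a
    DSSP-style hydrogen-bond energy.  The package also implements the
    site-directed spin-labelling EPR readouts used to probe the bundle
    experimentally (central-line mobility, power-saturation accessibility,
    helical periodicity, closed-versus-open segment calling), together with
    synthetic-data generators for every input so the full pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
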