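Package: osteokin
Title: Growth, Proliferation and Diffusion Kinetics of Osteosarcoma Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three minimal kinetic models to osteosarcoma cell-line data:
    a power-law (allometric) model of in vivo tumor volume growth, a logistic
    model of in vitro cell confluence, and a point-source solution of the
    linearized Fisher-Kolmogorov reaction-diffusion equation from which a
    per-timepoint diffusion coefficient is estimated.  Cell lines are ranked
    into growth, proliferation and diffusivity tiers, scale exponents are
    assigned to allometric clusters (2/3, 3/4, 5/6), diffusion estimates are
    validated by a coefficient-of-variation rule, and fitted parameters are
    correlated against experimental phenotype levels (tumorigenicity, colony
    formation, invasion, migration, proliferation).  Includes a synthetic-data
    generator with known ground truth for parameter-recovery testing and a
    pipeline that runs all stages from CSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
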