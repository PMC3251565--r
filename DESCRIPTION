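Package: spinrelax
Title: Model-Free Analysis of Backbone Amide 15N Spin Relaxation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein backbone dynamics from heteronuclear
    15N NMR relaxation data. Estimates longitudinal (R1) and transverse (R2)
    relaxation rates from peak-height decay series and steady-state 1H-15N NOEs
    from saturated/reference pairs, then infers per-residue Lipari-Szabo
    model-free parameters (generalized order parameter S2, effective internal
    correlation time tau_e, conformational exchange broadening Rex) and the
    overall rotational correlation time tau_m by chi-square minimization with
    stepwise model selection and Monte Carlo error estimation. Includes a
    synthetic-data generator emulating a small disulfide-bonded disintegrin
    with a flexible RGD loop, and reporting utilities for comparing the
    dynamics of two protein variants residue by residue.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
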