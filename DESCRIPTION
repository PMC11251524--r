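Package: riboscape
Title: Conformational Landscapes, Ion Atmosphere and SHAPE Reactivity of
    Riboswitch Aptamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for combined molecular-dynamics and chemical
    probing studies of riboswitch aptamer domains, built around the
    2'-deoxyguanosine (2'-dG) aptamer.  Provides trajectory fluctuation
    metrics (RMSD, RMSF, radius of gyration, native base-pair, stack and
    hydrogen-bond contacts), Cartesian principal-component analysis with
    free-energy surfaces and basin counting, ion-atmosphere statistics
    (bulk concentration, preferential interaction coefficients, windowed
    diffusion coefficients, association-site detection and residence
    times), and processing of capillary-electrophoresis SHAPE traces into
    normalized per-nucleotide reactivities.  Synthetic-data generators with
    known ground truth (harmonic or two-state fluctuations, Brownian ions
    with trap sites, multi-Gaussian electropherograms) make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
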