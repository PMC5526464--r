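Package: fflmpi
Title: Field-Free-Line Magnetic Particle Imaging Simulation and Design Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Full-system simulator and design-analysis workbench for projection
    field-free-line (FFL) magnetic particle imaging (MPI). Models coil windings
    by exact straight-segment Biot-Savart integration, ideal FFL gradient,
    shift and drive fields, Langevin magnetization of superparamagnetic iron
    oxide nanoparticle (SPION) tracers, reciprocity-based receive-coil voltage
    synthesis with harmonic (comb-filter) detection, discrete shift-and-rotate
    sinogram acquisition, and least-squares image reconstruction with analytic
    and Monte-Carlo SNR propagation. Includes closed-form receiver noise
    budgets (Johnson-Nyquist coil noise, cylindrical body-load loss),
    magnetostimulation and peripheral-nerve-stimulation safety screening, dose
    arithmetic for cerebral-blood-volume functional contrast, synthetic
    phantoms, and named rodent- and human-scale scanner presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
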