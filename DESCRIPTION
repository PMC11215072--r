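Package: AmyloidDyn
Title: Latent-Space Quantification and Progression Modeling of Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative latent-space analysis of volumetric amyloid PET.
    A 3D style-based generative adversarial network with a convolutional
    inversion encoder embeds PET volumes into a low-dimensional latent
    space; principal component analysis and linear regression quantify
    global SUVR from the latents; a non-parametric ordinary differential
    equation model (Gaussian-process regression of finite-difference
    latent velocities, integrated with forward Euler) forecasts amyloid
    trajectories and renders synthetic PET image evolutions. A synthetic
    phantom-brain cohort generator with known logistic amyloid dynamics
    provides ground truth for building and validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    RNifti,
    jsonlite,
    yaml,
    deSolve,
    pROC
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
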