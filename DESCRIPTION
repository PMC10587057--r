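Package: gyrodesign
Title: Generative Active-Learning Design of Graded Gyroid Bone Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs heterogeneous graded-porosity gyroid (triply periodic
    minimal surface) scaffolds with a target elastic modulus, maximal yield
    strength and a mass constraint. Scaffolds are parameterised by small
    porosity matrices realised through a spatially varying level-set
    isovalue, voxelised to binary occupancy grids and exportable as STL
    meshes. A 3D convolutional autoencoder learns an 8-dimensional latent
    design space, a Gaussian mixture models it for sampling, and twin 3D
    convolutional network regressors predict elastic modulus and yield
    strength from voxel grids. A constrained epsilon-greedy multi-objective
    active-learning loop searches the latent space for designs whose
    modulus sits in a target band while maximising strength under a mass
    cap, querying a pluggable mechanics oracle (a calibrated Gibson-Ashby
    style analytic model by default, or an external solver adapter).
    Includes stress-strain post-processing (linear-region modulus, 0.2
    percent offset yield), Gibson-Ashby scaling fits, regression activation
    maps for model interpretation, and random-search and Bayesian
    optimisation baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    mclust,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
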