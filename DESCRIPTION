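Package: trapmorph
Title: Growth Models and Morphometrics for Utricularia Trap Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the morphogenesis of Utricularia gibba suction traps as
    a growing polarised tissue sheet: a hollow spherical canvas with regional
    factors (midline, stalk, ventral midline, mouth) and a propagated polariser
    field is advanced through time by converting specified growth-rate tensors
    into resultant deformation via residual strain-energy minimisation on a
    wedge-element shell mesh. Includes virtual cell tiling with threshold-area
    division and clonal marking, shape and strain-rate morphometrics
    (circumference extraction, second-moment cell anisotropy, clone anisotropy
    decomposition, exponential-growth staging), quadrifid gland polarity
    scoring from 3D landmarks, and synthetic data generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
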