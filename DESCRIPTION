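Package: gaffa
Title: Anatomical Landmark Localization with Explicit MRF Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for anatomical landmark localization in 2-D medical
    images. Couples heatmap-regression localization (a compact U-Net trained
    with on-the-fly spatial, intensity and occlusion augmentation) with three
    landmark refinement paradigms: GAFFA, a differentiable single-iteration
    sum-product refinement of a Markov random field in log-energy space whose
    convolution kernels are initialized from Gaussian-mixture conditional
    displacement priors; a SpatialConfiguration-Net head; and an external
    graphical model solved with loopy belief propagation over blob candidates.
    Includes physical-scale evaluation metrics with outlier statistics, an
    occlusion-robustness test protocol, and a procedural generator of
    hand-like radiograph images with 37 consistent landmark annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mclust,
    jsonlite,
    png,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'augment.R'
    'gaffa-package.R'
    'gaffa.R'
    'gm.R'
    'heatmap.R'
    'io.R'
    'metrics.R'
    'nn.R'
    'occlusion.R'
    'priors.R'
    'scn.R'
    'study.R'
    'synthetic.R'
    'topology.R'
    'train.R'
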