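Package: mobvec
Title: Gravity-Equivalent Neural Embedding of Migration Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns dense vector representations of locations from individual
    migration and mobility trajectories with skip-gram negative-sampling
    (SGNS) word2vec, whose implied flow model has the same functional form as
    the gravity law of mobility. Provides trajectory corpus input/output,
    co-occurrence flux matrices, a deterministic SGNS trainer with the
    implied conditional and flux recovered from the trained vectors, spectral
    and diffusion baselines (SVD, Laplacian eigenmap, personalized PageRank),
    gravity-model fitting with geographic or embedding distances, a synthetic
    gravity-world simulator for benchmarking, SemAxis projections for
    interrogating latent axes, and element-centric clustering similarity for
    comparing hierarchical and flat clusterings of the embedding space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    geosphere,
    ape,
    withr,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
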