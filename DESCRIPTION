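Package: signicon
Title: Visual Iconicity Analysis of Sign Language Pose Trajectories
Version: 0.1.0
Authors@R: person("signicon", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for studying visual iconicity in sign languages from
    body-pose keypoint trajectories. Extrapolates hand positions from
    elbow-wrist geometry, normalizes coordinates into a signer-centred body
    frame, classifies signs as one- or two-handed from hand path lengths,
    relates two-handedness to latent lexical plurality through a hierarchical
    Bayesian logistic regression fitted by Hamiltonian Monte Carlo, and
    quantifies location iconicity of signs against non-signer location
    ratings via rectangle-distance scores and hand-activity heatmaps. A
    synthetic-data generator emulates keypoint videos, plurality rating
    questionnaires and location ratings so the full pipeline is testable
    without any external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
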