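Package: ribofold
Title: Coarse-Grained RNA Structure Prediction and Assessment Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for coarse-grained RNA tertiary structure
    prediction and assessment. Implements a composite-likelihood masked RNA
    language model with nucleotide and ordered-pair prediction heads,
    unsupervised contact extraction via the categorical Jacobian with average
    product correction, rigid-frame geometry for three-atom (P, C4', N)
    nucleotide models, generalized frame-aligned point error and binned
    distance losses with denoising perturbations, a consensus
    selection/optimization protocol over structure decoy pools (scoring,
    base-pair filtering, L-BFGS refinement and greedy clustering), and the
    standard RNA structure assessment metrics (TM-score, RMSD, interaction
    network fidelity, deformation index). Ships a synthetic-data module that
    generates covariation-bearing sequence families, toy three-dimensional
    folds and noisy decoy pools, so every stage runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
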