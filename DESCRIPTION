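Package: devoxel
Title: Quantitative ASL Perfusion, Carotid Flow and Distributed Deviating
    Voxel Analysis
Version: 0.1.0
Authors@R:
    person("devoxel", "maintainers", email = "devoxel@example.org",
           role = c("aut", "cre"))
Description: Quantifies cerebral blood flow (CBF) maps from 2D multislice
    pseudo-continuous arterial spin labeling (pCASL) control/label series
    using the single-compartment whitepaper model with slice-dependent
    post-labeling delay and background-suppression correction, including
    grey-matter partial-volume correction and robust control-label pair
    rejection. Quantifies internal carotid artery blood flow from
    velocity-encoded phase-contrast cine images. Implements a normative
    'distributed deviating voxels' statistic: voxelwise z-scores against a
    leave-one-out reference cohort, two-sided thresholding, and regional
    tallies of deviating voxels as a percentage of intracranial volume.
    Includes atlas-based regional means, staged covariate-adjusted group
    comparisons, a seeded synthetic phantom generator for end-to-end
    testing, minimal NIfTI-1 input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
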