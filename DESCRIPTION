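Package: t1relax
Title: Quantitative T1 Relaxation Mapping from T1-Weighted Gradient-Echo MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives voxel-wise T1 relaxation maps from ordinary 3D T1-weighted
    spoiled gradient-echo (3DT1TFE/SPGR) magnitude images by calibrating a
    scanner constant against reference tissues (normal-appearing white and
    gray matter) and inverting the steady-state signal equation in closed
    form. Includes ROI-level T1 statistics for chronic multiple sclerosis
    lesions and gray matter, a synthetic digital brain phantom with known
    per-tissue T1 and configurable Gaussian or Rician noise for validation,
    a longitudinal cohort simulator, and the paired-test, rank-correlation
    and linear-regression analyses used in longitudinal atrophy studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
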