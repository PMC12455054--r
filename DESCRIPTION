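Package: nadbold
Title: Neuronal Afterdischarge Detection and BOLD Baseline Decline Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combined in-vivo electrophysiology and BOLD-fMRI
    studies of stimulus-evoked neuronal afterdischarges (nAD) in the rodent
    hippocampus. Conditions dentate-gyrus local field potentials recorded
    inside the scanner (artifact blanking, decimation to 1000 Hz, zero-phase
    0.5-100 Hz band-pass), detects the end of afterdischarge episodes with a
    five-times-baseline amplitude rule, and scores their intensity as the
    rectified area under the curve per second. Quantifies sustained declines
    of the BOLD baseline in a volume of interest: normalization to a grand
    mean of 100 percent, group time courses, pointwise equal-variance t-tests
    with Bonferroni correction, a 98-percent recovery criterion, and
    condition-subtraction traces. Includes the group statistics used in such
    studies (pooled and paired t-tests from raw data or printed summaries,
    TOST equivalence with 90 percent confidence intervals, the n = 16/Delta^2
    sample-size rule) and a seeded synthetic-data generator that emulates the
    full experiment so that every stage of the pipeline can be tested without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
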