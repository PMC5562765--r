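Package: octpulse
Title: Ocular Fundus Pulsation Elastography and Angiography from Repeated
    Complex OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for phase-sensitive optical coherence
    tomography (OCT) of the posterior eye. Measures nanometer-scale ocular
    fundus pulsations as the relative axial motion between the retina and the
    chorioscleral complex by inter-B-scan phase differencing with phasor-based
    bulk-motion correction, converts phase shifts to axial velocities with
    incidence-angle correction, quantifies pulsatility by short-time Fourier
    analysis (fundamental and harmonic amplitudes, heart rate, displacement
    amplitude), maps perfusion by amplitude-decorrelation OCT angiography with
    Frangi vesselness enhancement and flux quantification over anatomical
    plexus slabs, and gates velocity maps retrospectively over the cardiac
    cycle. Ships a synthetic complex-speckle phantom generator with exact
    ground truth (layered reflectivity, cardiac displacement waveforms, bulk
    drift, curved geometry, decorrelating flow voxels), an HDF5 container
    dialect for complex OCT volumes, TIFF/CSV map export, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    tiff,
    EBImage,
    signal,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
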