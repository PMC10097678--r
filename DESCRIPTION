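Package: proprio
Title: Analysis of Proprioceptive Limb-Movement Encoding in Cortical Imaging and Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how passive forelimb movements delivered by a
    planar robotic manipulandum are encoded in mouse cortex and perception.
    Covers pantograph forward/inverse kinematics, trapezoidal trajectory
    generation, stereo triangulation and similarity-transform registration of
    3D joint tracking, and humerus azimuth-angle maps over the planar
    workspace; two-photon calcium trace preprocessing (FFT motion-shift
    estimation, AR(1) spike deconvolution, spike-rate densities,
    stimulus-evoked responses with a circular-shift randomization test);
    Gaussian direction-tuning fits with selectivity criteria, Rayleigh tests,
    forward/return angular-shift analysis and peripersonal delta-ratio
    statistics; dual-channel wide-field stack processing (channel
    demultiplexing, per-pixel hemodynamic regression correction,
    Savitzky-Golay smoothing, peak-frame maps, landmark-based affine atlas
    registration, half-peak activation contours); behavioral statistics for a
    two-alternative forced-choice discrimination task (adaptive side-bias
    controller, cumulative-Gaussian psychometric fitting with guess and lapse
    rates, probe-trial and inactivation summaries); and synthetic-data
    generators with attached ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    signal,
    pracma,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
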