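Package: graspkin
Title: Reach-to-Grasp Kinematics and Grasp-Posture Imaging for an
    Instrumented Drinking Glass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for sensorized-object assessment of upper-limb
    function in children. Segments inertial recordings of a simulated
    "drinking from a glass" task into accommodation, transport and return
    phases from gravity-compensated acceleration and sagittal-plane
    orientation; computes spatio-temporal metrics (movement units,
    straightness index, accelerometer activity counts, velocity statistics);
    unwraps omnidirectional hyperbolic-mirror frames into metric panoramas of
    the grasping hand and segments skin by K-means clustering in CIELAB
    chroma to quantify grasp contact area. Includes a fully seeded synthetic
    trial and frame generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
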