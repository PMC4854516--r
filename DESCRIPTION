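Package: wormbend
Title: Worm Posture, Head-Bending Amplitude and Resistive-Force-Theory
    Locomotion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of C. elegans head-bending behaviour from
    single-worm movies: centerline extraction and signed curvature kymographs
    from binary masks, head-bending amplitude (the temporal standard
    deviation of anterior curvature), an ellipse-orientation bending index
    for microfluidic recordings, min-max normalised calcium trace extraction,
    behaviour-calcium cross-correlation with a signed peak statistic, and a
    resistive-force-theory analysis of forward locomotion linking the angle
    of attack to propulsion efficiency, including a least-squares fit of the
    drag-coefficient ratio certified against a numerical force-balance
    oracle. A synthetic-data module generates worm movies, coupled calcium
    traces and locomotion bouts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
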