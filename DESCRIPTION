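Package: saemorph
Title: Shape-Adjusted Ellipse Morphometry of Nerve Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tilt-corrected nerve-fiber morphometry from segmented
    cross-section contours. Recovers the minor diameter of the unique
    ellipse matching a contour's measured area and perimeter
    (shape-adjusted ellipse, SAE), correcting the size overestimation
    caused by oblique sectioning of cylindrical fibers. Includes polygon
    contour measurement (shoelace area, perimeter, centroid,
    rotating-calipers Feret diameters), circularity shape descriptors,
    Hungarian-assignment pairing of axon and fiber contours for G-ratio
    and myelin thickness, traditional diameter comparators (minimum
    Feret, area-circle, perimeter-circle), a synthetic tilted-cylinder
    population generator for validation, population-level size
    distributions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
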