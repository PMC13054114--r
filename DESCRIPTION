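Package: nanoloc
Title: Intracellular Nanoparticle Localization and Morphometry from Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the intracellular localization of fluorescently
    labelled nanoparticles in multichannel confocal images. Segments nuclei,
    cell areas and particle-positive pixels, computes the exact Euclidean
    distance of every intracellular particle pixel to the nearest nucleus,
    converts distances to microns and summarizes them into perinuclear
    (0-5 um), intermediate (5-10 um) and peripheral (>10 um) fractions per
    image and condition. Also provides ImageJ-style particle morphometry
    (equivalent diameter, Crofton circularity) for dry-state micrographs,
    plasmids-per-particle payload arithmetic with a matched-mass
    loading-by-dosage dose design, and a ground-truthed synthetic scene and
    micrograph generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
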