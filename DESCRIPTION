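Package: gelwell
Title: Diffusion-Coalescence Kinetics and Image Quantification for DNA
    Hydrogel Particles in Microwell ATPS Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the growth of DNA nanostar (Y-motif) hydrogel particles
    inside dextran-rich droplets of a dextran/PEG aqueous two-phase system
    confined in cylindrical microwells. A two-equation kinetic model couples
    diffusive loss of unbound motifs through the dextran-PEG interface
    (Fick flux through a thin interfacial layer) with Smoluchowski
    coalescence into a single aggregate, and converts the gelled motif count
    to a compaction-corrected particle radius. The package also classifies
    particle wetting at the dextran-PEG interface from pairwise interfacial
    tensions, generates two-channel synthetic confocal images of microwell
    arrays with machine-readable ground truth, and quantifies droplet and
    particle size distributions from such images by global thresholding,
    connected-component labelling and area-to-radius conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
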