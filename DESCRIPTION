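Package: voxcube
Title: Voxel-Cube Quantification of Multichannel 3-D Confocal Co-Culture Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies and discriminates cancer-cell and fibroblast
    populations in multichannel 3-D confocal stacks of scaffold-free
    co-cultures.  Stacks are segmented on the nuclear (DAPI) channel by
    anisotropic Gaussian smoothing followed by Otsu thresholding, partitioned
    into non-overlapping 32 x 32 x 16 voxel cubes, and summarised as
    per-cube mean foreground intensities per channel.  A mono-culture
    derived carcinoembryonic antigen (CEA) reference threshold splits cubes
    into putative cancer and fibroblast compartments; further tools provide
    fluorescence-per-cubic-micrometre summaries, Costes-style randomised
    colocalization testing, 2-D region-of-interest quantification, and a
    seeded synthetic stack generator with per-voxel ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
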