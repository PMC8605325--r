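Package: mnlamina
Title: Micronucleus Nuclear-Lamina Image Quantification and Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline linking micronucleus (MN) chromosome
    content to nuclear-lamina organization and membrane rupture in
    super-resolution fluorescence stacks. Implements steerable-filter ridge
    detection with non-maximum suppression for lamin meshwork segmentation,
    Brenner best-focus equatorial splitting and hemisphere projection, lamina
    gap calling with area and intensity filters, micronucleus morphometry
    (minimum-volume enclosing ellipsoid, convex hull, sphere-equivalent
    surface area), rim-based lamin B1 intensity with background subtraction,
    photometric rupture and FISH scoring, nucleoporin spot counting,
    lamina-associated-domain (LAD) coverage per chromosome from BED interval
    files, and the accompanying statistical policy (family tests gating
    Barnard's unconditional exact test, phi coefficient, Spearman rank
    correlation, chi-square post-hoc power). A synthetic image generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    tiff,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    methods,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
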