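Package: mswmscore
Title: Preoperative Resection Scoring for Medial Sphenoid Wing Meningiomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a preoperative radiologic scoring pipeline for medial
    sphenoid wing meningiomas. From co-registered 3D label masks (tumor, named
    arterial segments C4/C5/M1/M2/A1/A2, cavernous sinus, skull) it measures
    tumor volume, circumferential arterial encasement (angular coverage around
    extracted vessel centerlines), lumen narrowing, cavernous sinus
    infiltration and bone invasion; combines them into a 1-10 point score; and
    maps the score to a predicted Simpson resection band. A statistics battery
    (Kruskal-Wallis and chi-square by resection grade, proportional-odds
    adjusted odds ratios, Spearman correlations, linear discriminant
    resubstitution accuracy) validates the score on cohort tables. Synthetic
    3D phantoms with analytically known ground truth and an ordinal cohort
    simulator make the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
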