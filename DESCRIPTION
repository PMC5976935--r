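Package: ctmort
Title: Opportunistic CT Biomarkers and Matched Mortality Modelling for
    Lung Cancer Screening Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies four opportunistic biomarkers from low-dose chest
    CT in Hounsfield units: coronary artery calcification by 130 HU
    threshold pixel counting inside a circular heart region of interest,
    emphysema as the fraction of lung voxels below -950 HU, pectoralis
    muscle area and attenuation at a user-selected T3-level slice, and
    subcutaneous fat attenuation in the -120 to -60 HU window.  Builds
    survivor/nonsurvivor cohorts from screening rosters with
    variance-normalised optimal 1:1 matching stratified on stage and
    gender, and fits multivariate logistic and Cox proportional-hazards
    mortality models.  Ships synthetic thorax phantoms and roster
    generators with exact, enumerated ground truth so that every imaging
    and matching operation is testable without restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
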