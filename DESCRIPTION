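Package: cryptArch
Title: Quantitative Grading of Crypt Architectural Distortion in Colonic Biopsies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated quantitative assessment of mucosal damage in inflammatory
    bowel disease from microscopy images of colonic biopsies. Crypt outlines and
    the muscularis mucosa are localized with a greedy active-contour (snake)
    procedure; eleven normalized morphometric features are extracted per image
    (nine Fourier-descriptor magnitudes of crypt shape, the minimum-spanning-tree
    inter-crypt spacing, and the regression-based crypt-base to muscularis
    distance) and classified into Normal or IBD grades I-III with a probabilistic
    neural network. A grade-parameterized synthetic image generator with exact
    ground truth supports validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, grDevices, tools, EBImage, png, jsonlite
Suggests: testthat (>= 3.0.0), tiff
biocViews: ImageAnalysis, Classification, Pathology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
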