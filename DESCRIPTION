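Package: octoneclass
Title: One-Class Classification of Skin Tissue in OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects abnormal skin tissue in optical coherence tomography (OCT)
    B-scans using a one-class strategy: a small U-Net is trained to segment
    normal skin into air, stratum corneum, epidermis and dermis; its last
    decoder activations serve as per-pixel features; pooled feature vectors
    train a one-class support vector machine on normal tissue only, whose
    signed prediction score flags anomalies and, along a lateral scan,
    localizes normal/abnormal boundaries after wavelet denoising. Includes a
    synthetic layered-skin phantom generator with speckle and three synthetic
    abnormality operators (basal-cell-carcinoma-like attenuation,
    squamous-cell-carcinoma-like bright regions, dermis-epidermis-junction
    disruption) so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
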