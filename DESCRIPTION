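Package: echopvr
Title: Noninvasive Echocardiographic Screening of Elevated Pulmonary
    Vascular Resistance in CTEPH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating Doppler-echocardiographic surrogates of
    pulmonary vascular resistance (PVR) in chronic thromboembolic pulmonary
    hypertension (CTEPH).  Computes pressure/diameter screening indices
    (sPAP_Echo/LVIDd, mPAP_Echo/LVIDd, TRV^2/TVI_RVOT) from raw Doppler and
    M-mode measurements via the simplified Bernoulli relation, derives
    invasive PVR from right-heart-catheterization records, and provides the
    full diagnostic-evaluation pipeline: Spearman correlation against
    invasive PVR, empirical ROC curves with Youden-optimal cutoffs, the
    DeLong test for correlated AUCs, paired pre/post-endarterectomy
    comparisons, and intraclass-correlation reproducibility.  A calibrated
    synthetic CTEPH cohort generator with physiologic couplings and
    realistic signal missingness makes every pipeline stage testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
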