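Package: mcri
Title: Multidimensional Clinical Response Index for Persistent Spinal Pain
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction, scoring and anchor-based evaluation of the
    Multidimensional Clinical Response Index (MCRI), a [0,10] composite
    outcome for persistent spinal pain syndrome after spinal surgery.
    Builds the index from raw questionnaire items (EQ-5D-5L, ODI, HADS),
    the numeric pain rating scale and intensity-weighted pain-map
    surfaces: exploratory factor analysis with principal-axis factoring
    and promax rotation, Bartlett factor scores, correlation-matrix
    principal components, and PGIC-anchored ROC and cutoff analysis with
    the Jonckheere-Terpstra trend test. Includes a longitudinal synthetic
    cohort generator emulating the statistical structure of the
    derivation study so the whole pipeline can be exercised without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
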