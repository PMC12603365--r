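Package: tmtstroke
Title: Sarcopenia and Functional Outcome Analysis in Acute Ischaemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking low temporal muscle thickness (TMT), an
    imaging surrogate of sarcopenia, to outcomes after acute ischaemic stroke
    in elderly patients. Derives dysphagia, early neurological deterioration
    (END) and period-specific recovery flags from raw registry records;
    estimates crude and covariate-adjusted odds ratios with maximum-likelihood
    and Firth-penalized logistic regression; decomposes the TMT effect on
    functional outcome through multiple mediators with bootstrap intervals;
    and maps region-of-interest lesion-by-TMT effect modification across
    merged brain atlases. Includes a synthetic-cohort and toy-lesion
    generator so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
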