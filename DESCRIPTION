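Package: connres
Title: Resilience of Functional Brain Networks to Virtual Stroke Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional connectomes from region-level BOLD time series
    (detrending, nuisance regression, winsorization, wavelet sub-band
    filtering, Pearson correlation), maps voxel-level lesion masks onto atlas
    regions by the 50 percent overlap rule, simulates recurrent strokes by
    deleting lesioned regions from the connectome, and quantifies network
    resilience of global efficiency, fixed-partition modularity and mean
    clustering via a normalized pre/post-attack statistic computed on the
    area under metric-versus-density curves. Includes a participation
    coefficient hub-redistribution analysis with exponentiated-Weibull
    distribution fitting, mixed-effects group statistics with
    Benjamini-Hochberg correction, and a synthetic-cohort generator
    (modular connectomes, BOLD-like series, virtual-lesion libraries)
    so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    emmeans,
    MASS,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
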