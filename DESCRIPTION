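Package: dmapcv
Title: Diffusion Maps, Committor Functions, and Collective-Variable
    Assessment for Molecular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyse reaction dynamics in molecular-dynamics trajectories with
    diffusion maps. Builds local and global diffusion-map kernels (constant,
    alpha-normalized, energy-weighted, locally scaled) from internal
    coordinates or aligned Cartesians, monitors quasi-stationarity of a
    trajectory by tracking the leading eigenvalues of the approximate
    Kolmogorov generator, ranks candidate collective variables (internal
    coordinates and principal components) by their Pearson correlation with
    the diffusion coordinates, solves the discrete committor boundary-value
    problem on the sampled graph, and projects potential-energy surfaces
    around a transition state. Ships overdamped-Langevin synthetic systems
    with analytic committors and generator spectra that serve as oracles for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
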