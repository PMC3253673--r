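Package: activegel
Title: Brownian Dynamics of Confined Filament-Motor Active Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained simulator and analysis toolkit for mixtures of
    semiflexible polar filaments and two-headed motor proteins confined to a
    pressurised quasi-two-dimensional cylindrical box. Filaments are
    bead-spring chains with curvature elasticity and WCA excluded volume,
    evolved by overdamped Brownian dynamics with anisotropic (2:1) slender-body
    drag; motors are Hookean springs with stochastic attachment, detachment and
    plus-end directed stepping handled by kinetic Monte Carlo; the confining
    elastic wall equilibrates against an external pressure by Metropolis Monte
    Carlo with a pressure-volume term. The analysis layer quantifies the
    emergent states (aster, semi-aster, spindle, nematic, vortex) through
    angular Fourier mode amplitudes of the polarity field, nearest-target state
    classification, vorticity order parameters, hyperbolic-tangent contraction
    fits, mean-squared angular displacement and distributional tests of
    contraction and switching times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
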