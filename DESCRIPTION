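Package: agestructrd
Title: Infection-Age-Structured Reaction-Diffusion Epidemic Models
Version: 0.1.0
Authors@R:
    person("agestructrd", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Numerical tools for a susceptible/infected compartment model in
    which infected individuals are structured by infection age and both
    compartments move by spatial diffusion, with logistic growth of the
    susceptibles and a renewal (age-zero) boundary condition for new
    infections.  Provides a positivity-preserving simulator based on the
    method of characteristics with implicit diffusion, finite-difference
    Laplacians for Dirichlet and Neumann boundary conditions, computation of
    trivial, disease-free and endemic steady states, the basic reproduction
    number as the spectral radius of a next-generation operator, spectral
    bounds via monotone bisection, and linear stability classification of
    steady states through a per-mode characteristic equation and a discrete
    linearization matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
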