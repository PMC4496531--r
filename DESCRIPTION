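Package: snfield
Title: Simulation and Numerical Verification of Stochastic Neural Field
    Equations with Spatially Correlated Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the stochastic neural field equation, a
    nonlocal integro-differential equation for cortical activity driven by
    Gaussian noise that is white in time and correlated in space.  Provides
    the standard connectivity kernels (Gaussian, Mexican hat, exponential,
    anisotropic long-range with orientation maps), numerical checks of the
    kernel admissibility conditions that underlie well-posedness on plain
    and weighted L2 spaces, two constructions of the integrable weight
    function (Fourier deconvolution for homogeneous kernels and power
    iteration for compact integral operators), generators for spatially
    smoothed space-time white noise and truncated Q-Wiener processes with
    their exact covariance functions, an exponential Euler integrator of
    the mild-solution equation together with a path-space Picard iteration
    used as a scheme-independent oracle, and Monte Carlo diagnostics for
    the Ito isometry, stationary covariance, moment boundedness and
    Holder-regularity exponents of the simulated fields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
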