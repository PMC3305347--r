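Package: bulbgenesis
Title: Adult Neurogenesis and Pattern Decorrelation in an Olfactory-Bulb
    Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator of structural plasticity in a recurrent
    mitral-granule cell network of the olfactory bulb. Inhibitory granule
    cells are persistently added with random reciprocal connections and
    removed with a probability that decreases sigmoidally with their
    thresholded activity summed over a stimulus ensemble (their
    "resilience"). The surviving connectivity develops lateral inhibition
    between co-active mitral cells and thereby decorrelates the bulbar
    representations of highly similar stimuli. Includes synthetic
    glomerular-pattern generators, steady-state solvers (linear and
    threshold-linear), connectivity perturbations probing imperfect
    synaptic reciprocity, a mean-field population model with phase-plane
    analysis and closed-form fixed points for a symmetric four-glomerulus
    caricature, and scripted in-silico experiments (decorrelation,
    novelty response of young granule cells, perceptual learning, and
    odor-enrichment protocols).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
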