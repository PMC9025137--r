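Package: myocolor
Title: Reaction-Diffusion and Gompertz Models of Myoglobin-Driven Meat
    Color in Cold Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts oxidative browning of fresh beef surfaces during
    refrigerated storage with two complementary models: a one-dimensional
    mass-action reaction-diffusion model of myoglobin redox chemistry with
    oxygen diffusing in from the package headspace and Arrhenius scaling of
    the rate constants, and a Gompertz phenomenological model of the CIELAB
    redness coordinate a*. Surface myoglobin composition is mapped to
    normalized redness a*/a*0 through a threshold on the MbO2/(MMb + Mb)
    ratio. Includes staged least-squares identification of the color
    threshold S and the activation energy Ea, ordinary least-squares
    regressions of the Gompertz lag and maximum rate on storage factors,
    and a synthetic storage-experiment generator built on a four-factor
    three-level definitive screening design so the full analysis is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
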