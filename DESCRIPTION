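Package: ufdfmonitor
Title: Kalman-Filtered In-Line Monitoring of Ultra- and Diafiltration Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time monitoring of protein ultrafiltration/diafiltration (UF/DF)
    from in-line sensor streams. Implements a semi-mechanistic buffer-exchange
    model (continuously stirred tank with an empirical sieving coefficient)
    inside a three-state extended Kalman filter that estimates the decaying
    buffer signal, the buffer-exchange rate and the terminal signal offset from
    noisy scalar inputs; the chemometric chain that feeds it (exposure
    normalization, asymmetric Whittaker baseline, Savitzky-Golay smoothing,
    mean-centered PLS protein-concentration models with Hotelling T2/Q outlier
    rejection, PCA buffer-exchange scores); density temperature and
    protein-concentration corrections; and a synthetic multi-sensor UF/DF
    process simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    digest,
    jsonlite,
    minpack.lm,
    mixOmics,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
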