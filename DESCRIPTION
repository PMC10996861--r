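Package: smsvoice
Title: Cepstral Peak Prominence Screening of Smith-Magenis Syndrome Voices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for non-invasive screening of Smith-Magenis syndrome
    (SMS) from sustained-vowel recordings using a single acoustic measure,
    the cepstral peak prominence (CPP). Implements smoothed CPP extraction
    from audio frames, prime-based windowing of variable-length per-speaker
    CPP streams into fixed-width samples, SMOTE balancing of training folds,
    a uniform interface over four supervised classifiers (random forest,
    support vector machine, linear discriminant analysis, k-nearest
    neighbours), a leave-one-speaker-out evaluation protocol with repeated
    iterations, and pairwise Mann-Whitney rank-sum comparison of methods.
    Ships synthetic sustained-vowel and synthetic cohort generators so the
    whole pipeline is exercisable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    graphics,
    jsonlite,
    MASS,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
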