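Package: porewatch
Title: Incremental Quality-Control Monitoring for Nanopore Sequencing Runs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time quality control for Oxford Nanopore sequencing
    experiments from the basecaller's sequencing summary files. Tails growing
    guppy 'sequencing_summary.txt' files from a persisted byte-offset
    checkpoint, classifies reads, and maintains mergeable per-run accumulators
    from which windowed, cumulative, per-channel and distributional statistics
    (yield, read length, mean q-score, translocation speed) are derived and
    emitted as small plot-ready TSV files plus a flowcell registry. Includes a
    polling watcher, a multi-run comparison layer, and a synthetic run
    generator with known ground truth (speed decay and refuel recovery) for
    end-to-end testing without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
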