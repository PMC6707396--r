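Package: linksetr
Title: Network Extension with Versioned Linksets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build, read and write versioned "linksets" (collections of typed,
    directed links between identified entities, stored in an XGMML dialect),
    extend arbitrary attributed networks with linkset interactions by matching
    node identifiers with direction control, filter the added interactions by
    cross-linkset support, and summarize, lay out and style the result. Includes
    deterministic synthetic-fixture generators and a command-line interface, so
    complete extension workflows run headlessly and reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
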