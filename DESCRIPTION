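Package: evosig
Title: In Silico Evolution of Allosteric Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves biochemical signaling networks in silico. Networks of
    multi-domain allosteric proteins are encoded on a binary-string genome;
    a rule-based compiler translates the genome into an explicit mass-action
    reaction network with two-state (Monod-Wyman-Changeux) conformational
    dynamics; stimulus protocols and fitness functions score ultrasensitive
    and adaptive input-output behaviour; and two evolutionary engines (a
    Kimura fixation-probability random walk and a fixed-size Wright-Fisher
    population) drive the genome through mutation operators that include
    point mutation, gene and domain duplication and deletion, domain
    shuffling, genome rearrangement and horizontal gene transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
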