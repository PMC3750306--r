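Package: bclgate
Title: Logic-Gate Analysis of a Bcl-2 Family Apoptotic Switch Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator and analysis toolkit for a minimal
    mass-action model of the mitochondrial (Bcl-2 family) apoptotic decision
    module. The model tracks eleven molecular species (Bax mRNA, Bax, Bcl-xL,
    Bad, scaffold 14-3-3, pro-caspases and caspases, and their complexes)
    driven by two exogenous inputs, apoptosis-competent p53 and
    unphosphorylated Akt. Tools are provided to locate the saddle-node
    bifurcation of the caspase switch, compute resting and stimulated steady
    states of the Bcl-2 subsystem, classify survive-versus-apoptosis fates
    and emergent Boolean gate types (OR, AND, AND*) as functions of total Bad
    and Bcl-xL, scan the input plane and pool-level axes, and determine
    minimal stimulus durations that commit a cell to apoptosis under
    transient stimulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
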