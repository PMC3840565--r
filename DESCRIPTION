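Package: synmapr
Title: Comparative Genome Mapping and Conserved Synteny Detection for Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome comparative mapping of a draft (scaffold-level)
    genome against fully sequenced model species. Scaffolds are anchored to a genetic
    linkage map through a marker -> BAC -> physical-map-contig -> anchor-sequence
    evidence chain; homologous genes are called from filtered protein-alignment hit
    tables with a best-hit interval rule; homologous chromosomes are assigned from an
    Oxford-grid gene-sharing matrix; and conserved syntenic blocks are detected as
    runs of adjacent model-chromosome genes co-located in single scaffolds, with
    per-linkage-group summary statistics (counts, spans, N50). A seeded
    genome-rearrangement simulator (fusions, fissions, inversions, translocations,
    gene loss, noisy hit tables) provides ground-truthed inputs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
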