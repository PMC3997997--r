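Package: mirnod
Title: MicroRNA Biomarker Screening from Exclusive-Target Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies candidate microRNA disease biomarkers by combining
    case/control differential expression with the structure of a union
    miRNA-mRNA interaction network. Each miRNA is scored by its novel out
    degree (NOD), the number of genes it targets exclusively, and candidates
    are ranked by NOD with a signed-rank significance test, evaluated by
    ROC/AUC, characterized by hypergeometric gene-set enrichment of their
    exclusive targets, and expanded into one-hop protein-interaction
    subnetworks. Includes a synthetic-data generator that emulates all
    pipeline inputs with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
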