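Package: hifnet
Title: Structural Analysis of Signaling-Pathway Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed pathway networks from KEGG KGML documents, Pajek
    .net files and TSV edge lists, and analyses their structure: topology
    indicators (density with and without self-loops, average degree, diameter,
    mean geodesic distance), degree, closeness and betweenness centrality under
    directed conventions, weak-component decomposition with core-subnetwork
    extraction, bow-tie macrostructure classification via strongly connected
    components, and scale-free analysis of the degree distribution by
    continuous-approximation maximum likelihood with Kolmogorov-Smirnov
    threshold selection and a semi-parametric bootstrap goodness-of-fit test.
    Ships generators for synthetic pathway data with known ground truth,
    including a synthetic snapshot of the HIF-1 signaling-pathway network that
    reproduces its published summary structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
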