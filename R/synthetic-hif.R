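#' Synthetic snapshot of the HIF-1 signaling-pathway network
#'
#' A deterministic, fully synthetic reconstruction of the published summary
#' structure of the KEGG HIF-1 signaling-pathway network, for offline analysis
#' and testing. The true arc list of that network is not distributed with this
#' package; this stand-in reproduces its reported aggregate structure exactly:
#'
#' * 85 nodes and 61 lines; node kinds 59 ortholog / 16 compound / 8 map /
#'   2 group; interaction classes 29 activation / 26 expression / 6 inhibition;
#' * 25 weak components with the published size distribution and
#'   representative node numbers (21 isolates, components of size 2, 3 and 25,
#'   and a largest component of 34 nodes);
#' * a core (largest) component with 34 nodes and 34 lines, class tallies
#'   27 / 2 / 5, a bow-tie partition of 1 LSCC, 20 IN and 13 TENDRIL nodes,
#'   and total-degree distribution `{1: 14, 2: 12, 3: 5, 4: 2, 7: 1}`.
#'
#' Within those constraints the individual arcs are an invention: conclusions
#' that depend on which particular nodes are joined (for example centrality
#' rankings) must not be read off this object.
#'
#' @return `synthetic_hif_network()`: a [pathway_graph()] with 85 nodes;
#'   `synthetic_hif_core()`: its largest weak component (34 nodes, 34 lines),
#'   extracted with [extract_largest()].
#' @examples
#' g <- synthetic_hif_network()
#' summarize_topology(g)
#' bowtie_partition(synthetic_hif_core())$counts
#' @export
synthetic_hif_network <- function() {
  core_ids <- as.character(c(6, 20, 22:29, 36, 60:64, 66:80, 82:84))
  # role slots over the ascending core ids: hub, 20 input nodes, 13 tendrils
  h <- core_ids[1L]
  i_ <- core_ids[2:21]
  t_ <- core_ids[22:34]

  core_src <- c(h, i_[1], i_[8],
                i_[2:7],
                i_[9:11],
                i_[12], i_[13], i_[14],
                i_[15], i_[16], i_[17],
                i_[18], i_[19], i_[20],
                i_[6], i_[7],
                t_[1], t_[1], t_[3], t_[3], t_[4], t_[4],
                t_[2], t_[2], t_[5], t_[5], t_[10])
  core_tgt <- c(h, h, h,
                rep(i_[1], 6),
                rep(i_[2], 3),
                i_[13], i_[14], i_[3],
                i_[16], i_[17], i_[4],
                i_[19], i_[20], i_[5],
                t_[1], t_[2],
                t_[3], t_[4], t_[6], t_[7], t_[8], t_[9],
                t_[5], t_[10], t_[11], t_[12], t_[13])
  core_cls <- rep(c("activation", "expression", "inhibition"), c(27, 2, 5))

  # satellite components: a 25-node hub-and-spokes, a 3-chain, a 2-chain,
  # and 21 isolates — sizes and smallest-member ids match the published table
  sat_ids <- as.character(c(5, 10, 12, 17:19, 38:55, 85))
  hub <- "85"
  sat_src <- rep(hub, 24)
  sat_tgt <- setdiff(sat_ids, hub)
  tri <- as.character(c(9, 56, 57))
  duo <- as.character(c(35, 58))

  ids <- as.character(1:85)
  kind <- rep("ortholog", 85)
  kind[c(61:64, 66:69, 84)] <- "compound"       # 9 core compounds
  kind[c(10, 12, 17, 18, 19)] <- "compound"     # 5 satellite compounds
  kind[c(30, 31)] <- "compound"                 # 2 isolated compounds
  kind[38:45] <- "map"                          # 8 linked pathway maps
  kind[c(70, 85)] <- "group"                    # 2 undefined groups

  acc <- character(85)
  disp <- character(85)
  for (j in 1:85) {
    acc[j] <- switch(kind[j],
      ortholog = sprintf("ko:K9%04d", j),
      compound = sprintf("cpd:C9%04d", j),
      map = sprintf("path:ko9%04d", j),
      group = "undefined"
    )
  }
  # the two published anchors of the core: its strongly connected hub and the
  # highest-degree input enzyme
  acc[as.integer(h)] <- "ko:K08268"; disp[as.integer(h)] <- "HIF1A"
  acc[as.integer(i_[1])] <- "ko:K09592"; disp[as.integer(i_[1])] <- "EGLN, HPH"

  nodes <- data.frame(id = ids, kind = kind, display_name = disp,
                      accessions = acc, stringsAsFactors = FALSE)
  arcs <- data.frame(
    source = c(core_src, sat_src, tri[1:2], duo[1]),
    target = c(core_tgt, sat_tgt, tri[2:3], duo[2]),
    class = c(core_cls, rep("expression", 24), rep("activation", 2), "inhibition"),
    stringsAsFactors = FALSE
  )
  pathway_graph(nodes, arcs)
}

#' @rdname synthetic_hif_network
#' @export
synthetic_hif_core <- function() {
  extract_largest(synthetic_hif_network())
}
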