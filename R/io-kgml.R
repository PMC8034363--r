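#' Parse a KGML pathway document into a pathway graph
#'
#' Reads a KEGG Markup Language (KGML) document and converts it to a
#' [pathway_graph()]. Each `<entry>` becomes one node (an entry listing several
#' accessions in its `name` attribute stays a single node); entry types map as
#' ortholog/gene -> ortholog, compound -> compound, map -> map, group -> group,
#' anything else -> undefined. Each `<relation>` yields an arc
#' `entry1 -> entry2`; relation subtypes map as activation -> activation,
#' expression -> expression, inhibition/repression -> inhibition, all others ->
#' other. A relation carrying a `compound` subtype is routed through the named
#' compound node as two arcs (`entry1 -> compound`, `compound -> entry2`) when
#' that compound entry exists in the document. `<reaction>` elements
#' (substrate/product semantics of true metabolic maps) become
#' compound-mediated arcs of class `other`: substrate -> enzyme entry ->
#' product, both directions for reversible reactions.
#'
#' @param x Path to a KGML file, or a single string containing the XML text.
#' @return A [pathway_graph()].
#' @examples
#' doc <- paste0(
#'   '<pathway name="path:ko00000" title="demo">',
#'   '<entry id="1" name="ko:K00001" type="ortholog"/>',
#'   '<entry id="2" name="ko:K00002" type="ortholog"/>',
#'   '<relation entry1="1" entry2="2" type="PPrel">',
#'   '<subtype name="activation" value="--&gt;"/></relation></pathway>'
#' )
#' parse_kgml(doc)
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x), error = function(e) {
    stop("malformed KGML document: ", conditionMessage(e), call. = FALSE)
  })
  root <- xml2::xml_find_first(doc, "/*")
  if (xml2::xml_name(root) != "pathway") {
    stop("malformed KGML document: root element is <", xml2::xml_name(root),
         ">, expected <pathway>")
  }

  entries <- xml2::xml_find_all(root, "./entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  ename <- xml2::xml_attr(entries, "name")
  gname <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    if (inherits(g, "xml_missing")) "" else xml2::xml_attr(g, "name") %||% ""
  }, character(1))
  gname[is.na(gname)] <- ""
  kind <- .kgml_kind(etype)
  nodes <- data.frame(id = eid, kind = kind, display_name = gname,
                      accessions = ifelse(is.na(ename), "", ename),
                      stringsAsFactors = FALSE)

  src <- character(0); tgt <- character(0); cls <- character(0)
  add_arc <- function(s, t, k) {
    src[[length(src) + 1L]] <<- s
    tgt[[length(tgt) + 1L]] <<- t
    cls[[length(cls) + 1L]] <<- k
  }

  relations <- xml2::xml_find_all(root, "./relation")
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    if (!(e1 %in% eid) || !(e2 %in% eid)) {
      stop(sprintf("relation %s -> %s references a missing entry", e1, e2))
    }
    subs <- xml2::xml_find_all(rel, "./subtype")
    snames <- xml2::xml_attr(subs, "name")
    svals <- xml2::xml_attr(subs, "value")
    k <- .kgml_class(snames)
    cpd <- svals[which(snames == "compound")]
    routed <- FALSE
    if (length(cpd)) {
      cpd <- cpd[1L]
      if (!is.na(cpd) && cpd %in% eid) {
        add_arc(e1, cpd, k)
        add_arc(cpd, e2, k)
        routed <- TRUE
      }
    }
    if (!routed) add_arc(e1, e2, k)
  }

  reactions <- xml2::xml_find_all(root, "./reaction")
  for (rx in reactions) {
    rid <- xml2::xml_attr(rx, "id")
    if (!(rid %in% eid)) {
      stop(sprintf("reaction %s references a missing entry", rid))
    }
    rev <- identical(xml2::xml_attr(rx, "type"), "reversible")
    for (s in xml2::xml_attr(xml2::xml_find_all(rx, "./substrate"), "id")) {
      if (!(s %in% eid)) stop(sprintf("reaction %s substrate %s is not an entry", rid, s))
      add_arc(s, rid, "other")
      if (rev) add_arc(rid, s, "other")
    }
    for (p in xml2::xml_attr(xml2::xml_find_all(rx, "./product"), "id")) {
      if (!(p %in% eid)) stop(sprintf("reaction %s product %s is not an entry", rid, p))
      add_arc(rid, p, "other")
      if (rev) add_arc(p, rid, "other")
    }
  }

  arcs <- data.frame(source = src, target = tgt, class = cls,
                     stringsAsFactors = FALSE)
  pathway_graph(nodes, arcs)
}

.kgml_kind <- function(type) {
  out <- rep("undefined", length(type))
  out[type %in% c("ortholog", "gene")] <- "ortholog"
  out[type == "compound"] <- "compound"
  out[type == "map"] <- "map"
  out[type == "group"] <- "group"
  out
}

# interaction class of a relation from its ordered subtype list: the first
# subtype that maps to a named class wins; no mappable subtype -> "other"
.kgml_class <- function(subtype_names) {
  for (s in subtype_names) {
    if (is.na(s)) next
    if (s == "activation") return("activation")
    if (s == "expression") return("expression")
    if (s %in% c("inhibition", "repression")) return("inhibition")
  }
  "other"
}
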