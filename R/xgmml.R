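# Cytoscape-compatible XGMML serialization (2.8-era dialect: typed <att>
# elements plus <graphics> children) and the matching reader used for
# round-trip testing.

.XGMML_NS <- "http://www.cs.rpi.edu/XGMML"

# node attribute name <-> column mapping (names standardized for Cytoscape)
.NODE_ATTS <- c("Node Type" = "kind", "Organism" = "organism",
                "Symbol" = "symbol", "Seed" = "seed", "Bait" = "bait",
                "Level" = "level", "Selected CC" = "cc",
                "Fold Change" = "fold_change", "Regulation" = "regulation",
                "Degree" = "degree", "P-value" = "p_value",
                "Z Raw" = "z_raw", "Z Std" = "z_std",
                "Top Enriched BP" = "top_bp", "Top Enriched KEGG" = "top_kegg")
.EDGE_ATTS <- c("Evidence" = "evidence", "Publications" = "pmids",
                "N Publications" = "n_pubs",
                "Methods" = "methods", "Sources" = "sources",
                "Class" = "class_label", "Class Score" = "class_total",
                "FSW" = "fsw", "Novel" = "novel")

.att_type <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "integer"
  else if (is.numeric(x)) "real"
  else "string"
}

.att_fmt <- function(v) {
  if (is.logical(v)) ifelse(v, "true", "false")
  else if (is.double(v)) sprintf("%.17g", v)
  else as.character(v)
}

.add_atts <- function(parent, row, mapping) {
  for (nm in names(mapping)) {
    v <- row[[mapping[[nm]]]]
    if (is.null(v) || (length(v) == 1L && is.na(v) && !is.logical(v))) next
    xml2::xml_add_child(parent, "att", name = nm, type = .att_type(v),
                        value = .att_fmt(v))
  }
}

#' Write a network to XGMML
#'
#' Produces well-formed UTF-8 XML with one `graph` element, one `node`
#' element per entity (typed `att` children plus a `graphics` child with
#' shape, fill color and size) and one `edge` per pair (atts plus a
#' `graphics` width taken from the Class score: A 2.5, B 2.0, C 1.5,
#' D 1.0, E/unclassified 0.5).  Element order is deterministic (nodes then
#' edges, each sorted by id / canonical pair key), so repeated writes of
#' the same network are byte-identical.
#'
#' @param net A `pmd_network`.
#' @param path Output path.
#' @param label Graph label.
#' @return Invisibly, `path`.
#' @export
write_xgmml <- function(net, path, label = "pmdnet network") {
  doc <- xml2::xml_new_root("graph", label = label, directed = "0",
                            xmlns = .XGMML_NS)
  nodes <- net$nodes[order(net$nodes$id), , drop = FALSE]
  edges <- net$edges[order(net$edges$pair), , drop = FALSE]
  idnum <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(nodes))) {
    row <- nodes[i, , drop = FALSE]
    nd <- xml2::xml_add_child(doc, "node", id = as.character(idnum[[row$id]]),
                              label = row$id)
    .add_atts(nd, row, .NODE_ATTS)
    size <- if (is.na(row$size)) 20 else row$size
    xml2::xml_add_child(nd, "graphics", type = row$shape, fill = row$color,
                        w = sprintf("%.17g", size), h = sprintf("%.17g", size))
  }
  for (i in seq_len(nrow(edges))) {
    row <- edges[i, , drop = FALSE]
    ed <- xml2::xml_add_child(doc, "edge",
                              label = row$pair,
                              source = as.character(idnum[[row$id_a]]),
                              target = as.character(idnum[[row$id_b]]))
    .add_atts(ed, row, .EDGE_ATTS)
    xml2::xml_add_child(ed, "graphics", width = sprintf("%.17g", row$width),
                        fill = "#333333")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.parse_att_value <- function(value, type) {
  switch(type,
         integer = as.integer(value),
         real = as.numeric(value),
         boolean = identical(value, "true"),
         value)
}

#' Read an XGMML network
#'
#' Parses a file written by [write_xgmml()] (or structurally compatible).
#' Recognized attribute names map back onto network columns; unknown
#' `att` elements are preserved in the `extra_node_atts` /
#' `extra_edge_atts` attributes of the result.
#'
#' @param path XGMML file path.
#' @return A `pmd_network`.
#' @export
read_xgmml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("XGMML parse error in '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(x = .XGMML_NS)
  node_els <- xml2::xml_find_all(doc, "./x:node", ns)
  edge_els <- xml2::xml_find_all(doc, "./x:edge", ns)

  read_atts <- function(el) {
    atts <- xml2::xml_find_all(el, "./x:att", ns)
    nm <- xml2::xml_attr(atts, "name")
    ty <- xml2::xml_attr(atts, "type")
    va <- xml2::xml_attr(atts, "value")
    stats::setNames(Map(.parse_att_value, va, ty), nm)
  }

  extra_nodes <- list(); extra_edges <- list()
  idmap <- character()
  node_rows <- lapply(node_els, function(el) {
    label <- xml2::xml_attr(el, "label")
    if (is.na(label)) stop("XGMML parse error: node without label at ",
                           xml2::xml_path(el))
    idmap[[xml2::xml_attr(el, "id")]] <<- label
    atts <- read_atts(el)
    row <- list(id = label)
    for (nm in names(.NODE_ATTS)) {
      if (nm %in% names(atts)) row[[.NODE_ATTS[[nm]]]] <- atts[[nm]]
    }
    unknown <- atts[setdiff(names(atts), names(.NODE_ATTS))]
    if (length(unknown) > 0L) extra_nodes[[label]] <<- unknown
    g <- xml2::xml_find_first(el, "./x:graphics", ns)
    if (!inherits(g, "xml_missing")) {
      row$shape <- xml2::xml_attr(g, "type")
      row$color <- xml2::xml_attr(g, "fill")
      row$size <- as.numeric(xml2::xml_attr(g, "w"))
    }
    row
  })
  edge_rows <- lapply(edge_els, function(el) {
    src <- xml2::xml_attr(el, "source"); tgt <- xml2::xml_attr(el, "target")
    if (is.na(src) || is.na(tgt)) stop("XGMML parse error: edge missing ",
                                       "source/target at ", xml2::xml_path(el))
    if (!src %in% names(idmap) || !tgt %in% names(idmap)) {
      stop("XGMML parse error: edge references unknown node id at ",
           xml2::xml_path(el))
    }
    atts <- read_atts(el)
    row <- list(id_a = idmap[[src]], id_b = idmap[[tgt]])
    for (nm in names(.EDGE_ATTS)) {
      if (nm %in% names(atts)) row[[.EDGE_ATTS[[nm]]]] <- atts[[nm]]
    }
    unknown <- atts[setdiff(names(atts), names(.EDGE_ATTS))]
    if (length(unknown) > 0L) {
      extra_edges[[pair_id(row$id_a, row$id_b)]] <<- unknown
    }
    g <- xml2::xml_find_first(el, "./x:graphics", ns)
    if (!inherits(g, "xml_missing")) row$width <- as.numeric(xml2::xml_attr(g, "width"))
    row
  })

  to_df <- function(rows) {
    if (length(rows) == 0L) return(NULL)
    cols <- unique(unlist(lapply(rows, names)))
    out <- lapply(cols, function(cl) {
      vals <- lapply(rows, function(r) r[[cl]] %||% NA)
      non_na <- which(!vapply(vals, function(v) is.null(v) || all(is.na(v)), logical(1)))
      proto <- if (length(non_na) > 0L) vals[[non_na[[1]]]] else NA_character_
      vapply(vals, function(v) {
        if (is.null(v) || (length(v) == 1L && is.na(v))) {
          switch(class(proto)[1], character = NA_character_,
                 integer = NA_integer_, numeric = NA_real_, logical = NA, NA)
        } else v
      }, proto)
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  nodes <- to_df(node_rows)
  if (is.null(nodes)) nodes <- data.frame(id = character(), stringsAsFactors = FALSE)
  edges <- to_df(edge_rows)
  if (is.null(edges)) edges <- data.frame(id_a = character(), id_b = character(),
                                          stringsAsFactors = FALSE)
  net <- pmd_network(nodes, edges)
  attr(net, "extra_node_atts") <- extra_nodes
  attr(net, "extra_edge_atts") <- extra_edges
  net
}

#' Export a plain edge-list TSV (for diffing)
#' @param net A `pmd_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(net, path) {
  e <- net$edges[order(net$edges$pair),
                 c("id_a", "id_b", "class_label", "class_total", "width", "fsw"),
                 drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
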