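#' Build the bipartite compound-target network
#'
#' One compound node per screened compound (including compounds whose
#' candidate target set came back empty), one target node per distinct
#' target, and one edge per (compound, target) membership. Edges can be
#' weighted by the best supporting drug-similarity score.
#'
#' @param candidate_sets A \code{candidate_targets} object (or a named
#'   list compound -> character vector of targets).
#' @param hits Optional screening hit table used to weight each edge by
#'   the maximum supporting drug similarity.
#' @param compound_meta Optional data.frame of per-compound metadata
#'   (column \code{id} plus e.g. herb, kind, cluster) attached to nodes.
#' @return A \code{ctn}: list with \code{nodes} (id, type) and
#'   \code{edges} (compound, target, weight).
#' @export
build_network <- function(candidate_sets, hits = NULL, compound_meta = NULL) {
  cids <- names(candidate_sets)
  if (is.null(cids) || anyDuplicated(cids)) {
    stop("candidate sets must be uniquely named by compound id",
         call. = FALSE)
  }
  tsets <- lapply(candidate_sets, function(e) {
    if (is.list(e) && !is.null(e$targets)) e$targets else as.character(e)
  })
  targets <- sort(unique(unlist(tsets, use.names = FALSE)))
  clash <- intersect(cids, targets)
  if (length(clash)) {
    stop(sprintf("id(s) used both as compound and target: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  erows <- Filter(Negate(is.null), lapply(cids, function(cid) {
    tg <- tsets[[cid]]
    if (length(tg) == 0L) return(NULL)
    data.frame(compound = cid, target = tg, stringsAsFactors = FALSE)
  }))
  edges <- if (length(erows)) {
    do.call(rbind, c(erows, list(make.row.names = FALSE)))
  } else {
    data.frame(compound = character(), target = character(),
               stringsAsFactors = FALSE)
  }
  edges[["weight"]] <- rep(NA_real_, nrow(edges))
  if (!is.null(hits) && nrow(edges) > 0L && nrow(hits) > 0L) {
    prov_ok <- inherits(candidate_sets, "candidate_targets")
    best <- function(cid, tg) {
      drugs <- if (prov_ok) candidate_sets[[cid]]$provenance[[tg]] else NULL
      h <- hits[hits$compound_id == cid &
                  (is.null(drugs) | hits$drug_id %in% drugs), , drop = FALSE]
      if (nrow(h) == 0L) NA_real_ else max(h$score)
    }
    edges$weight <- mapply(best, edges$compound, edges$target)
  }
  nodes <- rbind(
    data.frame(id = cids, type = rep("compound", length(cids)),
               stringsAsFactors = FALSE),
    data.frame(id = targets, type = rep("target", length(targets)),
               stringsAsFactors = FALSE))
  if (!is.null(compound_meta)) {
    stopifnot("id" %in% names(compound_meta))
    nodes <- merge(nodes, compound_meta, by = "id", all.x = TRUE,
                   sort = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ctn")
}

#' @export
print.ctn <- function(x, ...) {
  cat(sprintf("<ctn> %d nodes (%d compounds, %d targets), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "compound"),
              sum(x$nodes$type == "target"), nrow(x$edges)))
  invisible(x)
}

.check_ctn <- function(net) {
  stopifnot(inherits(net, "ctn"))
  cmp <- net$nodes$id[net$nodes$type == "compound"]
  tgt <- net$nodes$id[net$nodes$type == "target"]
  if (nrow(net$edges) > 0L) {
    if (!all(net$edges$compound %in% cmp) || !all(net$edges$target %in% tgt)) {
      stop("network has edges with unknown endpoints or wrong node types",
           call. = FALSE)
    }
  }
  invisible(net)
}

#' Degree table of a compound-target network
#'
#' Degrees per node, ranked descending with ties broken by node id;
#' attributes report the extremes and zero-degree compounds (compounds
#' that attracted no candidate targets).
#'
#' @param net A \code{ctn}.
#' @return data.frame: node, type, degree (sorted), with attributes
#'   \code{max_degree}, \code{min_degree}, \code{zero_degree_compounds}.
#' @export
degree_summary <- function(net) {
  .check_ctn(net)
  deg <- stats::setNames(rep(0L, nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0L) {
    te <- table(net$edges$compound)
    deg[names(te)] <- deg[names(te)] + as.integer(te)
    tt <- table(net$edges$target)
    deg[names(tt)] <- deg[names(tt)] + as.integer(tt)
  }
  out <- data.frame(node = net$nodes$id, type = net$nodes$type,
                    degree = unname(deg[net$nodes$id]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_degree") <- if (nrow(out)) max(out$degree) else NA_integer_
  attr(out, "min_degree") <- if (nrow(out)) min(out$degree) else NA_integer_
  attr(out, "zero_degree_compounds") <-
    out$node[out$type == "compound" & out$degree == 0L]
  out
}

#' Cluster compounds by fingerprint similarity
#'
#' Average-linkage hierarchical clustering on Tanimoto distance
#' (1 - similarity), cut at the given distance. Compounds are ordered by
#' id before clustering so the partition is invariant to input order.
#'
#' @param compounds A compound set (list with \code{$info} and \code{$fp})
#'   or a 0/1 fingerprint matrix with compound ids as rownames.
#' @param cut Tree cut height on the distance scale, 0 < cut < 1;
#'   default 0.4.
#' @return A \code{compound_partition}: list with \code{clusters} (list of
#'   id vectors), \code{assignment} (named integer vector), \code{cut},
#'   \code{method}.
#' @export
cluster_compounds <- function(compounds, cut = 0.4) {
  stopifnot(cut > 0, cut < 1)
  fp <- .query_fp_matrix(compounds, NULL)
  if (is.null(rownames(fp))) {
    stop("fingerprint matrix must carry compound ids as rownames",
         call. = FALSE)
  }
  fp <- fp[order(rownames(fp)), , drop = FALSE]
  if (nrow(fp) == 1L) {
    part <- stats::setNames(1L, rownames(fp))
  } else {
    d <- stats::as.dist(1 - tanimoto_matrix(fp))
    hc <- stats::hclust(d, method = "average")
    part <- stats::cutree(hc, h = cut)
  }
  clusters <- split(names(part), part)
  names(clusters) <- NULL
  structure(list(clusters = clusters, assignment = part,
                 cut = cut, method = "average"),
            class = "compound_partition")
}

#' @export
print.compound_partition <- function(x, ...) {
  cat(sprintf("<compound_partition> %d clusters (average linkage, cut %.2f)\n",
              length(x$clusters), x$cut))
  invisible(x)
}

#' Export a network as SIF
#'
#' Cytoscape simple-interaction format: one \code{compound binds target}
#' line per edge; zero-degree nodes are written as bare single-column
#' lines so the node set round-trips.
#'
#' @param net A \code{ctn}.
#' @param path Output file.
#' @export
write_sif <- function(net, path) {
  .check_ctn(net)
  lines <- character(0)
  if (nrow(net$edges) > 0L) {
    lines <- sprintf("%s\tbinds\t%s", net$edges$compound, net$edges$target)
  }
  linked <- unique(c(net$edges$compound, net$edges$target))
  lone <- setdiff(net$nodes$id, linked)
  writeLines(c(lines, lone), path)
  invisible(path)
}

#' Read a SIF file back into a network
#'
#' Node types are recovered from edge orientation (source = compound,
#' target = target); bare lines become zero-degree compounds unless
#' \code{lone_type} says otherwise.
#'
#' @param path SIF file written by \code{\link{write_sif}}.
#' @param lone_type Node type assigned to bare (edgeless) lines.
#' @return A \code{ctn}.
#' @export
read_sif <- function(path, lone_type = "compound") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- vapply(parts, length, integer(1)) >= 3L
  edges <- if (any(is_edge)) {
    do.call(rbind, c(lapply(parts[is_edge], function(p) {
      data.frame(compound = p[1], target = p[3], stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  } else {
    data.frame(compound = character(), target = character(),
               stringsAsFactors = FALSE)
  }
  edges[["weight"]] <- rep(NA_real_, nrow(edges))
  lone <- vapply(parts[!is_edge], `[[`, character(1), 1L)
  uc <- unique(edges$compound); ut <- sort(unique(edges$target))
  nodes <- rbind(
    data.frame(id = uc, type = rep("compound", length(uc)),
               stringsAsFactors = FALSE),
    data.frame(id = ut, type = rep("target", length(ut)),
               stringsAsFactors = FALSE),
    data.frame(id = lone, type = rep(lone_type, length(lone)),
               stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "ctn")
}

#' Convert a compound-target network to an igraph graph
#'
#' @param net A \code{ctn}.
#' @return An igraph object with a \code{type} vertex attribute
#'   (\code{TRUE} = target), satisfying igraph's bipartite convention.
#' @export
as_igraph <- function(net) {
  .check_ctn(net)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("compound", "target"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes)
  igraph::V(g)$type <- igraph::V(g)$type == "target"
  igraph::V(g)$node_type <-
    net$nodes$type[match(igraph::V(g)$name, net$nodes$id)]
  if (nrow(net$edges) > 0L) igraph::E(g)$weight_raw <- net$edges$weight
  g
}

#' Export a network as GraphML
#'
#' @param net A \code{ctn}.
#' @param path Output file; node types are stored in the \code{node_type}
#'   attribute.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file back into a network
#'
#' @param path GraphML written by \code{\link{write_graphml}}.
#' @return A \code{ctn}.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      type = igraph::V(g)$node_type,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    flip <- nodes$type[match(el[, 1], nodes$id)] == "target"
    edges <- data.frame(
      compound = ifelse(flip, el[, 2], el[, 1]),
      target = ifelse(flip, el[, 1], el[, 2]),
      stringsAsFactors = FALSE)
    edges$weight <- if ("weight_raw" %in% igraph::edge_attr_names(g)) {
      igraph::E(g)$weight_raw
    } else NA_real_
  } else {
    edges <- data.frame(compound = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ctn")
}

#' Write the node attribute table of a network
#'
#' @param net A \code{ctn}.
#' @param path Output TSV (id, type, degree plus any metadata columns).
#' @export
write_node_table <- function(net, path) {
  deg <- degree_summary(net)
  tab <- merge(net$nodes, deg[, c("node", "degree")],
               by.x = "id", by.y = "node", sort = TRUE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
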