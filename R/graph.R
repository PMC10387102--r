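#' Short-term (central-bin) correlation graph
#'
#' Undirected edges between significantly correlated pairs whose maximum
#' coefficient sits in the central bin, i.e. synchrony or propagation
#' faster than half a bin (|delay| <= 2.5 ms at 5 ms binning). Edges are
#' stored canonically with `a < b` and labeled by compartment geometry.
#'
#' @param cc A `correlation_result` from [correlate_pairs()].
#' @param layout An `electrode_layout`.
#' @param alpha Significance level (default: the level `cc` was computed
#'   at).
#' @return data.frame `a`, `b`, `delay_ms`, `strength` (cmax), `p`,
#'   `edge_class`, `span_pitches`, `window = "short_term"`.
#' @export
short_term_graph <- function(cc, layout, alpha = attr(cc, "alpha")) {
  sel <- !cc$undefined & cc$p <= alpha & cc$lag_bins == 0L
  e <- cc[sel, , drop = FALSE]
  a <- pmin(e$a, e$b); b <- pmax(e$a, e$b)
  out <- data.frame(a = a, b = b, delay_ms = e$delay_ms,
                    strength = e$cmax, p = e$p, stringsAsFactors = FALSE)
  out$edge_class <- if (nrow(out)) edge_class(layout, out$a, out$b) else character(0)
  out$span_pitches <- if (nrow(out)) edge_span(layout, out$a, out$b) else integer(0)
  out$window <- rep("short_term", nrow(out))
  rownames(out) <- NULL
  out
}

#' Delayed correlation graph (directed)
#'
#' Directed edges between significantly correlated pairs whose maximum
#' coefficient lies at a non-central lag (5-25 ms at 5 ms binning and the
#' default 5-bin window). A positive delay between electrodes A and B is
#' read as propagation from A to B (possibly through hidden nodes), so
#' each edge is oriented from the leading to the lagging electrode.
#'
#' @inheritParams short_term_graph
#' @return data.frame `from`, `to`, `delay_ms` (positive), `strength`,
#'   `p`, `edge_class`, `span_pitches`, `window = "delayed"`.
#' @export
delayed_graph <- function(cc, layout, alpha = attr(cc, "alpha")) {
  sel <- !cc$undefined & cc$p <= alpha & cc$lag_bins != 0L
  e <- cc[sel, , drop = FALSE]
  lead_a <- e$lag_bins > 0L
  out <- data.frame(from = ifelse(lead_a, e$a, e$b),
                    to = ifelse(lead_a, e$b, e$a),
                    delay_ms = abs(e$delay_ms), strength = e$cmax, p = e$p,
                    stringsAsFactors = FALSE)
  out$edge_class <- if (nrow(out)) edge_class(layout, out$from, out$to) else character(0)
  out$span_pitches <- if (nrow(out)) edge_span(layout, out$from, out$to) else integer(0)
  out$window <- rep("delayed", nrow(out))
  rownames(out) <- NULL
  out
}

graph_endpoints <- function(edges) {
  if (!nrow(edges)) return(character(0))
  if ("from" %in% names(edges)) c(edges$from, edges$to) else c(edges$a, edges$b)
}

#' Edge-class and compartment summaries of a connectivity graph
#'
#' Counts edges per geometric class, per electrode, and per microfluidic
#' compartment (edge endpoints per electrode of the compartment, over all
#' of the compartment's electrodes — the density a correlation map shows).
#'
#' @param edges An edge data.frame from [short_term_graph()],
#'   [delayed_graph()], or their row-bound union.
#' @param layout An `electrode_layout`.
#' @return List with `class_counts` (named vector over the four classes),
#'   `per_electrode` (electrode, compartment, n_edges; electrodes with at
#'   least one edge), `per_compartment` (compartment, n_electrodes,
#'   n_endpoints, edges_per_electrode), and `mean_edges_per_electrode`.
#' @export
classify_edges <- function(edges, layout) {
  classes <- c("soma_neurite", "same_column", "same_line", "misaligned")
  cls <- table(factor(edges$edge_class, levels = classes))
  ends <- graph_endpoints(edges)
  if (length(ends)) {
    tab <- table(ends)
    per_el <- data.frame(electrode = names(tab),
                         n_edges = as.integer(tab),
                         stringsAsFactors = FALSE)
    per_el$compartment <-
      layout$electrodes$compartment[layout_lookup(layout, per_el$electrode)]
    per_el <- per_el[, c("electrode", "compartment", "n_edges")]
  } else {
    per_el <- data.frame(electrode = character(0), compartment = character(0),
                         n_edges = integer(0))
  }
  comp_sizes <- table(layout$electrodes$compartment)
  comp <- data.frame(compartment = names(comp_sizes),
                     n_electrodes = as.integer(comp_sizes),
                     stringsAsFactors = FALSE)
  end_comp <- if (length(ends)) {
    layout$electrodes$compartment[layout_lookup(layout, ends)]
  } else {
    character(0)
  }
  comp$n_endpoints <- as.integer(table(factor(end_comp, levels = comp$compartment)))
  comp$edges_per_electrode <- comp$n_endpoints / comp$n_electrodes
  list(class_counts = c(cls),
       per_electrode = per_el,
       per_compartment = comp,
       mean_edges_per_electrode = if (nrow(per_el)) mean(per_el$n_edges) else 0)
}

#' Afferent/efferent node roles from the delayed graph
#'
#' Computes in- and out-degree of every electrode in the directed delayed
#' graph and assigns roles to somatic-chamber electrodes: `efferent`
#' (output node: outgoing edges only), `afferent` (input node: incoming
#' only), `mixed` (both), `isolated` (no delayed edges). Non-somatic
#' electrodes are reported with degrees only.
#'
#' @param delayed_edges Edge data.frame from [delayed_graph()].
#' @param layout An `electrode_layout`.
#' @return data.frame `electrode`, `compartment`, `in_degree`,
#'   `out_degree`, `role` (`NA` for non-somatic electrodes).
#' @export
node_roles <- function(delayed_edges, layout) {
  e <- layout$electrodes
  out_deg <- table(factor(delayed_edges$from, levels = e$id))
  in_deg <- table(factor(delayed_edges$to, levels = e$id))
  res <- data.frame(electrode = e$id, compartment = e$compartment,
                    in_degree = as.integer(in_deg),
                    out_degree = as.integer(out_deg),
                    stringsAsFactors = FALSE)
  somatic <- res$compartment %in% somatic_compartments()
  role <- rep(NA_character_, nrow(res))
  role[somatic & res$out_degree > 0 & res$in_degree == 0] <- "efferent"
  role[somatic & res$out_degree == 0 & res$in_degree > 0] <- "afferent"
  role[somatic & res$out_degree > 0 & res$in_degree > 0] <- "mixed"
  role[somatic & res$out_degree == 0 & res$in_degree == 0] <- "isolated"
  res$role <- role
  res
}

#' Convert a connectivity edge set to an igraph graph
#'
#' Vertices are the layout's electrodes, annotated with grid position and
#' compartment; edges carry delay, strength, p-value, class and window.
#' Short-term edge sets give undirected graphs, delayed sets directed ones.
#'
#' @param edges Edge data.frame from [short_term_graph()] or
#'   [delayed_graph()].
#' @param layout An `electrode_layout`.
#' @return An [igraph::graph] object.
#' @export
as_connectivity_igraph <- function(edges, layout) {
  directed <- "from" %in% names(edges)
  verts <- layout$electrodes
  names(verts)[names(verts) == "id"] <- "name"
  el <- if (directed) {
    data.frame(from = edges$from, to = edges$to, stringsAsFactors = FALSE)
  } else {
    data.frame(from = edges$a, to = edges$b, stringsAsFactors = FALSE)
  }
  keep <- setdiff(names(edges), c("a", "b", "from", "to"))
  el <- cbind(el, edges[, keep, drop = FALSE])
  igraph::graph_from_data_frame(el, directed = directed, vertices = verts)
}

#' Write a connectivity graph to GraphML
#'
#' @inheritParams as_connectivity_igraph
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, layout, path) {
  g <- as_connectivity_igraph(edges, layout)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
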