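#' Build the LC-PUFA biosynthesis pathway graph
#'
#' Computes the closure of a set of precursor fatty acids under all enzyme
#' activities that qualify as pathway edges: a panel record becomes an edge
#' when its conversion is at least `threshold` percent, or when it is a
#' qualitative (chromatogram-documented) activity. Starting from the
#' precursors, products of qualifying reactions are added as nodes and the
#' process repeats until no new acid is reachable. Because elongation
#' strictly increases chain length and desaturation strictly increases the
#' double-bond count, the result is a directed acyclic graph.
#'
#' The default precursors are the yeast endogenous MUFA (16:1n-7, 18:1n-9)
#' plus the two dietary C18 PUFA precursors (18:2n-6, 18:3n-3); the default
#' 5% threshold separates every activity treated as functional in the source
#' panels from every trace activity treated as absent.
#'
#' @param panels an activity-panel tibble from [load_activity_panels()].
#' @param precursors character vector of fatty-acid shorthand names.
#' @param threshold edge-inclusion threshold in percent (>= 0).
#' @param cap chain-length cap for nodes (default 24).
#' @return an object of class `"fa_pathway"`: a list with tibbles `nodes`
#'   (`id` canonical delta name, `shorthand` preferred display name, `chain`,
#'   `n_double_bonds`, `class`, `is_precursor`) and `edges` (`substrate`,
#'   `product` as node ids, `enzyme`, `activity_label`, `conversion`,
#'   `status`), the `precursors`, the `threshold`, and the underlying
#'   [igraph::graph] in `$graph`.
#' @examples
#' g <- build_pathway()
#' glance(g)
#' @export
build_pathway <- function(panels = load_activity_panels(),
                          precursors = c("16:1n-7", "18:1n-9",
                                         "18:2n-6", "18:3n-3"),
                          threshold = 5, cap = 24L) {
  if (!length(precursors)) abort_input("`precursors` must be non-empty.")
  if (threshold < 0) abort_input("`threshold` must be >= 0.")
  qualifying <- panels[panels$status == "qualitative" |
                         (panels$status == "quantified" &
                            !is.na(panels$conversion) &
                            panels$conversion >= threshold), , drop = FALSE]
  pre_ids <- fa_to_delta(precursors)
  frontier <- unique(pre_ids)
  nodes <- frontier
  edges <- qualifying[0, , drop = FALSE]
  while (length(frontier)) {
    hits <- qualifying[qualifying$substrate_delta %in% frontier, , drop = FALSE]
    hits <- hits[vapply(hits$product_delta, function(p) fa_chain(p) <= cap, TRUE), ,
                 drop = FALSE]
    edges <- rbind(edges, hits)
    frontier <- setdiff(unique(hits$product_delta), nodes)
    nodes <- c(nodes, frontier)
  }
  edges <- distinct(as_tibble(edges))
  node_tbl <- fa_describe(nodes) |>
    mutate(
      id = .data$delta,
      is_precursor = .data$delta %in% pre_ids,
      shorthand = dplyr::coalesce(.data$omega, .data$delta)
    ) |>
    select("id", "shorthand", "chain", "n_double_bonds", "class",
           "is_precursor")
  edge_tbl <- edges |>
    select(substrate = "substrate_delta", product = "product_delta",
           "enzyme", "activity_label", "conversion", "status")
  ig <- igraph::graph_from_data_frame(
    edge_tbl[, c("substrate", "product")], directed = TRUE,
    vertices = node_tbl$id)
  if (!igraph::is_dag(ig)) {
    abort("pathway graph is not acyclic; panel data are inconsistent.",
          class = "pufapath_graph_error")
  }
  structure(
    list(nodes = node_tbl, edges = edge_tbl, precursors = pre_ids,
         threshold = threshold, cap = cap, graph = ig),
    class = "fa_pathway")
}

#' @export
print.fa_pathway <- function(x, ...) {
  cat(sprintf(
    "<fa_pathway> %d nodes, %d edges (threshold %s%%, precursors: %s)\n",
    nrow(x$nodes), nrow(x$edges), format(x$threshold),
    paste(x$nodes$shorthand[x$nodes$is_precursor], collapse = ", ")))
  invisible(x)
}

#' Reachable biosynthetic products
#'
#' All non-precursor nodes of a pathway graph, optionally restricted by
#' chain length and/or unsaturation class, or by an arbitrary predicate on
#' the parsed [fatty_acid()].
#'
#' @param g an `fa_pathway` from [build_pathway()].
#' @param chain optional integer vector of chain lengths to keep.
#' @param class optional character vector of unsaturation classes to keep
#'   (see [fa_class()]).
#' @param predicate optional function taking a `fatty_acid` and returning
#'   `TRUE`/`FALSE`.
#' @return the filtered `nodes` tibble.
#' @examples
#' g <- build_pathway()
#' reachable_products(g, chain = 20, class = "nmi")
#' @export
reachable_products <- function(g, chain = NULL, class = NULL, predicate = NULL) {
  stopifnot(inherits(g, "fa_pathway"))
  out <- g$nodes[!g$nodes$is_precursor, , drop = FALSE]
  if (!is.null(chain)) out <- out[out$chain %in% chain, , drop = FALSE]
  if (!is.null(class)) out <- out[out$class %in% class, , drop = FALSE]
  if (!is.null(predicate)) {
    keep <- vapply(out$id, function(id) isTRUE(predicate(fa_parse(id))), TRUE)
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Enumerate biosynthetic routes to a target fatty acid
#'
#' All simple (cycle-free) routes from any precursor to the target, as an
#' ordered sequence of enzyme-labelled reaction steps. Routes are sorted by
#' number of steps, then lexicographically by their enzyme names.
#'
#' @inheritParams reachable_products
#' @param target fatty-acid shorthand of the target node.
#' @return a tibble with one row per step: `route`, `step`, `substrate`,
#'   `product`, `enzyme`, `activity_label`, `conversion`, `status`. A target
#'   that is itself a precursor yields zero routes (zero rows).
#' @examples
#' g <- build_pathway()
#' routes_to(g, "20:4n-6")
#' @export
routes_to <- function(g, target) {
  stopifnot(inherits(g, "fa_pathway"))
  tid <- fa_to_delta(target)
  if (!tid %in% g$nodes$id) {
    abort_input(sprintf("target %s is not a node of the pathway graph.", target))
  }
  empty <- tibble(route = integer(), step = integer(),
                  substrate = character(), product = character(),
                  enzyme = character(), activity_label = character(),
                  conversion = double(), status = character())
  paths <- list()
  for (p in g$precursors) {
    if (p == tid) next
    sp <- igraph::all_simple_paths(g$graph, from = p, to = tid, mode = "out")
    paths <- c(paths, lapply(sp, function(v) names(v)))
  }
  if (!length(paths)) return(empty)
  # expand each vertex path into concrete edge sequences (parallel enzyme
  # edges between the same pair each give a distinct route)
  routes <- list()
  for (vp in paths) {
    step_edges <- lapply(seq_len(length(vp) - 1L), function(i) {
      g$edges[g$edges$substrate == vp[i] & g$edges$product == vp[i + 1L], ,
              drop = FALSE]
    })
    idx <- expand.grid(lapply(step_edges, function(e) seq_len(nrow(e))))
    for (r in seq_len(nrow(idx))) {
      steps <- bind_rows(lapply(seq_along(step_edges), function(i) {
        step_edges[[i]][idx[r, i], , drop = FALSE]
      }))
      routes[[length(routes) + 1L]] <- steps
    }
  }
  key <- vapply(routes, function(s) {
    sprintf("%03d|%s", nrow(s), paste(s$enzyme, collapse = "|"))
  }, "")
  routes <- routes[order(key)]
  bind_rows(lapply(seq_along(routes), function(i) {
    mutate(routes[[i]], route = i, step = dplyr::row_number(),
           .before = 1L)
  }))
}

#' Export a pathway graph
#'
#' `pathway_edges_csv()` writes the edge list as CSV; `pathway_dot()` renders
#' GraphViz DOT text (returned invisibly, and written if `path` is given).
#'
#' @inheritParams reachable_products
#' @param path output file path.
#' @return the input `g`, invisibly (`pathway_dot()` returns the DOT lines).
#' @export
pathway_edges_csv <- function(g, path) {
  stopifnot(inherits(g, "fa_pathway"))
  readr::write_csv(g$edges, path)
  invisible(g)
}

#' @rdname pathway_edges_csv
#' @export
pathway_dot <- function(g, path = NULL) {
  stopifnot(inherits(g, "fa_pathway"))
  lab <- setNames(g$nodes$shorthand, g$nodes$id)
  lines <- c(
    "digraph pufa_pathway {",
    "  rankdir=LR;",
    sprintf("  \"%s\" [shape=%s];", g$nodes$id,
            ifelse(g$nodes$is_precursor, "box", "ellipse")),
    sprintf("  \"%s\" -> \"%s\" [label=\"%s (%s)\"];",
            g$edges$substrate, g$edges$product, g$edges$enzyme,
            g$edges$activity_label),
    "}")
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Reproduce the reference biosynthesis map
#'
#' Builds the pathway graph from the packaged enzyme panels with the default
#' precursors and 5% threshold, and summarises the C20 end products: the
#' methylene-interrupted PUFA and the non-methylene-interrupted (NMI) fatty
#' acids reachable from the C16/C18 precursors. Optionally writes
#' `nodes.csv`, `edges.csv` and `graph.dot` into `dir`.
#'
#' @param dir optional output directory (created if missing).
#' @param threshold edge-inclusion threshold in percent.
#' @return a list with the `fa_pathway` (`$pathway`) and tibbles
#'   `$c20_nmi` and `$c20_methylene_interrupted`.
#' @export
reproduce_pathway_map <- function(dir = NULL, threshold = 5) {
  g <- build_pathway(threshold = threshold)
  out <- list(
    pathway = g,
    c20_nmi = reachable_products(g, chain = 20, class = "nmi"),
    c20_methylene_interrupted =
      reachable_products(g, chain = 20, class = "methylene_interrupted"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(g$nodes, file.path(dir, "nodes.csv"))
    readr::write_csv(g$edges, file.path(dir, "edges.csv"))
    pathway_dot(g, file.path(dir, "graph.dot"))
  }
  out
}

#' @export
tidy.fa_pathway <- function(x, ...) x$edges

#' @export
glance.fa_pathway <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_precursors = sum(x$nodes$is_precursor),
    n_products = sum(!x$nodes$is_precursor),
    n_c20_nmi = nrow(reachable_products(x, chain = 20, class = "nmi")),
    threshold = x$threshold
  )
}
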