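#' Construct a signed directed regulatory network
#'
#' A signed network couples a node table (id, kind, species) with an edge
#' table (from, to, sign). Edge signs follow the regulatory-map convention:
#' `+1` activation, `-1` inhibition, `0` an interaction whose direction of
#' effect is unidentified ("neutral").
#'
#' @param edges A data frame with columns `from`, `to` and `sign`
#'   (integer-valued, each in `{-1, 0, 1}`).
#' @param nodes Optional data frame with columns `id`, `kind`
#'   (`"receptor"`, `"regulatory"`, `"marker"` or `"phenotype"`) and
#'   `species` (`"protein"`, `"miRNA"`, `"complex"` or `"other"`).
#'   Nodes appearing only in `edges` are added with defaults
#'   (`kind = "regulatory"`, `species = "protein"`).
#'
#' @return An object of class `signed_network`: a list with tibbles
#'   `$nodes` and `$edges`.
#' @examples
#' net <- signed_network(data.frame(from = "A", to = "B", sign = 1))
#' net
#' @export
signed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            sign = integer())
  }
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  edges <- tibble::tibble(
    from = as.character(edges$from),
    to   = as.character(edges$to),
    sign = as.integer(edges$sign)
  )
  if (any(!edges$sign %in% c(-1L, 0L, 1L))) {
    stop("edge signs must be one of -1, 0, +1", call. = FALSE)
  }
  if (any(!nzchar(edges$from)) || any(!nzchar(edges$to))) {
    stop("edge endpoints must be non-empty node ids", call. = FALSE)
  }
  dup <- duplicated(edges[c("from", "to")])
  if (any(dup)) {
    stop("duplicate edges for ordered pairs: ",
         paste(unique(paste0(edges$from[dup], "->", edges$to[dup])),
               collapse = ", "), call. = FALSE)
  }

  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = character())
  }
  nodes <- tibble::as_tibble(nodes)
  if (!"id" %in% names(nodes)) stop("node table needs an `id` column",
                                    call. = FALSE)
  nodes$id <- as.character(nodes$id)
  if (!"kind" %in% names(nodes)) nodes$kind <- "regulatory"
  if (!"species" %in% names(nodes)) nodes$species <- "protein"
  nodes <- nodes[c("id", "kind", "species")]

  extra <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(extra)) {
    nodes <- dplyr::bind_rows(
      nodes,
      tibble::tibble(id = extra, kind = "regulatory", species = "protein")
    )
  }
  if (anyDuplicated(nodes$id)) stop("node ids must be unique", call. = FALSE)
  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty", call. = FALSE)
  ok_kind <- c("receptor", "regulatory", "marker", "phenotype")
  ok_species <- c("protein", "miRNA", "complex", "other")
  if (any(!nodes$kind %in% ok_kind)) {
    stop("node kind must be one of: ", paste(ok_kind, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nodes$species %in% ok_species)) {
    stop("node species must be one of: ", paste(ok_species, collapse = ", "),
         call. = FALSE)
  }

  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat("<signed_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  tab <- table(factor(sign_label(x$edges$sign),
                      levels = c("activation", "inhibition", "neutral")))
  cat("  signs: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

sign_label <- function(s) {
  c(`-1` = "inhibition", `0` = "neutral", `1` = "activation")[as.character(s)]
}

#' Set node kinds on a signed network
#'
#' @param net A `signed_network`.
#' @param ids Character vector of node ids (must exist in `net`).
#' @param kind Single kind to assign to all of `ids`.
#' @param species Optional species to assign alongside.
#' @return The modified network.
#' @export
set_node_kind <- function(net, ids, kind, species = NULL) {
  stopifnot(inherits(net, "signed_network"))
  missing <- setdiff(ids, net$nodes$id)
  if (length(missing)) {
    stop("unknown node id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  net$nodes$kind[net$nodes$id %in% ids] <- kind
  if (!is.null(species)) net$nodes$species[net$nodes$id %in% ids] <- species
  signed_network(net$edges, net$nodes)
}

#' Convert a signed network to an igraph graph
#'
#' Edge signs are carried in the `sign` edge attribute; isolated nodes are
#' preserved.
#'
#' @param net A `signed_network`.
#' @return A directed `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = TRUE,
    vertices = net$nodes
  )
}

# nodes two networks share an edge-wise identical subgraph relation
is_subnetwork <- function(sub, full) {
  key <- function(e) paste(e$from, e$to, e$sign)
  all(sub$nodes$id %in% full$nodes$id) &&
    all(key(sub$edges) %in% key(full$edges))
}
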