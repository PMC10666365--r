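#' Enumerate three-node feedback loops
#'
#' Finds every simple directed 3-cycle in the network, in canonical form
#' (rotation starting at the lexicographically smallest node id), each
#' exactly once, sorted by canonical id. Self-loops and 2-cycles are
#' ignored by definition; the two opposite orientations of a triangle are
#' distinct motifs when both edge sets exist. The loop sign is the product
#' of the edge signs: positive, negative, or undetermined when any edge is
#' neutral (sign 0).
#'
#' @param net A [signed_network()].
#' @param exclude_neutral If `TRUE`, edges with sign 0 do not participate
#'   in cycles. Default `FALSE` (neutral edges stay rankable, with
#'   `loop_sign = "undetermined"`).
#' @return A tibble with one row per motif: `motif_id`, the cyclic node
#'   triple `n1, n2, n3`, edge signs `s12, s23, s31`, and `loop_sign`.
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("A", "B", "C"), to = c("B", "C", "A"), sign = c(1, 1, -1)))
#' enumerate_feedback_loops(net)
#' @export
enumerate_feedback_loops <- function(net, exclude_neutral = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  edges <- net$edges
  if (exclude_neutral) edges <- edges[edges$sign != 0L, ]
  edges <- edges[edges$from != edges$to, ]
  if (!nrow(edges)) return(empty_motif_tbl())

  succ <- split(edges$to, edges$from)
  sgn <- stats::setNames(edges$sign, paste(edges$from, edges$to, sep = "\r"))
  esign <- function(a, b) unname(sgn[paste(a, b, sep = "\r")])

  out <- list()
  for (a in names(succ)) {
    for (b in succ[[a]]) {
      if (!(b > a)) next        # canonical start: a is smallest
      cs <- succ[[b]]
      if (is.null(cs)) next
      for (ce in cs) {
        if (!(ce > a) || ce == b) next
        if (a %in% succ[[ce]]) {
          out[[length(out) + 1L]] <- c(a, b, ce)
        }
      }
    }
  }
  if (!length(out)) return(empty_motif_tbl())
  m <- do.call(rbind, out)
  tbl <- tibble::tibble(
    n1 = m[, 1], n2 = m[, 2], n3 = m[, 3],
    s12 = esign(m[, 1], m[, 2]),
    s23 = esign(m[, 2], m[, 3]),
    s31 = esign(m[, 3], m[, 1])
  )
  tbl$motif_id <- paste(tbl$n1, tbl$n2, tbl$n3, sep = "|")
  prod_sign <- tbl$s12 * tbl$s23 * tbl$s31
  tbl$loop_sign <- ifelse(prod_sign == 0L, "undetermined",
                          ifelse(prod_sign > 0L, "positive", "negative"))
  tbl <- tbl[order(tbl$motif_id), c("motif_id", "n1", "n2", "n3",
                                    "s12", "s23", "s31", "loop_sign")]
  tbl
}

empty_motif_tbl <- function() {
  tibble::tibble(motif_id = character(), n1 = character(), n2 = character(),
                 n3 = character(), s12 = integer(), s23 = integer(),
                 s31 = integer(), loop_sign = character())
}

#' Node degree and normalized betweenness centrality
#'
#' Degree counts all distinct incident edges (in + out), ignoring signs.
#' Betweenness is shortest-path betweenness on the directed graph (signs
#' ignored), normalized by (n-1)(n-2)/2 so that the sole intermediary on a
#' directed path scores 1.
#'
#' @param net A non-empty [signed_network()].
#' @return A tibble with columns `id`, `degree`, `betweenness`, one row per
#'   node (isolated nodes score 0/0).
#' @export
compute_topology <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  if (!nrow(net$nodes)) stop("network has no nodes", call. = FALSE)
  g <- as_igraph(net)
  deg <- igraph::degree(g, mode = "all", loops = TRUE)
  n <- nrow(net$nodes)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  tibble::tibble(
    id = igraph::V(g)$name,
    degree = as.integer(deg[igraph::V(g)$name]),
    betweenness = unname(btw[igraph::V(g)$name]) / denom
  )
}
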