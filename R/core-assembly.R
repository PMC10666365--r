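#' Merge feedback motifs into one signed network
#'
#' Node set = union of motif nodes; edge set = union of motif edges, signs
#' preserved.
#'
#' @param motifs Motif tibble (rows from [enumerate_feedback_loops()]),
#'   typically the unique selected motifs of [select_top_motifs()].
#' @return A [signed_network()].
#' @export
merge_motifs <- function(motifs) {
  stopifnot(nrow(motifs) > 0)
  edges <- dplyr::bind_rows(
    tibble::tibble(from = motifs$n1, to = motifs$n2, sign = motifs$s12),
    tibble::tibble(from = motifs$n2, to = motifs$n3, sign = motifs$s23),
    tibble::tibble(from = motifs$n3, to = motifs$n1, sign = motifs$s31)
  )
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  signed_network(edges)
}

#' Expand a core network with receptor first-neighbors
#'
#' Adds each listed receptor that is a first neighbor (in either
#' direction) of a core node, together with the connecting edges copied
#' from the full network. Receptors with no adjacency to the core are
#' skipped with a warning. Edges among two listed receptors present in
#' the full network are retained.
#'
#' @param core A `signed_network` (the merged motifs).
#' @param full The full source network the core was derived from.
#' @param receptors Character vector of receptor node ids; all must exist
#'   in `full`.
#' @return The expanded `signed_network`, with receptor nodes marked
#'   `kind = "receptor"`.
#' @export
expand_with_receptors <- function(core, full, receptors) {
  stopifnot(inherits(core, "signed_network"), inherits(full, "signed_network"))
  missing <- setdiff(receptors, full$nodes$id)
  if (length(missing)) {
    stop("receptor(s) absent from full network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  core_ids <- core$nodes$id
  added <- character()
  for (r in receptors) {
    if (!any(full$edges$from == r & full$edges$to %in% core_ids |
             full$edges$to == r & full$edges$from %in% core_ids)) {
      warning("receptor ", r, " has no edge touching the core; skipped",
              call. = FALSE)
      next
    }
    added <- c(added, r)
  }
  keep <- full$edges$from %in% added & full$edges$to %in% c(core_ids, added) |
          full$edges$to %in% added & full$edges$from %in% c(core_ids, added)
  new_edges <- dplyr::bind_rows(core$edges, full$edges[keep, ]) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)
  nodes <- dplyr::bind_rows(
    core$nodes,
    full$nodes[full$nodes$id %in% added, ]
  ) |> dplyr::distinct(.data$id, .keep_all = TRUE)
  net <- signed_network(new_edges, nodes)
  set_node_kind(net, added, "receptor")
}

#' Expand with EMT marker nodes and assign model layers
#'
#' Adds the four EMT marker nodes with every direct edge between a marker
#' and a current core node (both directions, marker-marker edges
#' included) copied from the full network. Markers with no core adjacency
#' are still added, isolated, with a warning. Layers are then assigned:
#' receptors to `input`, markers to `output-marker`, everything else to
#' `regulatory`.
#'
#' @param core A `signed_network` (typically after
#'   [expand_with_receptors()]).
#' @param full The full source network.
#' @param markers Named character vector of the four marker node ids,
#'   names giving their EMT roles; see [emt_markers()]. Defaults to the
#'   canonical CDH1/VIM/ZEB1/SNAI1 set.
#' @return A `core_network`: a `signed_network` with added fields
#'   `$layers` (tibble `id`, `layer`), `$receptors` and `$markers`.
#' @export
expand_with_markers <- function(core, full, markers = emt_markers()) {
  stopifnot(inherits(core, "signed_network"), inherits(full, "signed_network"))
  markers <- validate_markers(markers)
  missing <- setdiff(markers, full$nodes$id)
  if (length(missing)) {
    stop("marker(s) absent from full network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  core_ids <- unique(c(core$nodes$id, markers))
  keep <- (full$edges$from %in% markers & full$edges$to %in% core_ids) |
          (full$edges$to %in% markers & full$edges$from %in% core_ids)
  lonely <- markers[!markers %in% c(full$edges$from[keep],
                                    full$edges$to[keep])]
  if (length(lonely)) {
    warning("marker(s) with no core adjacency added isolated: ",
            paste(lonely, collapse = ", "), call. = FALSE)
  }
  edges <- dplyr::bind_rows(core$edges, full$edges[keep, ]) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)
  nodes <- dplyr::bind_rows(
    core$nodes,
    full$nodes[full$nodes$id %in% markers, ]
  ) |> dplyr::distinct(.data$id, .keep_all = TRUE)
  net <- signed_network(edges, nodes)
  net <- set_node_kind(net, markers, "marker")
  receptors <- net$nodes$id[net$nodes$kind == "receptor"]
  layers <- tibble::tibble(
    id = net$nodes$id,
    layer = dplyr::case_when(
      net$nodes$id %in% receptors ~ "input",
      net$nodes$id %in% markers ~ "output-marker",
      TRUE ~ "regulatory"
    )
  )
  net$layers <- layers
  net$receptors <- receptors
  net$markers <- markers
  class(net) <- c("core_network", class(net))
  net
}

#' @export
print.core_network <- function(x, ...) {
  NextMethod()
  tab <- table(x$layers$layer)
  cat("  layers: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assemble a core regulatory network in one call
#'
#' Convenience wrapper: [merge_motifs()], then [expand_with_receptors()],
#' then [expand_with_markers()].
#'
#' @inheritParams expand_with_receptors
#' @inheritParams expand_with_markers
#' @param motifs Motif tibble of the selected (unique) motifs.
#' @return A `core_network`.
#' @export
assemble_core <- function(motifs, full, receptors, markers = emt_markers()) {
  merge_motifs(motifs) |>
    expand_with_receptors(full, receptors) |>
    expand_with_markers(full, markers)
}
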