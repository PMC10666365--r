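#' Tidy a Boolean model into a rules tibble
#'
#' @param x A [boolean_model()].
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `gate`, `rule` (the
#'   bnet-style expression), `n_regulators`, `clamp` and, when the model
#'   was calibrated, the calibration `status`.
#' @method tidy boolean_model
#' @export
tidy.boolean_model <- function(x, ...) {
  rows <- purrr::map_dfr(x$nodes, function(nd) {
    r <- x$rules[[nd]]
    rhs <- if (r$gate == "INPUT") {
      cl <- x$clamps[nd]
      if (is.na(cl)) "free" else as.character(cl)
    } else {
      lit <- ifelse(r$polarity == -1, paste0("!", r$regulators),
                    r$regulators)
      paste(lit, collapse = switch(r$gate, IDENTITY = "", AND = " & ",
                                   OR = " | "))
    }
    tibble::tibble(node = nd, gate = r$gate, rule = rhs,
                   n_regulators = length(r$regulators),
                   clamp = unname(x$clamps[nd]))
  })
  if (!is.null(x$calibration)) {
    rows <- dplyr::left_join(rows,
                             x$calibration[c("node", "status")], by = "node")
  }
  rows
}

#' One-row model summary
#'
#' @param x A [boolean_model()].
#' @param ... Unused.
#' @return A tibble with node/gate counts, the number of clamped inputs
#'   and, when calibrated, the number of unresolved gates.
#' @export
glance.boolean_model <- function(x, ...) {
  gates <- vapply(x$rules, `[[`, "", "gate")
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_inputs = sum(gates == "INPUT"),
    n_and = sum(gates == "AND"),
    n_or = sum(gates == "OR"),
    n_clamped = sum(!is.na(x$clamps)),
    n_unresolved = if (is.null(x$calibration)) NA_integer_ else
      sum(x$calibration$status == "unresolved"))
}

#' Tidy a signed network into its edge tibble
#'
#' @param x A [signed_network()].
#' @param ... Unused.
#' @return The edge tibble with a readable `effect` column.
#' @method tidy signed_network
#' @export
tidy.signed_network <- function(x, ...) {
  dplyr::mutate(x$edges, effect = sign_label(.data$sign))
}

#' One-row network summary
#'
#' @param x A [signed_network()].
#' @param ... Unused.
#' @return A tibble with node/edge counts by sign.
#' @method glance signed_network
#' @export
glance.signed_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_activation = sum(x$edges$sign == 1),
    n_inhibition = sum(x$edges$sign == -1),
    n_neutral = sum(x$edges$sign == 0))
}
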