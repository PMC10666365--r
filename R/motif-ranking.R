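#' Per-motif features for the multi-objective ranking score
#'
#' Aggregates node-level properties to the motif level: `nd`, `bc` and `gp`
#' are means over the three motif nodes (configurable to sums), `dp` is the
#' count of motif nodes belonging to the disease pathway (0-3), and
#' `absfc` is the mean of |log2FC| over the motif nodes with non-missing
#' fold change (0, with `fc_missing = TRUE`, when all three are missing).
#' Nodes absent from the annotation table default to non-membership and a
#' zero prioritization score.
#'
#' @param motifs Motif tibble from [enumerate_feedback_loops()].
#' @param topo Topology tibble from [compute_topology()]; must cover all
#'   motif nodes.
#' @param annot Annotation tibble from [read_annotations()] (or `NULL`).
#' @param fc Fold-change tibble from [read_fold_changes()] (or `NULL`).
#' @param aggregate `"mean"` (default) or `"sum"` for the nd/bc/gp
#'   aggregation.
#' @return A tibble with columns `motif_id`, `nd`, `bc`, `dp`, `gp`,
#'   `absfc`, `fc_missing`.
#' @export
featurize_motifs <- function(motifs, topo, annot = NULL, fc = NULL,
                             aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else sum
  nodes <- unique(c(motifs$n1, motifs$n2, motifs$n3))
  absent <- setdiff(nodes, topo$id)
  if (length(absent)) {
    stop("motif node(s) absent from topology: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  deg <- stats::setNames(topo$degree, topo$id)
  btw <- stats::setNames(topo$betweenness, topo$id)
  dp <- gp <- NULL
  if (!is.null(annot)) {
    dp <- stats::setNames(annot$dp_member, annot$id)
    gp <- stats::setNames(annot$gp_score, annot$id)
  }
  fcv <- if (!is.null(fc)) stats::setNames(fc$log2fc, fc$id) else NULL

  purrr::pmap_dfr(motifs[c("motif_id", "n1", "n2", "n3")],
    function(motif_id, n1, n2, n3) {
      trio <- c(n1, n2, n3)
      f <- if (is.null(fcv)) rep(NA_real_, 3) else unname(fcv[trio])
      f[!is.na(f) & f == 0] <- NA  # zero FC carries no sign: treat missing
      known <- f[!is.na(f)]
      tibble::tibble(
        motif_id = motif_id,
        nd = agg(unname(deg[trio])),
        bc = agg(unname(btw[trio])),
        dp = if (is.null(dp)) 0L else
          sum(dplyr::coalesce(unname(dp[trio]), FALSE)),
        gp = if (is.null(gp)) 0 else
          agg(dplyr::coalesce(unname(gp[trio]), 0)),
        absfc = if (length(known)) mean(abs(known)) else 0,
        fc_missing = length(known) < 3L
      )
    })
}

#' Score motifs with the weighted, max-normalized multi-objective function
#'
#' For weighting scenario j with weights (w1..w4), motif i scores
#' \deqn{w_{1j}/2 (ND_i/\max ND + BC_i/\max BC) + w_{2j} DP_i/\max DP +
#'       w_{3j} GP_i/\max GP + w_{4j} |FC|_i/\max |FC|}
#' where every maximum is taken over the motif batch; a term whose batch
#' maximum is zero contributes zero. The halving of the topological pair
#' avoids over-emphasizing topology relative to the three non-topological
#' properties.
#'
#' @param features Feature tibble from [featurize_motifs()].
#' @param scenarios One or more weighting scenarios
#'   ([read_weight_scenarios()] tibble, or a single-row data frame with
#'   `id`, `w1..w4`).
#' @return A tibble with columns `scenario`, `motif_id`, `score`, sorted by
#'   scenario then score (descending, ties by motif id).
#' @export
score_motifs <- function(features, scenarios) {
  stopifnot(nrow(features) > 0)
  scenarios <- tibble::as_tibble(scenarios)
  norm <- function(x) {
    m <- max(x)
    if (m <= 0) rep(0, length(x)) else x / m
  }
  nd <- norm(features$nd); bc <- norm(features$bc)
  dp <- norm(as.numeric(features$dp)); gp <- norm(features$gp)
  fcn <- norm(features$absfc)
  out <- purrr::pmap_dfr(scenarios[c("id", "w1", "w2", "w3", "w4")],
    function(id, w1, w2, w3, w4) {
      tibble::tibble(
        scenario = id,
        motif_id = features$motif_id,
        score = (w1 / 2) * (nd + bc) + w2 * dp + w3 * gp + w4 * fcn
      )
    })
  dplyr::arrange(out, .data$scenario, dplyr::desc(.data$score),
                 .data$motif_id)
}

#' Select the top-k motifs per weighting scenario
#'
#' Ties are broken deterministically: score descending, then canonical
#' motif id ascending. The union collapses duplicate selections across
#' scenarios into a unique motif set.
#'
#' @param scores Score tibble from [score_motifs()].
#' @param k Number of motifs to keep per scenario (default 10).
#' @return A list with `selected` (tibble: `scenario`, `motif_id`, `score`,
#'   `rank`) and `unique_motifs` (character vector of distinct selected
#'   motif ids, sorted).
#' @export
select_top_motifs <- function(scores, k = 10) {
  stopifnot(k >= 1)
  n_motifs <- dplyr::n_distinct(scores$motif_id)
  if (n_motifs < k) {
    warning(sprintf("only %d motifs available; taking all (k = %d)",
                    n_motifs, k), call. = FALSE)
  }
  selected <- scores |>
    dplyr::arrange(.data$scenario, dplyr::desc(.data$score),
                   .data$motif_id) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  list(selected = selected,
       unique_motifs = sort(unique(selected$motif_id)))
}
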