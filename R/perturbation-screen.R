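#' Baseline stimulus-response of a calibrated model
#'
#' Computes the steady state under the model's own input clamps (no
#' intervention) and its EMT level; this is the reference all perturbation
#' deltas are taken against.
#'
#' @param model A calibrated [boolean_model()] with marker metadata.
#' @return A one-row screen tibble (see [single_screen()] for columns).
#' @export
baseline_response <- function(model) {
  row <- screen_row(model, interventions = NULL, label = "(baseline)")
  if (is.na(row$zeb1) || is.na(row$cdh1) || is.na(row$vim) ||
      is.na(row$snai1)) {
    warning("baseline leaves marker(s) unknown; EMT reported as interval",
            call. = FALSE)
  }
  row$delta_lo <- 0L
  row$delta_hi <- 0L
  row
}

screen_candidates <- function(model, candidates) {
  if (!is.null(candidates)) {
    markers <- unname(model$markers)
    if (any(candidates %in% markers)) {
      stop("marker node(s) cannot be perturbation candidates: ",
           paste(intersect(candidates, markers), collapse = ", "),
           call. = FALSE)
    }
    return(candidates)
  }
  if (is.null(model$layers)) {
    return(setdiff(model$nodes, unname(model$markers)))
  }
  model$layers$id[model$layers$layer == "regulatory"]
}

screen_row <- function(model, interventions, label) {
  st <- steady_state(model, interventions)
  mk <- validate_markers(model$markers %||% emt_markers())
  emt <- emt_level(st, mk)
  tibble::tibble(
    intervention = label,
    zeb1 = unname(st[mk["zeb1"]]), cdh1 = unname(st[mk["cdh1"]]),
    vim = unname(st[mk["vim"]]), snai1 = unname(st[mk["snai1"]]),
    emt_lo = emt$lo, emt_hi = emt$hi)
}

add_delta <- function(tbl, base_emt) {
  tbl$delta_lo <- tbl$emt_lo - base_emt$hi
  tbl$delta_hi <- tbl$emt_hi - base_emt$lo
  tbl
}

intervention_label <- function(nodes, values) {
  paste(paste0(nodes, "=", values), collapse = ",")
}

#' Single-perturbation screen
#'
#' Clamps each candidate node to 0 (sustained inhibition) and to 1
#' (sustained activation), recomputes the steady state, and records the
#' resulting marker states and EMT level. Candidates default to the
#' regulatory-layer nodes (markers are never perturbed). Output is sorted
#' by EMT ascending, then intervention label.
#'
#' @param model A calibrated [boolean_model()].
#' @param candidates Character vector of candidate nodes (default: the
#'   regulatory layer).
#' @return A tibble with columns `intervention`, the four marker states
#'   (`zeb1`, `cdh1`, `vim`, `snai1`), `emt_lo`, `emt_hi`, `delta_lo`,
#'   `delta_hi` (interval arithmetic against the baseline).
#' @export
single_screen <- function(model, candidates = NULL) {
  candidates <- screen_candidates(model, candidates)
  base <- emt_of(model, NULL)
  grid <- tidyr::expand_grid(node = sort(candidates), value = c(0, 1))
  rows <- purrr::pmap_dfr(grid, function(node, value) {
    iv <- stats::setNames(value, node)
    screen_row(model, iv, intervention_label(node, value))
  })
  rows <- add_delta(rows, base)
  dplyr::arrange(rows, .data$emt_lo, .data$emt_hi, .data$intervention)
}

emt_of <- function(model, interventions) {
  st <- steady_state(model, interventions)
  emt_level(st, validate_markers(model$markers %||% emt_markers()))
}

#' Double-perturbation screen
#'
#' Evaluates every unordered candidate pair under all four clamp value
#' combinations. A hard cap of 10,000 steady-state evaluations guards
#' against combinatorial explosion; restrict `candidates` to stay under
#' it. Pairs achieving the minimum EMT are flagged.
#'
#' @inheritParams single_screen
#' @return A screen tibble as in [single_screen()] with an extra logical
#'   column `at_minimum`.
#' @export
double_screen <- function(model, candidates = NULL) {
  candidates <- sort(screen_candidates(model, candidates))
  n <- length(candidates)
  if (n < 2L) stop("need at least two candidates", call. = FALSE)
  n_eval <- choose(n, 2) * 4
  if (n_eval > 10000) {
    stop("double screen would need ", n_eval, " evaluations (cap 10000); ",
         "restrict `candidates`", call. = FALSE)
  }
  base <- emt_of(model, NULL)
  pairs <- utils::combn(candidates, 2, simplify = FALSE)
  vals <- expand.grid(v1 = c(0, 1), v2 = c(0, 1))
  rows <- purrr::map_dfr(pairs, function(p) {
    purrr::pmap_dfr(vals, function(v1, v2) {
      iv <- stats::setNames(c(v1, v2), p)
      screen_row(model, iv, intervention_label(p, c(v1, v2)))
    })
  })
  rows <- dplyr::distinct(rows, .data$intervention, .keep_all = TRUE)
  rows <- add_delta(rows, base)
  rows <- dplyr::arrange(rows, .data$emt_lo, .data$emt_hi,
                         .data$intervention)
  rows$at_minimum <- rows$emt_lo == min(rows$emt_lo) &
    rows$emt_hi == min(rows$emt_hi[rows$emt_lo == min(rows$emt_lo)])
  rows
}

#' Single-failure robustness analysis
#'
#' Interprets a failure as a sustained flip of one regulatory node to the
#' value opposite its baseline steady state (nodes with unknown baseline
#' are tested at both values) and asks whether the EMT level changes.
#' Failures model mutation-type events, so miRNA-species nodes are
#' excluded by default; set `include_mirna = TRUE` to flip them too.
#' When unknown markers persist, EMT levels are compared by interval
#' midpoint.
#'
#' @param model A calibrated [boolean_model()].
#' @param include_mirna Also fail miRNA nodes (default `FALSE`).
#' @param candidates Optional explicit node set (default: regulatory
#'   layer, minus miRNAs unless included).
#' @return A list with `fragile_nodes` (ids whose failure changes EMT),
#'   `tested` (count), and `details` (per-node tibble).
#' @export
robustness_analysis <- function(model, include_mirna = FALSE,
                                candidates = NULL) {
  candidates <- screen_candidates(model, candidates)
  if (!include_mirna && !is.null(model$species)) {
    candidates <- candidates[model$species[candidates] != "miRNA"]
  }
  base_state <- steady_state(model)
  base <- emt_of(model, NULL)
  details <- purrr::map_dfr(sort(candidates), function(nd) {
    b <- base_state[[nd]]
    test_vals <- if (is.na(b)) c(0, 1) else 1 - b
    purrr::map_dfr(test_vals, function(v) {
      emt <- emt_of(model, stats::setNames(v, nd))
      tibble::tibble(node = nd, baseline = b, failed_to = v,
                     emt_lo = emt$lo, emt_hi = emt$hi,
                     fragile = emt_midpoint(emt) != emt_midpoint(base))
    })
  })
  list(fragile_nodes = sort(unique(details$node[details$fragile])),
       tested = length(candidates),
       details = details)
}

#' Minimal intervention sets optimizing the EMT level
#'
#' Exhaustively searches intervention sets of size up to `max_size`
#' (1 or 2) for those achieving the minimal (or maximal) reachable EMT
#' level, smallest sets first. The unperturbed baseline counts as the
#' empty set, so if no intervention improves on it only the baseline is
#' returned. Intervals from unknown markers are compared by midpoint.
#'
#' @param model A calibrated [boolean_model()].
#' @param max_size Maximum intervention set size, 1 or 2.
#' @param objective `"minimize"` (default) or `"maximize"` the EMT level.
#' @param candidates Candidate nodes (default: regulatory layer).
#' @return A tibble of optimal intervention sets: `intervention`, `size`,
#'   `emt_lo`, `emt_hi`.
#' @export
find_minimal_interventions <- function(model, max_size = 1,
                                       objective = c("minimize", "maximize"),
                                       candidates = NULL) {
  objective <- match.arg(objective)
  stopifnot(max_size %in% c(1, 2))
  candidates <- screen_candidates(model, candidates)
  base <- emt_of(model, NULL)
  results <- tibble::tibble(intervention = "(baseline)", size = 0L,
                            emt_lo = base$lo, emt_hi = base$hi)
  if (length(candidates)) {
    s1 <- single_screen(model, candidates)
    results <- dplyr::bind_rows(
      results,
      dplyr::transmute(s1, intervention = .data$intervention, size = 1L,
                       emt_lo = .data$emt_lo, emt_hi = .data$emt_hi))
    if (max_size >= 2 && length(candidates) >= 2) {
      s2 <- double_screen(model, candidates)
      results <- dplyr::bind_rows(
        results,
        dplyr::transmute(s2, intervention = .data$intervention, size = 2L,
                         emt_lo = .data$emt_lo, emt_hi = .data$emt_hi))
    }
  }
  mid <- (results$emt_lo + results$emt_hi) / 2
  best <- if (objective == "minimize") min(mid) else max(mid)
  out <- results[mid == best, ]
  out <- dplyr::arrange(out, .data$size, .data$intervention)
  # minimality: drop any set that contains a smaller optimal set
  smaller <- character(0)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$intervention[i], ",", fixed = TRUE)[[1]]
    keep[i] <- !any(parts %in% smaller) || out$size[i] == min(out$size)
    if (keep[i]) smaller <- union(smaller, parts)
  }
  out[keep, ]
}
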