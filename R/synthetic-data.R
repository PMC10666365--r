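#' Parameters for a synthetic regulatory-network scenario
#'
#' Describes a seeded random signed digraph with planted three-node
#' feedback loops, in-degree-0 receptor nodes wired into the planted
#' loops, four designated marker nodes wired from regulatory nodes, and a
#' fold-change profile whose signs equal the steady states of a
#' ground-truth Boolean model, with a controllable fraction of flipped
#' signs. All generators are pure functions of (seed, parameters).
#'
#' @param seed Integer RNG seed.
#' @param n_nodes Number of regulatory-layer nodes (receptors and the
#'   four markers are added on top).
#' @param n_planted_loops Number of distinct 3-cycles inserted.
#' @param edge_density Probability of each additional ordered regulatory
#'   edge.
#' @param sign_mix Probabilities (activation, inhibition, neutral),
#'   summing to 1, for random edge signs; planted-loop and wiring edges
#'   are drawn from the non-neutral part.
#' @param n_receptors Number of in-degree-0 receptor nodes.
#' @param fc_noise Fraction of fold-change signs flipped (0 to 1).
#' @param fc_magnitude Log-normal scale of |log2FC| magnitudes.
#' @param p_mirna Fraction of regulatory nodes flagged as miRNA species.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L, n_nodes = 30L,
                               n_planted_loops = 5L, edge_density = 0.05,
                               sign_mix = c(0.6, 0.3, 0.1),
                               n_receptors = 10L, fc_noise = 0,
                               fc_magnitude = 1, p_mirna = 0.15) {
  stopifnot(n_nodes >= 4L, n_planted_loops >= 0L,
            edge_density > 0, edge_density < 1,
            length(sign_mix) == 3L, abs(sum(sign_mix) - 1) < 1e-9,
            fc_noise >= 0, fc_noise <= 1, fc_magnitude > 0)
  if (n_planted_loops > choose(n_nodes, 3)) {
    stop("cannot plant ", n_planted_loops, " distinct loops among ",
         n_nodes, " nodes", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_planted_loops = as.integer(n_planted_loops),
                 edge_density = edge_density, sign_mix = sign_mix,
                 n_receptors = as.integer(n_receptors),
                 fc_noise = fc_noise, fc_magnitude = fc_magnitude,
                 p_mirna = p_mirna),
            class = "synthetic_scenario")
}

nonneutral_sign <- function(n, sign_mix) {
  p <- sign_mix[1:2] / sum(sign_mix[1:2])
  sample(c(1L, -1L), n, replace = TRUE, prob = p)
}

#' Generate a synthetic signed network with planted feedback loops
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `network` (a [signed_network()] with node kinds and
#'   species assigned) and `planted_motifs` (canonical motif tibble of the
#'   inserted 3-cycles).
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::local_seed(scenario$seed)
  reg <- sprintf("G%03d", seq_len(scenario$n_nodes))
  rec <- if (scenario$n_receptors > 0)
    sprintf("R%02d", seq_len(scenario$n_receptors)) else character()
  mks <- c("MZEB1", "MCDH1", "MVIM", "MSNAI1")

  # planted distinct 3-cycles (canonical triples, non-neutral signs)
  planted_edges <- tibble::tibble(from = character(), to = character(),
                                  sign = integer())
  triples <- list()
  seen <- character()
  while (length(triples) < scenario$n_planted_loops) {
    tri <- sort(sample(reg, 3L))
    k <- paste(tri, collapse = "|")
    if (k %in% seen) next
    seen <- c(seen, k)
    triples[[length(triples) + 1L]] <- tri
    planted_edges <- dplyr::bind_rows(planted_edges, tibble::tibble(
      from = tri, to = tri[c(2, 3, 1)],
      sign = nonneutral_sign(3L, scenario$sign_mix)))
  }

  # random background edges among regulatory nodes
  grid <- expand.grid(from = reg, to = reg, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  pick <- stats::runif(nrow(grid)) < scenario$edge_density
  bg <- tibble::as_tibble(grid[pick, ])
  bg$sign <- sample(c(1L, -1L, 0L), nrow(bg), replace = TRUE,
                    prob = scenario$sign_mix)
  edges <- dplyr::bind_rows(planted_edges, bg) |>
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)

  # receptors: in-degree 0, wired into planted-loop nodes (or any
  # regulatory node when nothing is planted)
  targets_pool <- if (length(seen)) unique(unlist(triples)) else reg
  for (r in rec) {
    k <- sample(1:3, 1)
    tg <- sample(targets_pool, min(k, length(targets_pool)))
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = r, to = tg,
      sign = nonneutral_sign(length(tg), scenario$sign_mix)))
  }
  # markers: wired from regulatory nodes, no outgoing edges
  for (m in mks) {
    k <- sample(1:3, 1)
    src <- sample(reg, k)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = src, to = m,
      sign = nonneutral_sign(k, scenario$sign_mix)))
  }
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)

  n_mirna <- round(scenario$p_mirna * length(reg))
  mirna <- if (n_mirna > 0) sample(reg, n_mirna) else character()
  nodes <- tibble::tibble(
    id = c(reg, rec, mks),
    kind = c(rep("regulatory", length(reg)), rep("receptor", length(rec)),
             rep("marker", length(mks))),
    species = c(ifelse(reg %in% mirna, "miRNA", "protein"),
                rep("protein", length(rec) + length(mks))))
  net <- signed_network(edges, nodes)

  planted <- if (length(triples)) {
    sgn <- stats::setNames(net$edges$sign,
                           paste(net$edges$from, net$edges$to, sep = "\r"))
    rows <- purrr::map_dfr(triples, function(tri) {
      s <- unname(sgn[paste(tri, tri[c(2, 3, 1)], sep = "\r")])
      tibble::tibble(motif_id = paste(tri, collapse = "|"),
                     n1 = tri[1], n2 = tri[2], n3 = tri[3],
                     s12 = s[1], s23 = s[2], s31 = s[3])
    })
    prod_sign <- rows$s12 * rows$s23 * rows$s31
    rows$loop_sign <- ifelse(prod_sign == 0L, "undetermined",
                             ifelse(prod_sign > 0L, "positive", "negative"))
    dplyr::arrange(rows, .data$motif_id)
  } else empty_motif_tbl()

  list(network = net, planted_motifs = planted)
}

#' Generate a ground-truth Boolean model and matching fold changes
#'
#' Assigns a random gate (AND or OR over the edge-sign literals) to every
#' multi-regulator node, identity gates to single-regulator nodes, and
#' random 0/1 clamps to input (0-regulator) nodes; computes the model's
#' logical steady state; and emits a fold-change profile whose sign equals
#' each node's steady-state value (1 positive, 0 negative), with log-normal
#' magnitudes and a fraction `fc_noise` of signs flipped. Nodes left
#' unknown by feedback cycles get missing fold changes.
#'
#' @param network A [signed_network()] from [generate_network()].
#' @param scenario The same [synthetic_scenario()].
#' @return A list with `model` (a [boolean_model()] whose `$truth_gates`
#'   records the planted gates), `fc` (fold-change tibble) and
#'   `flipped` (ids whose FC sign was noise-flipped).
#' @export
generate_ground_truth_model <- function(network, scenario) {
  withr::local_seed(scenario$seed + 1L)
  edges <- network$edges[network$edges$sign != 0L, ]
  nodes <- network$nodes$id
  rules <- list(); clamps <- numeric(0)
  for (nd in nodes) {
    inc <- edges[edges$to == nd, ]
    nr <- nrow(inc)
    if (nr == 0L) {
      rules[[nd]] <- list(gate = "INPUT", regulators = character(),
                          polarity = integer())
      clamps[nd] <- sample(c(0, 1), 1)
    } else if (nr == 1L) {
      rules[[nd]] <- list(gate = "IDENTITY", regulators = inc$from,
                          polarity = inc$sign)
    } else {
      rules[[nd]] <- list(gate = sample(c("AND", "OR"), 1),
                          regulators = inc$from, polarity = inc$sign)
    }
  }
  markers_present <- all(c("MZEB1", "MCDH1", "MVIM", "MSNAI1") %in% nodes)
  model <- boolean_model(
    rules, clamps = clamps,
    layers = tibble::tibble(
      id = nodes,
      layer = dplyr::case_when(
        network$nodes$kind == "receptor" ~ "input",
        network$nodes$kind == "marker" ~ "output-marker",
        TRUE ~ "regulatory")),
    markers = if (markers_present)
      emt_markers("MZEB1", "MCDH1", "MVIM", "MSNAI1") else NULL,
    species = stats::setNames(network$nodes$species, network$nodes$id))
  model$truth_gates <- vapply(model$rules, `[[`, "", "gate")

  lss <- logical_steady_state(model)
  known <- names(lss)[!is.na(lss)]
  mag <- stats::rlnorm(length(known), meanlog = log(scenario$fc_magnitude),
                       sdlog = 0.5)
  sgn <- ifelse(lss[known] == 1, 1, -1)
  flip <- stats::runif(length(known)) < scenario$fc_noise
  sgn[flip] <- -sgn[flip]
  fc <- tibble::tibble(id = nodes, log2fc = NA_real_)
  fc$log2fc[match(known, fc$id)] <- sgn * mag
  model$fc_state <- fc_sign_state(fc, nodes)
  list(model = model, fc = fc, flipped = known[flip])
}

#' Generate per-node annotations for a synthetic network
#'
#' Gene-prioritization scores are uniform on \[0, 5\] and disease-pathway
#' membership is Bernoulli(`p_member`), emulating externally supplied
#' annotation tables.
#'
#' @param network A [signed_network()].
#' @param scenario A [synthetic_scenario()] (drives the seed).
#' @param p_member Membership probability (default 0.3).
#' @return An annotation tibble (`id`, `dp_member`, `gp_score`).
#' @export
generate_annotations <- function(network, scenario, p_member = 0.3) {
  withr::local_seed(scenario$seed + 2L)
  ids <- network$nodes$id
  tibble::tibble(
    id = ids,
    dp_member = stats::runif(length(ids)) < p_member,
    gp_score = stats::runif(length(ids), 0, 5))
}

#' One-call synthetic dataset
#'
#' Bundles [generate_network()], [generate_ground_truth_model()] and
#' [generate_annotations()] for a scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list: `network`, `planted_motifs`, `model`, `fc`,
#'   `annotations`, `flipped`.
#' @export
synthetic_dataset <- function(scenario = synthetic_scenario()) {
  gn <- generate_network(scenario)
  gt <- generate_ground_truth_model(gn$network, scenario)
  annot <- generate_annotations(gn$network, scenario)
  list(network = gn$network, planted_motifs = gn$planted_motifs,
       model = gt$model, fc = gt$fc, annotations = annot,
       flipped = gt$flipped)
}

#' Compare inferred gates against the planted ground truth
#'
#' A node counts toward recovery only where AND and OR are distinguishable
#' on the realized regulator states (their outputs differ and the target
#' state is known); on other nodes the data cannot identify the gate.
#'
#' @param inferred A model from [infer_gates()].
#' @param truth A model from [generate_ground_truth_model()].
#' @return A list: `rate` (recovered fraction among distinguishable
#'   multi-regulator nodes; `NaN` if none), `n_distinguishable`,
#'   `n_recovered`, `details` tibble.
#' @export
gate_recovery <- function(inferred, truth) {
  lss <- logical_steady_state(truth)
  rows <- purrr::map_dfr(truth$nodes, function(nd) {
    r <- truth$rules[[nd]]
    if (!r$gate %in% c("AND", "OR")) return(NULL)
    lit <- unname(lss[r$regulators])
    lit[r$polarity == -1] <- 1 - lit[r$polarity == -1]
    or_out <- if (any(lit == 1, na.rm = TRUE)) 1
              else if (!anyNA(lit)) 0 else NA_real_
    and_out <- if (any(lit == 0, na.rm = TRUE)) 0
               else if (!anyNA(lit)) 1 else NA_real_
    distinguishable <- !is.na(or_out) && !is.na(and_out) &&
      or_out != and_out && !is.na(lss[[nd]])
    tibble::tibble(node = nd, truth_gate = r$gate,
                   inferred_gate = inferred$rules[[nd]]$gate,
                   distinguishable = distinguishable,
                   recovered = distinguishable &&
                     r$gate == inferred$rules[[nd]]$gate)
  })
  nd <- sum(rows$distinguishable)
  list(rate = if (nd) sum(rows$recovered) / nd else NaN,
       n_distinguishable = nd, n_recovered = sum(rows$recovered),
       details = rows)
}
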