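# Brute-force oracles, deliberately independent of the implementation
# paths (no igraph, no adjacency-list shortcuts).

# all directed 3-cycles by iterating every ordered node triple
oracle_3cycles <- function(net) {
  ids <- net$nodes$id
  has <- function(a, b) any(net$edges$from == a & net$edges$to == b)
  found <- character()
  for (a in ids) for (b in ids) for (ce in ids) {
    if (a == b || b == ce || a == ce) next
    if (has(a, b) && has(b, ce) && has(ce, a)) {
      rot <- c(a, b, ce)
      k <- which(rot == min(rot))[1]
      canon <- rot[((k - 1 + 0:2) %% 3) + 1]
      found <- c(found, paste(canon, collapse = "|"))
    }
  }
  sort(unique(found))
}

# all-pairs shortest-path betweenness via per-source BFS path counts
oracle_betweenness <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  succ <- lapply(ids, function(a) net$edges$to[net$edges$from == a &
                                                 net$edges$to != a])
  names(succ) <- ids
  bfs <- function(s) {
    dist <- stats::setNames(rep(Inf, n), ids)
    sigma <- stats::setNames(rep(0, n), ids)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- character()
      for (u in frontier) for (v in succ[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(ids, bfs); names(sp) <- ids
  bc <- stats::setNames(rep(0, n), ids)
  for (s in ids) for (t in ids) {
    if (s == t || sp[[s]]$sigma[t] == 0) next
    for (v in ids) {
      if (v == s || v == t) next
      if (is.finite(sp[[s]]$dist[v]) && is.finite(sp[[v]]$dist[t]) &&
          sp[[s]]$dist[v] + sp[[v]]$dist[t] == sp[[s]]$dist[t]) {
        bc[v] <- bc[v] + sp[[s]]$sigma[v] * sp[[v]]$sigma[t] /
          sp[[s]]$sigma[t]
      }
    }
  }
  denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  bc / denom
}

# two-valued evaluation of an acyclic model under a full input assignment
oracle_acyclic_eval <- function(model, inputs) {
  state <- stats::setNames(rep(NA_real_, length(model$nodes)), model$nodes)
  state[names(inputs)] <- inputs
  cl <- model$clamps[!is.na(model$clamps)]
  state[names(cl)] <- cl
  for (pass in seq_along(model$nodes)) {
    for (nd in model$nodes) {
      if (!is.na(state[nd])) next
      r <- model$rules[[nd]]
      v <- unname(state[r$regulators])
      if (anyNA(v)) next
      v[r$polarity == -1] <- 1 - v[r$polarity == -1]
      state[nd] <- switch(r$gate,
        IDENTITY = v, AND = as.numeric(all(v == 1)),
        OR = as.numeric(any(v == 1)), INPUT = NA_real_)
    }
  }
  state
}

# matrix of two-valued evaluations over every completion of the free
# inputs (nodes x completions); a model with no free inputs has exactly
# one completion
oracle_completions <- function(model) {
  free <- names(model$clamps)[is.na(model$clamps)]
  if (!length(free)) {
    return(matrix(oracle_acyclic_eval(model, numeric(0)),
                  dimnames = list(model$nodes, NULL)))
  }
  grid <- expand.grid(rep(list(0:1), length(free)))
  vapply(seq_len(nrow(grid)), function(i) {
    oracle_acyclic_eval(model,
                        stats::setNames(as.numeric(grid[i, ]), free))
  }, stats::setNames(numeric(length(model$nodes)), model$nodes))
}

# random signed digraph (plain base R sampling)
random_net <- function(n_nodes, p_edge, seed, p_neutral = 0.1) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  keep <- runif(nrow(grid)) < p_edge
  edges <- grid[keep, ]
  edges$sign <- sample(c(1L, -1L, 0L), nrow(edges), replace = TRUE,
                       prob = c((1 - p_neutral) * 0.6,
                                (1 - p_neutral) * 0.4, p_neutral))
  signed_network(edges, data.frame(id = ids))
}

# random acyclic boolean model over a layered DAG
random_acyclic_model <- function(n_nodes, seed, n_inputs = 3,
                                 p_free = 0.3) {
  set.seed(seed)
  ids <- sprintf("B%02d", seq_len(n_nodes))
  rules <- list(); clamps <- numeric(0)
  for (i in seq_along(ids)) {
    nd <- ids[i]
    if (i <= n_inputs) {
      rules[[nd]] <- list(gate = "INPUT", regulators = character(),
                          polarity = integer())
      clamps[nd] <- if (runif(1) < p_free) NA_real_ else sample(0:1, 1)
    } else {
      k <- sample(1:min(3, i - 1), 1)
      regs <- sample(ids[seq_len(i - 1)], k)
      pol <- sample(c(1L, -1L), k, replace = TRUE)
      gate <- if (k == 1) "IDENTITY" else sample(c("AND", "OR"), 1)
      rules[[nd]] <- list(gate = gate, regulators = regs, polarity = pol)
    }
  }
  boolean_model(rules, clamps = clamps)
}

fig2_network <- function() {
  signed_network(data.frame(
    from = c("X1", "X4", "X2", "X4", "X3"),
    to   = c("X2", "X2", "X3", "X3", "X4"),
    sign = c(1L, -1L, 1L, 1L, 1L)))
}

fig2_fc <- function() {
  tibble::tibble(id = c("X1", "X2", "X3", "X4"),
                 log2fc = c(1.8, -1.2, 0.9, 1.5))
}

fig2_model <- function() infer_gates(fig2_network(), fig2_fc())
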