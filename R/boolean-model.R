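#' Construct a Boolean model
#'
#' A Boolean model maps every node to a gate over signed literals:
#' `INPUT` (no regulators; its value comes from a clamp, or stays free),
#' `IDENTITY` (one literal), or an `AND`/`OR` combination of two or more
#' literals. A literal is the regulator itself (activator, edge sign +1)
#' or its negation (inhibitor, edge sign -1). Node states are
#' three-valued: 0, 1, or `NA` (unknown), combined with Kleene semantics.
#'
#' @param rules Named list; each element is a list with fields `gate`
#'   (`"INPUT"`, `"IDENTITY"`, `"AND"`, `"OR"`), `regulators` (character)
#'   and `polarity` (same length, values +1/-1).
#' @param clamps Named numeric vector of input clamps (0, 1 or `NA` for
#'   free); clamped nodes carry their clamp value at every step,
#'   overriding their gate.
#' @param layers,markers,species Optional metadata carried from the core
#'   network (layer tibble, [emt_markers()] mapping, named species
#'   vector).
#' @param fc_state Optional named 0/1/`NA` state derived from fold-change
#'   signs, used to seed synchronous simulation of cyclic models.
#' @return An object of class `boolean_model`.
#' @export
boolean_model <- function(rules, clamps = NULL, layers = NULL,
                          markers = NULL, species = NULL, fc_state = NULL) {
  nodes <- names(rules)
  stopifnot(length(nodes) == length(rules), !anyDuplicated(nodes))
  for (nd in nodes) {
    r <- rules[[nd]]
    nr <- length(r$regulators)
    ok <- switch(r$gate,
      INPUT = nr == 0L, IDENTITY = nr == 1L,
      AND = nr >= 2L, OR = nr >= 2L, FALSE)
    if (!ok) {
      stop("node ", nd, ": gate ", r$gate, " with ", nr, " regulator(s)",
           call. = FALSE)
    }
    bad <- setdiff(r$regulators, nodes)
    if (length(bad)) {
      stop("node ", nd, ": unknown regulator(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (nr && (length(r$polarity) != nr || !all(r$polarity %in% c(-1, 1)))) {
      stop("node ", nd, ": polarity must be +1/-1 per regulator",
           call. = FALSE)
    }
  }
  if (is.null(clamps)) clamps <- stats::setNames(numeric(0), character(0))
  stopifnot(all(names(clamps) %in% nodes),
            all(is.na(clamps) | clamps %in% c(0, 1)))
  structure(
    list(rules = rules, clamps = clamps, nodes = nodes, layers = layers,
         markers = markers, species = species, fc_state = fc_state,
         calibration = NULL),
    class = "boolean_model")
}

#' @export
print.boolean_model <- function(x, ...) {
  gates <- vapply(x$rules, `[[`, "", "gate")
  cat("<boolean_model> ", length(x$nodes), " nodes (",
      paste(names(table(gates)), table(gates), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  cl <- x$clamps[!is.na(x$clamps)]
  if (length(cl)) {
    cat("  clamps: ", paste(names(cl), cl, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Kleene three-valued gate evaluation; `state` is named 0/1/NA
eval_gate <- function(rule, state) {
  if (rule$gate == "INPUT") return(NA_real_)
  v <- unname(state[rule$regulators])
  v[rule$polarity == -1] <- 1 - v[rule$polarity == -1]
  switch(rule$gate,
    IDENTITY = v,
    AND = if (any(v == 0, na.rm = TRUE)) 0
          else if (!anyNA(v)) 1 else NA_real_,
    OR  = if (any(v == 1, na.rm = TRUE)) 1
          else if (!anyNA(v)) 0 else NA_real_)
}

apply_model <- function(model, state, clamps) {
  new <- state
  for (nd in model$nodes) {
    cl <- clamps[nd]
    new[[nd]] <- if (!is.na(cl)) cl else eval_gate(model$rules[[nd]], state)
  }
  new
}

full_clamps <- function(model, interventions = NULL) {
  cl <- stats::setNames(rep(NA_real_, length(model$nodes)), model$nodes)
  cl[names(model$clamps)] <- model$clamps
  if (length(interventions)) {
    bad <- setdiff(names(interventions), model$nodes)
    if (length(bad)) stop("unknown intervention node(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cl[names(interventions)] <- unlist(interventions)
  }
  cl
}

#' Three-valued logical steady state (LSS)
#'
#' Starts from clamps known and everything else unknown, then repeatedly
#' re-evaluates every gate under Kleene three-valued semantics until no
#' node changes. Information only grows during the iteration, so the
#' result is the unique maximal partial fixed point, independent of
#' update order. Nodes not determined by the clamps (e.g. inside
#' feedback cycles) stay unknown.
#'
#' @param model A [boolean_model()].
#' @param interventions Optional named 0/1 vector of additional clamps
#'   (overriding the model's own clamps).
#' @return Named numeric state vector (0/1/`NA`) over all model nodes.
#' @export
logical_steady_state <- function(model, interventions = NULL) {
  cl <- full_clamps(model, interventions)
  state <- stats::setNames(rep(NA_real_, length(model$nodes)), model$nodes)
  state[!is.na(cl)] <- cl[!is.na(cl)]
  repeat {
    new <- apply_model(model, state, cl)
    if (identical(new, state)) return(state)
    state <- new
  }
}

#' Synchronous simulation to an attractor
#'
#' Iterates the synchronous update map from a full initial state (clamped
#' nodes held fixed at every step) until a previously seen state repeats,
#' and returns the attractor: a fixed point (period 1) or a cycle of
#' states.
#'
#' @param model A [boolean_model()].
#' @param initial Named state vector; must be 0/1 on all free
#'   (non-clamped) nodes for guaranteed termination. Unknown (`NA`)
#'   entries are allowed and propagate with Kleene semantics.
#' @param max_steps Maximum iterations before giving up (default
#'   `4 * number of nodes`, ample for the short transients of regulatory
#'   cores; raise it for adversarial models).
#' @param interventions Optional named 0/1 clamp vector.
#' @return A list with `attractor` (list of named states), `period`, and
#'   `n_steps` (steps taken until the first repeat).
#' @export
simulate_synchronous <- function(model, initial, max_steps = NULL,
                                 interventions = NULL) {
  cl <- full_clamps(model, interventions)
  if (is.null(max_steps)) max_steps <- 4L * length(model$nodes)
  state <- stats::setNames(rep(NA_real_, length(model$nodes)), model$nodes)
  state[names(initial)] <- unlist(initial)
  state[!is.na(cl)] <- cl[!is.na(cl)]
  key <- function(s) paste(ifelse(is.na(s), "u", s), collapse = "")
  keys <- key(state)
  trace <- list(state)
  for (step in seq_len(max_steps)) {
    state <- apply_model(model, state, cl)
    hit <- match(key(state), keys)
    if (!is.na(hit)) {
      cycle <- trace[hit:length(trace)]
      return(list(attractor = cycle, period = length(cycle),
                  n_steps = step))
    }
    keys <- c(keys, key(state))
    trace[[step + 1L]] <- state
  }
  stop("no attractor found within ", max_steps, " steps", call. = FALSE)
}

#' Model steady state with fold-change-seeded cycle resolution
#'
#' First computes the three-valued [logical_steady_state()]. If feedback
#' cycles leave nodes unknown and a fold-change-derived seed state is
#' available, the remaining nodes are seeded with their fold-change signs
#' and the synchronous map is iterated to its attractor; nodes constant
#' across the attractor get that value, oscillating nodes stay unknown.
#' This is the steady-state convention used by all screening functions.
#'
#' @inheritParams logical_steady_state
#' @param seed_state Named 0/1/`NA` seed for cycle nodes (default: the
#'   model's fold-change sign state).
#' @return Named numeric state vector (0/1/`NA`).
#' @export
steady_state <- function(model, interventions = NULL,
                         seed_state = model$fc_state) {
  lss <- logical_steady_state(model, interventions)
  cl <- full_clamps(model, interventions)
  open <- is.na(lss) & is.na(cl)
  if (!any(open) || is.null(seed_state)) return(lss)
  init <- lss
  seeds <- intersect(names(seed_state)[!is.na(seed_state)],
                     names(init)[open])
  if (!length(seeds)) return(lss)
  init[seeds] <- seed_state[seeds]
  sim <- simulate_synchronous(model, init, interventions = interventions)
  att <- do.call(rbind, sim$attractor)
  vals <- apply(att, 2, function(col) {
    if (anyNA(col) || length(unique(col)) > 1L) NA_real_ else col[1]
  })
  out <- lss
  out[is.na(out)] <- vals[names(out)[is.na(out)]]
  out
}

#' Infer calibrated Boolean gates from a core network and fold changes
#'
#' Translates a core network into a Boolean model whose gates are
#' calibrated against fold-change signs (positive FC = state 1, negative
#' FC = state 0; missing or zero FC = unknown):
#' * 0 regulators: `INPUT`, clamped to the node's FC sign (free when
#'   unknown);
#' * 1 regulator: `IDENTITY` (negated literal for an inhibitor);
#' * 2+ regulators: both candidate gates -- OR of the literals and AND of
#'   the literals -- are evaluated on the regulators' FC-sign states; the
#'   candidate whose output matches the target's FC sign is chosen. A tie
#'   goes to OR (independent regulation is the default reading); if
#'   neither matches, OR is kept and the node is flagged `unresolved`;
#'   if the comparison is impossible (target or all regulator FCs
#'   unknown), OR is kept and the node is flagged `uncalibrated`.
#'
#' Neutral (sign 0) edges are excluded from gates by default.
#'
#' @param core A `core_network` (or plain `signed_network`; all nodes then
#'   count as regulatory).
#' @param fc Fold-change tibble ([read_fold_changes()]).
#' @param include_neutral If `TRUE`, sign-0 edges join gates as
#'   activators.
#' @return A [boolean_model()] whose `$calibration` field is the per-node
#'   report tibble (`node`, `gate`, `n_regulators`, `status`, `note`).
#' @export
infer_gates <- function(core, fc, include_neutral = FALSE) {
  stopifnot(inherits(core, "signed_network"))
  edges <- core$edges
  if (!include_neutral) edges <- edges[edges$sign != 0L, ]
  else edges$sign[edges$sign == 0L] <- 1L
  nodes <- core$nodes$id
  fcs <- fc_sign_state(fc, nodes)

  rules <- list()
  clamps <- numeric(0)
  rep_rows <- list()
  for (nd in nodes) {
    inc <- edges[edges$to == nd, ]
    nr <- nrow(inc)
    s_t <- fcs[[nd]]
    if (nr == 0L) {
      rules[[nd]] <- list(gate = "INPUT", regulators = character(),
                          polarity = integer())
      clamps[nd] <- s_t
      status <- "input"
      note <- if (is.na(s_t)) "free (FC sign unknown)" else
        paste0("clamped to ", s_t)
    } else if (nr == 1L) {
      rules[[nd]] <- list(gate = "IDENTITY", regulators = inc$from,
                          polarity = inc$sign)
      status <- "identity"
      note <- ""
    } else {
      lit <- unname(fcs[inc$from])
      lit[inc$sign == -1] <- 1 - lit[inc$sign == -1]
      or_out <- if (any(lit == 1, na.rm = TRUE)) 1
                else if (!anyNA(lit)) 0 else NA_real_
      and_out <- if (any(lit == 0, na.rm = TRUE)) 0
                 else if (!anyNA(lit)) 1 else NA_real_
      or_ok <- !is.na(s_t) && !is.na(or_out) && or_out == s_t
      and_ok <- !is.na(s_t) && !is.na(and_out) && and_out == s_t
      gate <- if (and_ok && !or_ok) "AND" else "OR"
      rules[[nd]] <- list(gate = gate, regulators = inc$from,
                          polarity = inc$sign)
      if (is.na(s_t)) {
        status <- "uncalibrated"; note <- "target FC sign unknown"
      } else if (all(is.na(fcs[inc$from]))) {
        status <- "uncalibrated"; note <- "all regulator FC signs unknown"
      } else if (or_ok && and_ok) {
        status <- "tie"; note <- "OR chosen (both gates match)"
      } else if (or_ok || and_ok) {
        status <- "calibrated"; note <- ""
      } else {
        status <- "unresolved"
        note <- "neither OR nor AND matches the FC sign; OR kept"
      }
    }
    rep_rows[[nd]] <- tibble::tibble(
      node = nd, gate = rules[[nd]]$gate, n_regulators = nr,
      status = status, note = note)
  }

  layers <- if (!is.null(core$layers)) core$layers else
    tibble::tibble(id = nodes, layer = "regulatory")
  model <- boolean_model(
    rules, clamps = clamps, layers = layers,
    markers = core$markers,
    species = stats::setNames(core$nodes$species, core$nodes$id),
    fc_state = fcs)
  model$calibration <- dplyr::bind_rows(rep_rows)
  model
}

# FC sign -> state: positive 1, negative 0, zero/missing NA
fc_sign_state <- function(fc, nodes) {
  out <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  if (is.null(fc)) return(out)
  hit <- fc$id %in% nodes & !is.na(fc$log2fc) & fc$log2fc != 0
  out[fc$id[hit]] <- as.numeric(fc$log2fc[hit] > 0)
  out
}

#' Compare a model's steady state with fold-change signs
#'
#' Per node, reports whether the steady-state value matches the observed
#' fold-change sign (`match`/`mismatch`), could not be determined
#' (`undetermined`), or has no fold-change to compare (`no_fc`).
#'
#' @param model A [boolean_model()].
#' @param fc Fold-change tibble.
#' @return A tibble `node`, `state`, `fc_sign`, `status`, with a
#'   `summary` attribute counting each status.
#' @export
validate_calibration <- function(model, fc) {
  st <- steady_state(model)
  fcs <- fc_sign_state(fc, model$nodes)
  status <- dplyr::case_when(
    is.na(fcs[model$nodes]) ~ "no_fc",
    is.na(st[model$nodes]) ~ "undetermined",
    st[model$nodes] == fcs[model$nodes] ~ "match",
    TRUE ~ "mismatch")
  out <- tibble::tibble(node = model$nodes,
                        state = unname(st[model$nodes]),
                        fc_sign = unname(fcs[model$nodes]),
                        status = status)
  attr(out, "summary") <- table(status)
  out
}

#' Write a Boolean model as bnet-style rules text
#'
#' One line per node: `target, expression`, with `&` = AND, `|` = OR,
#' `!` = NOT. Input nodes are written as `target, 0`, `target, 1` or
#' `target, free`. Round-trips through [read_boolean_model()].
#'
#' @param model A [boolean_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boolean_model <- function(model, path) {
  lines <- "targets, factors"
  for (nd in model$nodes) {
    r <- model$rules[[nd]]
    rhs <- if (r$gate == "INPUT") {
      cl <- model$clamps[nd]
      if (is.na(cl)) "free" else as.character(cl)
    } else {
      lit <- ifelse(r$polarity == -1, paste0("!", r$regulators),
                    r$regulators)
      op <- switch(r$gate, IDENTITY = "", AND = " & ", OR = " | ")
      paste(lit, collapse = op)
    }
    lines <- c(lines, paste0(nd, ", ", rhs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Boolean model from bnet-style rules text
#'
#' Parses the dialect written by [write_boolean_model()]: per line
#' `target, expression` where the expression is `0`, `1`, `free`, or a
#' flat AND-only / OR-only combination of optionally negated node names.
#'
#' @param path Path to the rules file.
#' @return A [boolean_model()] (without calibration metadata).
#' @export
read_boolean_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lines <- lines[tolower(gsub("\\s", "", lines)) != "targets,factors"]
  rules <- list(); clamps <- numeric(0)
  for (ln in lines) {
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed rule line: ", ln, call. = FALSE)
    nd <- trimws(parts[1]); rhs <- trimws(parts[2])
    if (rhs %in% c("0", "1", "free")) {
      rules[[nd]] <- list(gate = "INPUT", regulators = character(),
                          polarity = integer())
      clamps[nd] <- if (rhs == "free") NA_real_ else as.numeric(rhs)
      next
    }
    has_and <- grepl("&", rhs, fixed = TRUE)
    has_or <- grepl("|", rhs, fixed = TRUE)
    if (has_and && has_or) {
      stop("mixed AND/OR expression not supported: ", ln, call. = FALSE)
    }
    toks <- trimws(strsplit(rhs, "[&|]")[[1]])
    pol <- ifelse(startsWith(toks, "!"), -1L, 1L)
    regs <- sub("^!", "", toks)
    gate <- if (length(regs) == 1L) "IDENTITY" else if (has_and) "AND"
            else "OR"
    rules[[nd]] <- list(gate = gate, regulators = regs, polarity = pol)
  }
  boolean_model(rules, clamps = clamps)
}
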