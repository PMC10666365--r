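test_that("gate inference reproduces the worked 4-node example", {
  m <- fig2_model()
  expect_equal(m$rules$X2$gate, "AND")
  expect_equal(stats::setNames(m$rules$X2$polarity, m$rules$X2$regulators),
               c(X1 = 1L, X4 = -1L))
  expect_equal(m$rules$X3$gate, "OR")
  expect_equal(m$rules$X4$gate, "IDENTITY")
  expect_equal(m$rules$X1$gate, "INPUT")
  expect_equal(unname(m$clamps["X1"]), 1)
})

test_that("single-regulator gates carry the edge polarity", {
  net <- signed_network(data.frame(from = c("A", "A"), to = c("B", "C"),
                                   sign = c(1L, -1L)))
  fc <- tibble::tibble(id = c("A", "B", "C"), log2fc = c(1, 1, -1))
  m <- infer_gates(net, fc)
  expect_equal(m$rules$B$polarity, 1L)
  expect_equal(m$rules$C$polarity, -1L)
})

test_that("unresolvable and uncalibratable gates default to OR, flagged", {
  net <- signed_network(data.frame(from = c("A", "B"), to = c("T", "T"),
                                   sign = 1L))
  # both regulators positive but target negative: neither OR nor AND fits
  fc1 <- tibble::tibble(id = c("A", "B", "T"), log2fc = c(1, 1, -1))
  m1 <- infer_gates(net, fc1)
  expect_equal(m1$rules$T$gate, "OR")
  expect_equal(m1$calibration$status[m1$calibration$node == "T"],
               "unresolved")
  # all regulator fold changes missing
  fc2 <- tibble::tibble(id = "T", log2fc = 1)
  m2 <- infer_gates(net, fc2)
  expect_equal(m2$calibration$status[m2$calibration$node == "T"],
               "uncalibrated")
})

test_that("neutral edges are excluded from gates unless requested", {
  net <- signed_network(data.frame(from = c("A", "N"), to = c("T", "T"),
                                   sign = c(1L, 0L)))
  fc <- tibble::tibble(id = c("A", "N", "T"), log2fc = c(1, -1, 1))
  m <- infer_gates(net, fc)
  expect_equal(m$rules$T$gate, "IDENTITY")
  expect_equal(m$rules$T$regulators, "A")
  m2 <- infer_gates(net, fc, include_neutral = TRUE)
  expect_setequal(m2$rules$T$regulators, c("A", "N"))
})

test_that("the worked example state (1,0,1,1) is a synchronous fixed point", {
  m <- fig2_model()
  init <- c(X1 = 1, X2 = 0, X3 = 1, X4 = 1)
  sim <- simulate_synchronous(m, init)
  expect_equal(sim$period, 1)
  expect_equal(sim$attractor[[1]][c("X1", "X2", "X3", "X4")], init)
  # and calibration matches all four fold-change signs
  vc <- validate_calibration(m, fig2_fc())
  expect_true(all(vc$status == "match"))
})

test_that("a flipped fold-change sign shows up as a mismatch", {
  fc <- fig2_fc()
  fc$log2fc[fc$id == "X3"] <- -0.9
  vc <- validate_calibration(fig2_model(), fc)  # model from clean FC
  expect_equal(vc$status[vc$node == "X3"], "mismatch")
})

test_that("negative feedback oscillates under synchronous update", {
  # self-inhibition: the minimal period-2 oscillator
  solo <- boolean_model(list(
    A = list(gate = "IDENTITY", regulators = "A", polarity = -1L)))
  expect_equal(simulate_synchronous(solo, c(A = 1))$period, 2)
  # a negative two-node loop rotates through all four states
  m <- boolean_model(list(
    A = list(gate = "IDENTITY", regulators = "B", polarity = 1L),
    B = list(gate = "IDENTITY", regulators = "A", polarity = -1L)))
  sim <- simulate_synchronous(m, c(A = 1, B = 1))
  expect_equal(sim$period, 4)
  expect_gt(sim$period, 1)  # never settles to a fixed point
})

test_that("synchronous attractors match a step-by-step replay oracle", {
  for (seed in 1:10) {
    m <- random_acyclic_model(8, seed, p_free = 0)
    init <- stats::setNames(sample(0:1, 8, TRUE), m$nodes)
    sim <- simulate_synchronous(m, init)
    # independent replay: iterate gates manually and find the repeat
    cl <- m$clamps[!is.na(m$clamps)]
    st <- init; st[names(cl)] <- cl
    hist <- list(st)
    repeat {
      nxt <- st
      for (nd in m$nodes) {
        if (nd %in% names(cl)) { nxt[nd] <- cl[nd]; next }
        r <- m$rules[[nd]]
        v <- unname(st[r$regulators])
        v[r$polarity == -1] <- 1 - v[r$polarity == -1]
        nxt[nd] <- switch(r$gate, IDENTITY = v,
                          AND = as.numeric(all(v == 1)),
                          OR = as.numeric(any(v == 1)),
                          INPUT = st[nd])
      }
      idx <- which(vapply(hist, identical, TRUE, y = nxt))
      if (length(idx)) {
        want <- hist[idx[1]:length(hist)]
        break
      }
      hist[[length(hist) + 1L]] <- nxt
      st <- nxt
    }
    expect_equal(sim$attractor, want)
  }
})

test_that("LSS: no clamps means nothing is determined", {
  m <- boolean_model(list(
    A = list(gate = "INPUT", regulators = character(),
             polarity = integer()),
    B = list(gate = "IDENTITY", regulators = "A", polarity = 1L)),
    clamps = c(A = NA_real_))
  lss <- logical_steady_state(m)
  expect_true(all(is.na(lss)))
})

test_that("LSS is a fixed point and update-order independent", {
  for (seed in 1:10) {
    m <- random_acyclic_model(10, seed)
    lss <- logical_steady_state(m)
    again <- melanocore:::apply_model(m, lss,
                                      melanocore:::full_clamps(m, NULL))
    again[names(m$clamps)[!is.na(m$clamps)]] <-
      m$clamps[!is.na(m$clamps)]
    expect_equal(again, lss)
  }
})

test_that("LSS equals truth-table evaluation on clamped acyclic models", {
  for (seed in 1:15) {
    m <- random_acyclic_model(9, seed, p_free = 0)  # all inputs clamped
    lss <- logical_steady_state(m)
    want <- oracle_acyclic_eval(m, inputs = numeric(0))
    expect_equal(lss, want)
    expect_false(anyNA(lss))
  }
})

test_that("LSS is sound against exhaustive enumeration over free inputs", {
  for (seed in 1:15) {
    m <- random_acyclic_model(9, seed, p_free = 0.6)
    lss <- logical_steady_state(m)
    states <- oracle_completions(m)
    for (nd in m$nodes) {
      vals <- unique(states[nd, ])
      if (!is.na(lss[nd])) {
        # known in LSS: every completion agrees with it
        expect_equal(vals, lss[[nd]])
      } else if (length(vals) > 1) {
        # completions disagree: LSS must not have committed
        succeed()
      }
    }
  }
})

test_that("adding a clamp consistent with the LSS never loses information", {
  for (seed in 1:10) {
    m <- random_acyclic_model(9, seed, p_free = 0.5)
    lss <- logical_steady_state(m)
    known <- names(lss)[!is.na(lss)]
    known <- setdiff(known, names(m$clamps)[!is.na(m$clamps)])
    if (!length(known)) next
    nd <- known[1]
    lss2 <- logical_steady_state(m, stats::setNames(lss[[nd]], nd))
    expect_true(all(is.na(lss) | lss2 == lss))
  }
})

test_that("fold-change-seeded steady state resolves the worked example", {
  m <- fig2_model()
  st <- steady_state(m)
  expect_equal(st[c("X1", "X2", "X3", "X4")],
               c(X1 = 1, X2 = 0, X3 = 1, X4 = 1))
  # plain LSS alone cannot determine the cycle nodes
  lss <- logical_steady_state(m)
  expect_true(anyNA(lss[c("X2", "X3", "X4")]))
})

test_that("EMT levels follow the marker formula, with tight intervals", {
  lvl <- emt_level(c(ZEB1 = 1, CDH1 = 0, VIM = 0, SNAI1 = 1))
  expect_equal(c(lvl$lo, lvl$hi), c(3L, 3L))
  all0 <- emt_level(c(ZEB1 = 0, CDH1 = 0, VIM = 0, SNAI1 = 0))
  expect_equal(all0$lo, 1L)  # the NOT(CDH1) term
  iv <- emt_level(c(ZEB1 = 1, CDH1 = 0, VIM = NA, SNAI1 = 1))
  expect_equal(c(iv$lo, iv$hi), c(3L, 4L))
  expect_error(emt_level(c(ZEB1 = 1, CDH1 = 0, VIM = 1)), "SNAI1")
})

test_that("EMT is monotone in each marker's direction", {
  combos <- expand.grid(z = 0:1, c = 0:1, v = 0:1, s = 0:1)
  for (i in seq_len(nrow(combos))) {
    st <- c(ZEB1 = combos$z[i], CDH1 = combos$c[i], VIM = combos$v[i],
            SNAI1 = combos$s[i])
    base <- emt_level(st)$lo
    for (up in c("ZEB1", "VIM", "SNAI1")) {
      st2 <- st; st2[up] <- 1
      expect_gte(emt_level(st2)$lo, base)
    }
    st3 <- st; st3["CDH1"] <- 1
    expect_lte(emt_level(st3)$lo, base)
  }
})
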