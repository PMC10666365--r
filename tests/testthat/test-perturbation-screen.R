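fixture_model <- function() {
  fx <- melanoma_fixture()
  infer_gates(fx$core, fx$fc)
}

test_that("the fixture baseline reproduces the reference marker states", {
  b <- baseline_response(fixture_model())
  expect_equal(c(b$zeb1, b$cdh1, b$vim, b$snai1), c(1, 0, 0, 1))
  expect_equal(b$emt_lo, 3L)
  expect_equal(b$emt_hi, 3L)
  expect_equal(b$delta_lo, 0L)
})

test_that("single screen finds the reference inhibitions and activation", {
  s <- single_screen(fixture_model())
  row <- function(iv) s[s$intervention == iv, ]
  expect_equal(unlist(row("MDM2=0")[c("zeb1", "cdh1", "vim", "snai1")],
                      use.names = FALSE), c(1, 1, 0, 0))
  expect_equal(row("MDM2=0")$emt_lo, 1L)
  expect_equal(row("MIR25=0")$emt_lo, 1L)
  expect_equal(unlist(row("AKT1=1")[c("zeb1", "cdh1", "vim", "snai1")],
                      use.names = FALSE), c(1, 0, 1, 1))
  expect_equal(row("AKT1=1")$emt_lo, 4L)
  # sorted by EMT ascending
  expect_equal(s$emt_lo, sort(s$emt_lo))
  # both clamp values present for every candidate
  expect_equal(sum(grepl("^AKT1=", s$intervention)), 2)
  expect_error(single_screen(fixture_model(), candidates = "CDH1"),
               "marker")
})

test_that("clamping a node at its steady-state value changes nothing", {
  m <- fixture_model()
  st <- steady_state(m)
  s <- single_screen(m)
  for (nd in c("E2F1", "CTNNB1", "MDM2")) {
    lab <- paste0(nd, "=", st[[nd]])
    expect_equal(s$delta_lo[s$intervention == lab], 0L)
    expect_equal(s$delta_hi[s$intervention == lab], 0L)
  }
})

test_that("double screen is exhaustive, deduplicated and self-consistent", {
  m <- fixture_model()
  d <- double_screen(m)
  n <- 5  # regulatory-layer candidates
  expect_equal(nrow(d), choose(n, 2) * 4)
  expect_false(anyDuplicated(d$intervention) > 0)
  # re-evaluating the EMT formula on the marker columns reproduces emt
  redo <- purrr::pmap_int(d[c("zeb1", "cdh1", "vim", "snai1")],
    function(zeb1, cdh1, vim, snai1) {
      emt_level(c(ZEB1 = zeb1, CDH1 = cdh1, VIM = vim, SNAI1 = snai1))$lo
    })
  expect_equal(d$emt_lo, redo)
  # co-inhibition of the two signature proteins is at least as strong as
  # either single inhibition
  s <- single_screen(m)
  both <- d[d$intervention == "AKT1=0,MDM2=0", ]
  expect_lte(both$emt_lo, s$emt_lo[s$intervention == "MDM2=0"])
  expect_lte(both$emt_lo, s$emt_lo[s$intervention == "AKT1=0"])
  expect_true(d$at_minimum[d$intervention == "AKT1=0,MDM2=0"])
  # a pair of non-influential nodes has delta 0
  expect_equal(d$delta_lo[d$intervention == "CTNNB1=1,E2F1=1"], 0L)
})

test_that("screens are deterministic across re-runs", {
  m <- fixture_model()
  expect_identical(single_screen(m), single_screen(m))
  expect_identical(double_screen(m), double_screen(m))
})

test_that("robustness finds exactly the two fragile signature proteins", {
  r <- robustness_analysis(fixture_model())
  expect_identical(r$fragile_nodes, c("AKT1", "MDM2"))
  expect_equal(r$tested, 4)  # regulatory proteins, miRNA excluded
  r2 <- robustness_analysis(fixture_model(), include_mirna = TRUE)
  expect_identical(r2$fragile_nodes, c("AKT1", "MDM2", "MIR25"))
})

test_that("a node with no path to any marker is never fragile", {
  # linear chain with a dangling branch that cannot reach the markers
  edges <- tibble::tribble(
    ~from, ~to, ~sign,
    "IN", "A", 1L, "A", "MZ", 1L, "A", "MC", -1L,
    "A", "DEAD", 1L, "DEAD", "DEAD2", 1L,
    "IN", "MV", 1L, "A", "MS", 1L)
  net <- signed_network(edges)
  net <- set_node_kind(net, "IN", "receptor")
  net <- set_node_kind(net, c("MZ", "MC", "MV", "MS"), "marker")
  net$layers <- tibble::tibble(
    id = net$nodes$id,
    layer = dplyr::case_when(net$nodes$id == "IN" ~ "input",
                             grepl("^M", net$nodes$id) ~ "output-marker",
                             TRUE ~ "regulatory"))
  net$markers <- emt_markers("MZ", "MC", "MV", "MS")
  net$receptors <- "IN"
  class(net) <- c("core_network", class(net))
  fc <- tibble::tibble(id = net$nodes$id,
                       log2fc = c(1, 1, 1, -1, 1, 1, 1, 1)[
                         match(net$nodes$id,
                               c("IN", "A", "MZ", "MC", "DEAD", "DEAD2",
                                 "MV", "MS"))])
  m <- infer_gates(net, fc)
  r <- robustness_analysis(m)
  expect_false("DEAD" %in% r$fragile_nodes)
  expect_false("DEAD2" %in% r$fragile_nodes)
  # every node on the single chain input -> markers is fragile
  expect_true("A" %in% r$fragile_nodes)
  s <- single_screen(m, candidates = c("DEAD", "DEAD2"))
  expect_true(all(s$delta_lo == 0 & s$delta_hi == 0))
})

test_that("minimal intervention search returns the optimal sets", {
  m <- fixture_model()
  mins <- find_minimal_interventions(m, 1, "minimize")
  expect_setequal(mins$intervention, c("MDM2=0", "MIR25=0"))
  expect_true(all(mins$emt_lo == 1))
  maxs <- find_minimal_interventions(m, 1, "maximize")
  expect_equal(maxs$intervention, "AKT1=1")
  expect_equal(maxs$emt_lo, 4L)
  # with no candidates only the baseline is reported
  base_only <- find_minimal_interventions(m, 1, candidates = character())
  expect_equal(base_only$intervention, "(baseline)")
  # size-2 search never reports supersets of a winning single clamp
  mins2 <- find_minimal_interventions(m, 2, "minimize")
  expect_setequal(mins2$intervention[mins2$size == 1],
                  c("MDM2=0", "MIR25=0"))
  pairs <- mins2$intervention[mins2$size == 2]
  expect_false(any(grepl("MDM2=0|MIR25=0", pairs)))
})

test_that("a planted dominant repressor of the epithelial marker is found", {
  # REP represses the CDH1-role marker; its inhibition is the unique
  # level-0 minimizer
  edges <- tibble::tribble(
    ~from, ~to, ~sign,
    "IN", "REP", 1L,
    "REP", "MC", -1L, "REP", "MZ", 1L, "REP", "MV", 1L, "REP", "MS", 1L)
  net <- signed_network(edges)
  net <- set_node_kind(net, "IN", "receptor")
  net <- set_node_kind(net, c("MZ", "MC", "MV", "MS"), "marker")
  net$layers <- tibble::tibble(
    id = net$nodes$id,
    layer = dplyr::case_when(net$nodes$id == "IN" ~ "input",
                             grepl("^M", net$nodes$id) ~ "output-marker",
                             TRUE ~ "regulatory"))
  net$markers <- emt_markers("MZ", "MC", "MV", "MS")
  net$receptors <- "IN"
  class(net) <- c("core_network", class(net))
  fc <- tibble::tibble(id = c("IN", "REP", "MZ", "MC", "MV", "MS"),
                       log2fc = c(2, 1.5, 1, -1, 1, 1))
  m <- infer_gates(net, fc)
  expect_equal(baseline_response(m)$emt_lo, 4L)
  mins <- find_minimal_interventions(m, 1, "minimize")
  expect_equal(mins$intervention, "REP=0")
  expect_equal(mins$emt_lo, 0L)
})
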