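#' Bundled melanoma-style core network fixture
#'
#' A hand-built minimal sufficient core model of E2F1-driven EMT
#' regulation in melanoma: ten receptor inputs (AR, ESR1, FGFR1, FLT4,
#' NR2F2, NR4A1, TGFBR1, TGFBR2, THRA, THRB), a regulatory layer (E2F1,
#' AKT1, MDM2, MIR25, CTNNB1) and the four EMT markers (ZEB1, CDH1, VIM,
#' SNAI1). It wires the mechanistic axes reported for this system --
#' MDM2 represses CDH1; CDH1 loss de-represses CTNNB1 which activates
#' SNAI1; AKT1 activates VIM and MDM2; and a positive three-node
#' feedback loop E2F1 -> MIR25 -> MDM2 -> E2F1 -- and ships a
#' fold-change profile
#' whose signs match the model's steady state, so the Boolean model
#' derived by [infer_gates()] reproduces the reference behavior:
#' baseline markers (ZEB1, CDH1, VIM, SNAI1) = (1, 0, 0, 1), EMT level 3;
#' clamping MDM2 = 0 or MIR25 = 0 gives (1, 1, 0, 0), EMT 1; clamping
#' AKT1 = 1 gives (1, 0, 1, 1), EMT 4; and the single-failure fragile
#' set is exactly \{AKT1, MDM2\}.
#'
#' This is a synthetic stand-in: a ~19-node minimal model reproducing the
#' reference input/output behavior, not a reconstruction of the full
#' 48-node melanoma core (whose edge list is distributed as supplementary
#' data); a full core can be supplied as a SIF file instead.
#'
#' @return A list with `core` (a `core_network`), `fc` (fold-change
#'   tibble) and `annotations` (annotation tibble).
#' @examples
#' fx <- melanoma_fixture()
#' model <- infer_gates(fx$core, fx$fc)
#' baseline_response(model)
#' @export
melanoma_fixture <- function() {
  receptors <- c("AR", "ESR1", "FGFR1", "FLT4", "NR2F2", "NR4A1",
                 "TGFBR1", "TGFBR2", "THRA", "THRB")
  markers <- emt_markers()
  edges <- tibble::tribble(
    ~from,     ~to,       ~sign,
    # receptor wiring
    "FGFR1",  "E2F1",    1L,
    "TGFBR1", "E2F1",    1L,
    "FLT4",   "E2F1",    1L,
    "THRA",   "AKT1",    1L,
    "THRB",   "AKT1",   -1L,
    "NR2F2",  "MDM2",    1L,
    "AR",     "MDM2",    1L,
    "ESR1",   "MIR25",   1L,
    "NR4A1",  "ZEB1",    1L,
    "TGFBR2", "ZEB1",    1L,
    # regulatory layer, incl. the positive feedback loop
    # E2F1 -> MIR25 -> MDM2 -> E2F1
    "E2F1",   "MDM2",    1L,
    "AKT1",   "MDM2",    1L,
    "E2F1",   "MIR25",   1L,
    "MIR25",  "MDM2",    1L,
    "MDM2",   "E2F1",    1L,
    "E2F1",   "ZEB1",    1L,
    "MDM2",   "CDH1",   -1L,
    "MIR25",  "CDH1",   -1L,
    "CDH1",   "CTNNB1", -1L,
    "CTNNB1", "SNAI1",   1L,
    "CDH1",   "SNAI1",  -1L,
    "AKT1",   "VIM",     1L
  )
  nodes <- tibble::tibble(
    id = c(receptors, "E2F1", "AKT1", "MDM2", "MIR25", "CTNNB1",
           unname(markers)),
    kind = c(rep("receptor", length(receptors)), rep("regulatory", 5),
             rep("marker", 4)),
    species = ifelse(
      c(receptors, "E2F1", "AKT1", "MDM2", "MIR25", "CTNNB1",
        unname(markers)) == "MIR25", "miRNA", "protein"))
  net <- signed_network(edges, nodes)
  net$layers <- tibble::tibble(
    id = net$nodes$id,
    layer = dplyr::case_when(
      net$nodes$kind == "receptor" ~ "input",
      net$nodes$kind == "marker" ~ "output-marker",
      TRUE ~ "regulatory"))
  net$receptors <- receptors
  net$markers <- markers
  class(net) <- c("core_network", class(net))

  # FC signs mirror the reference steady state; receptors without
  # expression evidence (AR, FLT4, TGFBR2, THRB) are missing, i.e. free.
  fc <- tibble::tribble(
    ~id,      ~log2fc,
    "AR",     NA,
    "ESR1",   1.42,
    "FGFR1",  2.10,
    "FLT4",   NA,
    "NR2F2",  0.85,
    "NR4A1",  1.31,
    "TGFBR1", 1.77,
    "TGFBR2", NA,
    "THRA",  -1.05,
    "THRB",   NA,
    "E2F1",   2.65,
    "AKT1",  -0.62,
    "MDM2",   1.48,
    "MIR25",  1.12,
    "CTNNB1", 0.93,
    "ZEB1",   1.89,
    "CDH1",  -2.31,
    "VIM",   -0.74,
    "SNAI1",  1.26
  )
  annotations <- tibble::tibble(
    id = net$nodes$id,
    dp_member = net$nodes$id %in% c("E2F1", "AKT1", "MDM2", "CTNNB1",
                                    "CDH1", "ZEB1", "SNAI1", "VIM"),
    gp_score = dplyr::case_when(
      net$nodes$id %in% c("AKT1", "MDM2") ~ 4.5,
      net$nodes$id == "E2F1" ~ 5.0,
      net$nodes$id %in% unname(markers) ~ 3.5,
      TRUE ~ 1.5))
  list(core = net, fc = fc, annotations = annotations)
}
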