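#' The four EMT marker nodes and their roles
#'
#' EMT is scored as `ZEB1 + NOT(CDH1) + VIM + SNAI1`, an ordinal level
#' from 0 to 4: loss of the epithelial marker CDH1 and gain of the
#' mesenchymal markers ZEB1, VIM and SNAI1 each contribute one level.
#'
#' @param zeb1,cdh1,vim,snai1 Node ids playing the four roles (defaults:
#'   the gene symbols themselves). Only `cdh1` enters negated.
#' @return A named character vector of length 4 with names
#'   `zeb1`, `cdh1`, `vim`, `snai1`.
#' @export
emt_markers <- function(zeb1 = "ZEB1", cdh1 = "CDH1", vim = "VIM",
                        snai1 = "SNAI1") {
  c(zeb1 = zeb1, cdh1 = cdh1, vim = vim, snai1 = snai1)
}

validate_markers <- function(markers) {
  markers <- unlist(markers)
  need <- c("zeb1", "cdh1", "vim", "snai1")
  if (is.null(names(markers)) || !all(need %in% names(markers))) {
    stopifnot(length(markers) == 4L)
    names(markers) <- need
  }
  markers[need]
}

#' Ordinal EMT level of a logic state
#'
#' Evaluates `EMT = ZEB1 + NOT(CDH1) + VIM + SNAI1` on a three-valued
#' state. When every marker is known the result is a point level in
#' 0..4; unknown markers widen it to the tight interval obtained by
#' minimizing/maximizing over their completions.
#'
#' @param state Named numeric vector of node states (0, 1 or `NA` for
#'   unknown), covering the four marker nodes.
#' @param markers Marker mapping from [emt_markers()].
#' @return A list of class `emt_level` with integer fields `lo` and `hi`
#'   (`lo == hi` for a point value).
#' @examples
#' emt_level(c(ZEB1 = 1, CDH1 = 0, VIM = 0, SNAI1 = 1))
#' @export
emt_level <- function(state, markers = emt_markers()) {
  markers <- validate_markers(markers)
  absent <- setdiff(unname(markers), names(state))
  if (length(absent)) {
    stop("marker node(s) missing from state: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  v <- state[unname(markers)]
  contrib <- c(v[1], 1 - v[2], v[3], v[4])  # zeb1, NOT cdh1, vim, snai1
  lo <- sum(ifelse(is.na(contrib), 0, contrib))
  hi <- sum(ifelse(is.na(contrib), 1, contrib))
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "emt_level")
}

#' @export
print.emt_level <- function(x, ...) {
  if (x$lo == x$hi) cat("EMT level:", x$lo, "\n")
  else cat("EMT level in [", x$lo, ", ", x$hi, "]\n", sep = "")
  invisible(x)
}

#' @export
format.emt_level <- function(x, ...) {
  if (x$lo == x$hi) as.character(x$lo) else paste0("[", x$lo, ",", x$hi, "]")
}

emt_midpoint <- function(x) (x$lo + x$hi) / 2
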