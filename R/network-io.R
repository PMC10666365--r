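#' Read a signed interaction network from a 3-column SIF file
#'
#' Each non-comment line holds `source sign target`, whitespace- or
#' tab-separated. Sign tokens `+1`, `1`, `activate` map to activation (+1);
#' `-1`, `inhibit` to inhibition (-1); `0`, `unknown` to neutral (0).
#' Lines starting with `#` and blank lines are skipped.
#'
#' @param path Path to the SIF file.
#' @param duplicate_policy What to do when the same ordered (source, target)
#'   pair occurs more than once: `"error"` (default) or `"keep_first"`.
#'   Repeats with conflicting signs are always an error.
#' @return A [signed_network()].
#' @export
read_signed_network <- function(path,
                                duplicate_policy = c("error", "keep_first")) {
  duplicate_policy <- match.arg(duplicate_policy)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(signed_network())

  parse_one <- function(i) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(toks) != 3L) {
      stop(sprintf("%s line %d: expected 3 fields, found %d",
                   basename(path), i, length(toks)), call. = FALSE)
    }
    s <- parse_sign_token(toks[2])
    if (is.na(s)) {
      stop(sprintf("%s line %d: unknown sign token '%s'",
                   basename(path), i, toks[2]), call. = FALSE)
    }
    tibble::tibble(from = toks[1], to = toks[3], sign = s)
  }
  edges <- dplyr::bind_rows(lapply(keep, parse_one))

  pair <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(pair)) {
    conflict <- vapply(split(edges$sign, pair), function(s)
      length(unique(s)) > 1L, logical(1))
    if (any(conflict)) {
      stop("conflicting signs for duplicated edge(s): ",
           paste(gsub("\r", " -> ", names(conflict)[conflict]),
                 collapse = ", "), call. = FALSE)
    }
    if (duplicate_policy == "error") {
      stop("duplicate edge(s): ",
           paste(unique(gsub("\r", " -> ", pair[duplicated(pair)])),
                 collapse = ", "), call. = FALSE)
    }
    edges <- edges[!duplicated(pair), ]
  }
  signed_network(edges)
}

parse_sign_token <- function(tok) {
  switch(tok,
    "+1" = 1L, "1" = 1L, "activate" = 1L,
    "-1" = -1L, "inhibit" = -1L,
    "0" = 0L, "unknown" = 0L,
    NA_integer_)
}

#' Write a signed network as a 3-column SIF file
#'
#' @param net A `signed_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  sgn <- ifelse(net$edges$sign > 0, "+1", ifelse(net$edges$sign < 0, "-1", "0"))
  writeLines(paste(net$edges$from, sgn, net$edges$to), path)
  invisible(path)
}

#' Read per-node log2 fold changes
#'
#' Expects a TSV with a header and two columns: node id and log2 fold
#' change. Blank or `NA` cells are recorded as missing; missing is distinct
#' from zero (a zero fold change carries no sign information and is treated
#' as missing downstream).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `log2fc` (may contain `NA`).
#' @export
read_fold_changes <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2L) stop("fold-change table needs id and log2FC columns",
                           call. = FALSE)
  ids <- as.character(raw[[1]])
  txt <- trimws(as.character(raw[[2]]))
  txt[txt == "" | toupper(txt) == "NA" | toupper(txt) == "NAN"] <- NA
  vals <- suppressWarnings(as.numeric(txt))
  bad <- which(!is.na(txt) & is.na(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric fold change '%s' at row %d", txt[bad[1]],
                 bad[1]), call. = FALSE)
  }
  tibble::tibble(id = ids, log2fc = vals)
}

#' Read per-node annotations: disease-pathway membership and gene
#' prioritization scores
#'
#' Expects a TSV with a header and columns `id`, `dp_member`
#' (logical/0-1) and `gp_score` (non-negative real). Nodes absent from the
#' table default downstream to non-membership and a zero score.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `dp_member`, `gp_score`.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("id", "dp_member", "gp_score")
  if (!all(need %in% names(raw))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dp <- tolower(trimws(raw$dp_member)) %in% c("true", "t", "1", "yes")
  gp <- suppressWarnings(as.numeric(raw$gp_score))
  if (anyNA(gp) || any(!is.finite(gp)) || any(gp < 0)) {
    stop("gp_score values must be finite and >= 0", call. = FALSE)
  }
  tibble::tibble(id = as.character(raw$id), dp_member = dp, gp_score = gp)
}

#' Read motif-weighting scenarios from a YAML or JSON config
#'
#' Each scenario carries an id and four non-negative weights `w1..w4`:
#' `w1` applies (halved) to the topological pair degree + betweenness,
#' `w2` to disease-pathway membership, `w3` to the gene-prioritization
#' score, and `w4` to the mean absolute log2 fold change.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with a top-level
#'   `scenarios` list. If omitted, the bundled default grid of 13
#'   scenarios is returned.
#' @return A tibble with columns `id`, `w1`, `w2`, `w3`, `w4` in file order.
#' @export
read_weight_scenarios <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "weight_scenarios.yaml",
                        package = "melanocore", mustWork = TRUE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  sc <- cfg$scenarios %||% cfg
  rows <- purrr::map(sc, function(s) {
    w <- as.numeric(c(s$w1, s$w2, s$w3, s$w4))
    if (length(w) != 4L || anyNA(w)) {
      stop("each scenario needs numeric w1..w4", call. = FALSE)
    }
    if (any(w < 0)) stop("negative weight in scenario '", s$id, "'",
                         call. = FALSE)
    if (all(w == 0)) stop("all-zero weights in scenario '", s$id, "'",
                          call. = FALSE)
    tibble::tibble(id = as.character(s$id),
                   w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4])
  })
  dplyr::bind_rows(rows)
}

#' The bundled default 13-scenario weighting grid
#'
#' Scenario 1 is uniform; 2-5 emphasize one property (weight 2, others 1);
#' 6-9 use one property only; 10-13 emphasize pairs. Intended as a
#' reproducible stand-in for a user-defined iterative weighting scheme;
#' override with your own config via [read_weight_scenarios()].
#'
#' @return A 13-row scenario tibble.
#' @export
default_weight_scenarios <- function() {
  read_weight_scenarios(NULL)
}
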