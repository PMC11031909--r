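#' Read a protein interaction edge list
#'
#' The dialect is deliberately permissive: fields are separated by any run of
#' whitespace or tabs, anything after a `#` is a comment, blank lines are
#' skipped, and columns beyond the first two are ignored. A line with a
#' single token declares an isolated protein (needed because refined
#' networks keep the full node set while dropping edges). Self-loops are
#' dropped and duplicate or reversed-duplicate pairs are merged.
#'
#' @param path Path to the edge-list file.
#' @return A [pin()] network.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nodes <- character()
  from <- character()
  to <- character()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    tk <- tk[nzchar(tk)]
    if (length(tk) == 0L) next
    if (any(!validUTF8(tk))) stop("malformed edge-list line ", i, " in ", path)
    if (length(tk) == 1L) {
      nodes <- c(nodes, tk)
    } else {
      from <- c(from, tk[1L])
      to <- c(to, tk[2L])
    }
  }
  pin(nodes = nodes, edges = cbind(from, to))
}

#' Write a protein interaction edge list
#'
#' Deterministic inverse of [read_edge_list()]: edges are emitted one per
#' line with endpoints sorted within the pair and lines sorted; isolated
#' nodes are emitted as single-token lines so the node set round-trips.
#'
#' @param net A [pin()] network.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  deg <- pin_degree(net)
  iso <- names(deg)[deg == 0L]
  lines <- character()
  if (nrow(net$edges) > 0L) {
    lines <- paste(net$edges[, 1L], net$edges[, 2L], sep = "\t")
  }
  writeLines(c(lines, iso), path)
  invisible(path)
}

# Shared strict TSV table reader: header row names the value columns, first
# column holds protein ids. Errors name the offending line.
read_keyed_table <- function(path, value_check, what) {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop("empty ", what, " table: ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  header <- toks[[1L]]
  p <- length(header)
  if (p < 2L) stop(what, " table needs an id column and at least one value column: ", path)
  body <- toks[-1L]
  body_lineno <- lineno[-1L]
  bad <- which(lengths(body) != p)
  if (length(bad)) {
    stop("ragged row at line ", body_lineno[bad[1L]], " of ", path,
         " (expected ", p, " fields, got ", lengths(body)[bad[1L]], ")")
  }
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein id '", ids[duplicated(ids)][1L], "' in ", path)
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = p - 1L,
                 dimnames = list(ids, header[-1L]))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1L]))
    if (anyNA(v)) {
      stop("non-numeric cell at line ", body_lineno[r], " of ", path)
    }
    vals[r, ] <- v
  }
  value_check(vals, path)
  vals
}

#' Read a gene-expression matrix
#'
#' TSV with a header row naming the time points and one row per protein; all
#' values must be finite numbers and every row must have the same number of
#' time points. Proteins absent from the matrix are treated downstream as
#' never active (see [build_dpin()]).
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, rows named by protein id, columns by time point.
#' @export
read_expression_matrix <- function(path) {
  read_keyed_table(path, function(v, p) {
    if (any(!is.finite(v))) stop("non-finite expression value in ", p)
  }, "expression")
}

#' Write a gene-expression matrix
#'
#' @param expr Numeric matrix with protein-id rownames and time-point
#'   colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(expr, path) {
  write_keyed_table(expr, "protein", path)
}

#' Read a subcellular localization count table
#'
#' TSV with a header row naming the compartments and one row per protein;
#' cells are nonnegative integer counts of localization evidence (a protein
#' may occur in a compartment more than once, which is why counts rather
#' than indicators are stored). The nucleus compartment is identified by
#' column name when scores are computed, not by position.
#'
#' @param path Path to the localization TSV.
#' @return Integer matrix, rows named by protein id, columns by compartment.
#' @export
read_localization_table <- function(path) {
  v <- read_keyed_table(path, function(v, p) {
    if (any(v < 0) || any(v != round(v))) {
      stop("localization counts must be nonnegative integers in ", p)
    }
  }, "localization")
  storage.mode(v) <- "integer"
  v
}

#' Write a subcellular localization count table
#'
#' @param loc Integer matrix with protein-id rownames and compartment
#'   colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_localization_table <- function(loc, path) {
  write_keyed_table(loc, "protein", path)
}

#' Read orthology scores
#'
#' Two-column TSV (`protein`, score) with a header row; the score of a
#' protein is the number of reference organisms in which it has an ortholog,
#' a proxy for evolutionary conservation. Zero is a valid recorded score and
#' is distinct from an absent protein (absent defaults to 0 downstream).
#'
#' @param path Path to the orthology TSV.
#' @return Named integer vector of scores.
#' @export
read_orthology_scores <- function(path) {
  v <- read_keyed_table(path, function(v, p) {
    if (any(v < 0) || any(v != round(v))) {
      stop("orthology scores must be nonnegative integers in ", p)
    }
  }, "orthology")
  out <- as.integer(v[, 1L])
  names(out) <- rownames(v)
  out
}

#' Write orthology scores
#'
#' @param orth Named integer vector of orthology scores.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_orthology_scores <- function(orth, path) {
  m <- matrix(as.numeric(orth), ncol = 1L,
              dimnames = list(names(orth), "orthologs"))
  write_keyed_table(m, "protein", path)
}

#' Read a protein id list
#'
#' One id per line; `#` comments and blank lines are skipped; duplicates are
#' merged. Used for the essential-protein reference set.
#'
#' @param path Path to the list file.
#' @return Sorted character vector of unique protein ids.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop("protein list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  sort(unique(lines[nzchar(lines)]), method = "radix")
}

#' Write a protein id list
#'
#' @param ids Character vector of protein ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_list <- function(ids, path) {
  writeLines(sort(unique(as.character(ids)), method = "radix"), path)
  invisible(path)
}

# Deterministic keyed-table writer shared by the matrix formats. Numeric
# formatting goes through as.character(), which round-trips exactly for the
# rounded values the generators emit.
write_keyed_table <- function(mat, id_name, path) {
  header <- paste(c(id_name, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(r) {
    paste(c(rownames(mat)[r], as.character(mat[r, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
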