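# Readers, writers and validation for the two standard inputs (Newick tree
# and delimited tip-range table) and the analysis outputs.

#' Read a Newick tree
#'
#' Thin wrapper around \code{ape::read.tree} that insists on branch
#' lengths. Binary-ness is checked later, at validation, so that a
#' polytomous file parses and fails with a named-node diagnostic instead
#' of a parser error.
#'
#' @param path Path to a Newick file.
#' @return A \code{phylo}.
#' @export
read_tree_file <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree))
    stop("malformed Newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree$edge.length))
    stop("tree in ", path, " has no branch lengths")
  tree
}

#' Validate a tree for analysis
#'
#' Checks rootedness, binary topology (naming offending nodes), branch
#' lengths and (with a warning only) ultrametricity. Optionally
#' cross-validates a tip-range map against the tip labels.
#'
#' @param tree A \code{phylo}.
#' @param tip_ranges Optional named range map to cross-check.
#' @return \code{TRUE}, invisibly; errors otherwise.
#' @export
validate_input <- function(tree, tip_ranges = NULL) {
  td <- .tree_data(tree)
  if (!is.null(tip_ranges)) {
    miss <- setdiff(tree$tip.label, names(tip_ranges))
    if (length(miss))
      stop("tips without a range: ", paste(miss, collapse = ", "))
    extra <- setdiff(names(tip_ranges), tree$tip.label)
    if (length(extra))
      stop("range-table tips absent from the tree: ",
           paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a tip-range table
#'
#' Reads a delimited text table (TSV by default, header row required) in
#' either of two dialects, auto-detected from the header: (i) a
#' \code{tip} column plus one 0/1 column per area (ambiguity is resolved
#' in favour of this dialect), or (ii) a \code{tip} column and a
#' \code{range} column of comma-separated area labels. The first column is
#' used as the tip column if none is literally named \code{tip}.
#'
#' @param path File path.
#' @param space A \code{range_space}; area columns must match its labels.
#' @param sep Field delimiter.
#' @return Named integer vector of state indices.
#' @export
read_range_table <- function(path, space, sep = "\t") {
  if (!file.exists(path)) stop("range table not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("range table needs a tip column plus range data")
  tip_col <- if ("tip" %in% names(df)) "tip" else names(df)[1]
  tips <- as.character(df[[tip_col]])
  if (anyDuplicated(tips))
    stop("duplicate tip rows: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  if (all(space$areas %in% names(df))) {
    mat <- as.matrix(df[, space$areas, drop = FALSE])
    states <- vapply(seq_len(nrow(mat)), function(i)
      parse_range(as.integer(mat[i, ]), space), integer(1))
  } else if ("range" %in% names(df)) {
    states <- vapply(df$range, parse_range, integer(1), space = space,
                     USE.NAMES = FALSE)
  } else {
    stop("unrecognised range-table header: need either one 0/1 column per ",
         "area (", paste(space$areas, collapse = ", "),
         ") or a 'range' column")
  }
  setNames(states, tips)
}

#' Write a tip-range table
#'
#' @param tip_states Named integer state vector.
#' @param space A \code{range_space}.
#' @param path Output path (TSV).
#' @param dialect \code{"matrix"} (0/1 column per area, default) or
#'   \code{"labels"} (comma-separated labels in a \code{range} column).
#' @export
write_range_table <- function(tip_states, space, path,
                              dialect = c("matrix", "labels")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    M <- .membership(space)[tip_states, , drop = FALSE]
    df <- data.frame(tip = names(tip_states), M, check.names = FALSE,
                     row.names = NULL)
  } else {
    rng <- vapply(tip_states, function(s)
      paste(space$areas[space$sets[[s]]], collapse = ","), character(1))
    df <- data.frame(tip = names(tip_states), range = rng, row.names = NULL)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write node marginals as TSV
#'
#' One row per node (ape id plus the documented post-order index), one
#' column per state, plus per-area presence probabilities.
#'
#' @param marginals A \code{range_marginals}.
#' @param path Output path.
#' @export
write_marginals <- function(marginals, path) {
  po <- setNames(marginals$nodes$postorder, marginals$nodes$node)
  nn <- nrow(marginals$prob)
  df <- data.frame(node = seq_len(nn),
                   postorder = unname(po[as.character(seq_len(nn))]),
                   is_tip = seq_len(nn) <= marginals$n_tips,
                   marginals$prob, marginals$presence, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotated Newick with top node states
#'
#' Writes the tree with each internal node labelled by its three most
#' probable states, e.g. \code{"Borneo=0.61/Borneo+Sumatra=0.20/..."}
#' (characters that would break the Newick grammar are avoided).
#'
#' @param marginals A \code{range_marginals}.
#' @param path Optional output path; if \code{NULL} the Newick string is
#'   returned.
#' @export
annotated_newick <- function(marginals, path = NULL) {
  tre <- marginals$tree
  ntip <- marginals$n_tips
  lab <- vapply((ntip + 1L):nrow(marginals$prob), function(v) {
    p <- marginals$prob[v, ]
    top <- order(p, decreasing = TRUE)[seq_len(min(3L, length(p)))]
    paste(sprintf("%s=%.3f", gsub("[,:;()\\[\\]]", "_", names(p)[top]),
                  p[top]), collapse = "/")
  }, character(1))
  tre$node.label <- lab
  if (is.null(path)) return(ape::write.tree(tre))
  ape::write.tree(tre, path)
  invisible(path)
}

#' Write a richness-through-time profile as TSV
#'
#' @param richness A \code{range_richness}.
#' @param path Output path.
#' @export
write_richness <- function(richness, path) {
  df <- data.frame(time = richness$times, n_lineages = richness$n_lineages,
                   richness$richness, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the scenario grid as TSV and JSON
#'
#' @param grid A \code{range_scenarios}.
#' @param tsv,json Output paths (either may be \code{NULL}).
#' @export
write_scenarios <- function(grid, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(grid$summary, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json)) {
    payload <- list(
      bd_mu = grid$bd$bd_mu,
      bd = list(lambda_hat = grid$bd$lambda_hat, mu_hat = grid$bd$mu_hat,
                loglik = grid$bd$loglik),
      mu_levels = as.list(grid$mu_levels),
      selected = as.list(grid$selected),
      tie_break = grid$tie_break,
      cells = grid$summary)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(grid)
}
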