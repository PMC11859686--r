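#' Read a formula-by-plant incidence table
#'
#' Expects delimited text with a header: first column the formula id, one
#' column per plant (0/1), and a final 0/1 column named `class`. Cells other
#' than 0/1 are rejected with a row- and column-naming error. Plant columns
#' whose names normalize to the same canonical form (case, whitespace and
#' known spelling variants, see [name_normalizer()]) are merged by logical OR
#' with a warning — presence/absence semantics, so OR, not sum.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, otherwise comma).
#' @param normalizer A [name_normalizer()] used to detect duplicate plant
#'   columns.
#' @return A [formula_dataset()].
#' @export
read_formula_table <- function(path, sep = NULL, normalizer = name_normalizer()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 3) stop("empty or degenerate table: ", path)
  if (!"class" %in% names(raw)) stop("missing label column named \"class\"")
  ids <- raw[[1]]
  label_col <- which(names(raw) == "class")
  plant_cols <- setdiff(seq_along(raw)[-1], label_col)
  if (length(plant_cols) == 0) stop("no plant columns found")

  parse_binary <- function(values, colname) {
    v <- trimws(values)
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      stop(sprintf("non-binary cell at row %d, column \"%s\": \"%s\"",
                   which(!ok)[1], colname, v[which(!ok)[1]]), call. = FALSE)
    }
    as.integer(v)
  }

  labels <- parse_binary(raw[[label_col]], "class")
  m <- vapply(plant_cols, function(j) parse_binary(raw[[j]], names(raw)[j]),
              integer(nrow(raw)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(raw))
  colnames(m) <- names(raw)[plant_cols]
  rownames(m) <- ids

  canon <- vapply(colnames(m), normalize_name, character(1), normalizer = normalizer)
  if (anyDuplicated(canon)) {
    dups <- unique(canon[duplicated(canon)])
    warning(sprintf("merging duplicate plant columns by OR: %s",
                    paste(dups, collapse = "; ")), call. = FALSE)
    merged <- vapply(unique(canon), function(nm) {
      as.integer(rowSums(m[, canon == nm, drop = FALSE]) > 0)
    }, integer(nrow(m)))
    colnames(merged) <- unique(canon)
    rownames(merged) <- ids
    m <- merged
  }
  formula_dataset(m, labels, provenance = path)
}

#' Write a formula dataset as delimited text
#'
#' Inverse of [read_formula_table()]: first column `formula_id`, one column
#' per plant, final column `class`.
#'
#' @param dataset A `formula_dataset`.
#' @param path Output path; extension selects the delimiter as in
#'   [read_formula_table()].
#' @return `path`, invisibly.
#' @export
write_formula_table <- function(dataset, path) {
  validate_formula_dataset(dataset)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- data.frame(
    formula_id = dataset$formula_ids,
    dataset$matrix,
    class = dataset$labels,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE)
  invisible(path)
}

#' Write a network as a plain-text adjacency list
#'
#' Dialect: a roster header line `#nodes: id1 id2 ...` (so isolated nodes
#' survive the round trip — the clustering guarantees every node a cluster,
#' isolates included), then one whitespace-delimited `u v w` line per edge
#' with the lexicographically smaller endpoint first.
#'
#' @param network An igraph formula network (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjacency_list <- function(network, path) {
  nodes <- sort(igraph::V(network)$name)
  el <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#nodes:", paste(nodes, collapse = " ")), con)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    tmp <- el[swap, 1]
    el[swap, 1] <- el[swap, 2]
    el[swap, 2] <- tmp
    ord <- order(el[, 1], el[, 2])
    writeLines(sprintf("%s %s %.10g", el[ord, 1], el[ord, 2], w[ord]), con)
  }
  invisible(path)
}

#' Read a plain-text adjacency list into a network
#'
#' Parses the dialect written by [write_adjacency_list()]. Malformed lines
#' raise an error naming the line number.
#'
#' @param path Path to the adjacency file.
#' @return An undirected igraph with a `weight` edge attribute.
#' @export
read_adjacency_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  nodes <- character()
  from <- character(); to <- character(); w <- numeric()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "#nodes:")) {
      nodes <- c(nodes, strsplit(trimws(sub("^#nodes:", "", line)), "\\s+")[[1]])
      next
    }
    if (startsWith(line, "#")) next
    parts <- strsplit(line, "\\s+")[[1]]
    if (!length(parts) %in% c(2, 3)) {
      stop(sprintf("malformed adjacency line %d: \"%s\"", i, lines[i]), call. = FALSE)
    }
    wt <- if (length(parts) == 3) suppressWarnings(as.numeric(parts[3])) else 1
    if (is.na(wt)) {
      stop(sprintf("malformed weight on line %d: \"%s\"", i, lines[i]), call. = FALSE)
    }
    if (parts[1] == parts[2]) {
      stop(sprintf("self-loop on line %d: \"%s\"", i, lines[i]), call. = FALSE)
    }
    from <- c(from, parts[1]); to <- c(to, parts[2]); w <- c(w, wt)
  }
  nodes <- sort(unique(c(nodes, from, to)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
    g <- igraph::simplify(g, edge.attr.comb = list(weight = "first"))
  }
  g
}

#' Construct a candidate table
#'
#' A ranked table of plant candidates with a support statistic: formula count
#' for the network branch, permutation-importance weight for the ML branch.
#'
#' @param plant_name Character vector of (canonical) plant names, unique.
#' @param support Positive support values.
#' @param branch One of `"network"`, `"ml"`, `"overlap"`.
#' @return Data frame of class `candidate_table`, sorted by decreasing
#'   support, ties broken alphabetically.
#' @export
candidate_table <- function(plant_name, support, branch) {
  branch <- match.arg(branch, c("network", "ml", "overlap"))
  if (anyDuplicated(plant_name)) stop("duplicate plant names in candidate table")
  if (any(support <= 0)) stop("support must be positive")
  out <- data.frame(plant_name = as.character(plant_name),
                    support = as.numeric(support),
                    branch = rep(branch, length(plant_name)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$plant_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Read / write candidate tables
#'
#' @param path CSV path with columns `plant_name`, `support`, `branch`.
#' @return For the reader, a `candidate_table`.
#' @export
read_candidate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_name", "support", "branch")
  if (!all(need %in% names(df))) {
    stop("candidate table must have columns: ", paste(need, collapse = ", "))
  }
  candidate_table(df$plant_name, df$support, unique(df$branch))
}

#' @rdname read_candidate_table
#' @param tbl A `candidate_table`.
#' @export
write_candidate_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
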