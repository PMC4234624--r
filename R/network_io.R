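#' Construct a weekly directed network
#'
#' A weekly network is a directed \pkg{igraph} graph whose vertex names are
#' student identifiers and whose graph attribute \code{week} carries the
#' ordinal course-week label. Edges point from the namer to the named
#' student. Identifiers are opaque, case-sensitive strings that are
#' consistent across weeks.
#'
#' @param edges two-column data frame (or matrix) of character ids:
#'   first column the namer, second the named. May contain duplicates and
#'   self-loops; these are retained until [simplify_network()] is applied.
#' @param week ordinal week label (coerced to integer).
#' @param nodes optional character vector of node ids to declare explicitly
#'   (e.g. isolates); the vertex set is the union of \code{nodes} and all
#'   edge endpoints.
#' @return a directed \code{igraph} object with graph attribute \code{week}.
#' @export
weekly_network <- function(edges, week, nodes = NULL) {
  week <- as.integer(week)
  if (length(week) != 1L || is.na(week)) {
    stop("'week' must be a single integer label", call. = FALSE)
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    el <- matrix(character(0), ncol = 2L)
  } else {
    el <- cbind(as.character(edges[[1]]), as.character(edges[[2]]))
  }
  if (any(!nzchar(el))) stop("node ids must be non-empty strings", call. = FALSE)
  verts <- unique(c(as.character(nodes), as.vector(t(el))))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  missing <- setdiff(verts, igraph::V(g)$name)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  igraph::graph_attr(g, "week") <- week
  g
}

#' Week label of a weekly network
#' @param net a weekly network (igraph with \code{week} attribute).
#' @return integer week label (NA if absent).
#' @export
week_label <- function(net) {
  w <- igraph::graph_attr(net, "week")
  if (is.null(w)) NA_integer_ else as.integer(w)
}

#' Directed edge set of a network as a character matrix
#' @param net igraph object.
#' @return two-column character matrix (namer, named), one row per edge.
#' @export
edge_set <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  mode(el) <- "character"
  el
}

edge_keys <- function(net) {
  el <- edge_set(net)
  if (nrow(el) == 0L) character(0) else paste(el[, 1], el[, 2], sep = "\r")
}

#' Read weekly edge lists from a delimited text file
#'
#' The file must have a header with columns \code{week}, \code{source} and
#' \code{target} (additional columns are ignored). One network is returned
#' per distinct week, in ascending week order. Raw duplicates and
#' self-loops are retained; apply [simplify_network()] downstream.
#'
#' @param path path to the delimited file.
#' @param sep field separator, default comma.
#' @return named list of weekly networks, names the week labels.
#' @export
read_edge_lists <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("week", "source", "target")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns 'week', 'source', 'target'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  wk <- suppressWarnings(as.integer(df$week))
  if (anyNA(wk)) {
    stop("non-parsable week label(s): ",
         paste(unique(df$week[is.na(wk)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$source)) || any(!nzchar(df$target))) {
    stop("node ids must be non-empty", call. = FALSE)
  }
  weeks <- sort(unique(wk))
  nets <- lapply(weeks, function(w) {
    weekly_network(df[wk == w, c("source", "target")], week = w)
  })
  names(nets) <- as.character(weeks)
  nets
}

#' Strip self-loops and duplicate directed links
#'
#' Removes self-loops and multiple identical ordered pairs. The vertex set
#' is unchanged: a node whose only incident edges were self-loops is kept
#' as an isolate, with a warning.
#'
#' @param net a weekly network.
#' @return the simplified network.
#' @export
simplify_network <- function(net) {
  deg_before <- igraph::degree(net, mode = "all")
  out <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  deg_after <- igraph::degree(out, mode = "all")
  orphaned <- names(deg_after)[deg_after == 0 & deg_before > 0]
  if (length(orphaned)) {
    warning("node(s) kept as isolates after removing self-loops: ",
            paste(orphaned, collapse = ", "), call. = FALSE)
  }
  out
}

#' Merge two weekly networks into one
#'
#' The merged network has the union of the two edge sets and vertex sets,
#' and is then simplified. Used e.g. to combine the first two course weeks
#' when early responses are unreliable.
#'
#' @param net1,net2 weekly networks.
#' @param new_label week label for the merged network.
#' @return simplified merged weekly network.
#' @export
merge_weeks <- function(net1, net2, new_label = week_label(net1)) {
  el <- rbind(edge_set(net1), edge_set(net2))
  verts <- union(igraph::V(net1)$name, igraph::V(net2)$name)
  suppressWarnings(
    simplify_network(weekly_network(as.data.frame(el), new_label, nodes = verts))
  )
}

#' Read a node attribute table
#'
#' Expects a header with columns \code{id}, \code{gender}, \code{section},
#' \code{grade}. Category vocabularies are taken from \code{vocab} when
#' supplied, otherwise from the sorted distinct values observed; values
#' outside a declared vocabulary are a validation error.
#'
#' @param path path to the delimited file.
#' @param sep field separator, default comma.
#' @param vocab optional named list of character vectors giving the fixed
#'   category ordering for each of \code{gender}, \code{section},
#'   \code{grade}.
#' @return data frame with class \code{attribute_table}; the vocabularies
#'   are stored in \code{attr(x, "vocab")} and the columns are factors with
#'   those levels.
#' @export
read_attributes <- function(path, sep = ",", vocab = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("id", "gender", "section", "grade")
  if (!all(need %in% names(df))) {
    stop("attribute table must have columns 'id', 'gender', 'section', 'grade'",
         call. = FALSE)
  }
  attribute_table(df[need], vocab = vocab)
}

#' Construct/validate an attribute table
#' @param df data frame with columns id, gender, section, grade.
#' @param vocab optional named list of category vocabularies.
#' @return validated \code{attribute_table}.
#' @export
attribute_table <- function(df, vocab = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate node ids in attribute table", call. = FALSE)
  attrs <- c("gender", "section", "grade")
  if (is.null(vocab)) vocab <- list()
  for (a in attrs) {
    v <- vocab[[a]]
    if (is.null(v)) v <- sort(unique(as.character(df[[a]])))
    if (!length(v)) stop("empty vocabulary for attribute '", a, "'", call. = FALSE)
    bad <- setdiff(unique(as.character(df[[a]])), v)
    if (length(bad)) {
      stop("attribute '", a, "' has value(s) outside its vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    vocab[[a]] <- v
    df[[a]] <- factor(as.character(df[[a]]), levels = v,
                      ordered = identical(a, "grade"))
  }
  structure(df, vocab = vocab, class = c("attribute_table", "data.frame"))
}

#' Check that every node of a network has attributes
#' @param attrs an \code{attribute_table}.
#' @param net a weekly network.
#' @return invisibly TRUE; error when a node is missing.
#' @export
validate_attributes <- function(attrs, net) {
  missing <- setdiff(igraph::V(net)$name, attrs$id)
  if (length(missing)) {
    stop("node(s) missing from attribute table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Export a weekly network to a file
#'
#' Supported formats: \code{"csv"} (week,source,target edge list, readable
#' by [read_edge_lists()]), \code{"graphml"} and \code{"pajek"} (via
#' \pkg{igraph}). Round trips preserve node and edge content.
#'
#' @param net a weekly network.
#' @param path output file path.
#' @param format one of "csv", "graphml", "pajek".
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("csv", "graphml", "pajek")) {
  format <- match.arg(format)
  if (format == "csv") {
    el <- edge_set(net)
    df <- data.frame(week = rep(week_label(net), nrow(el)),
                     source = el[, 1], target = el[, 2],
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    g <- net
    if (format == "pajek") igraph::V(g)$id <- igraph::V(g)$name
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Write an attribute table to CSV
#' @param attrs an \code{attribute_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_attributes <- function(attrs, path) {
  df <- as.data.frame(lapply(attrs, as.character), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
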