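#' Build an alluvial diagram from a sequence of partitions
#'
#' One column per week: boxes are communities with height proportional to
#' the number of students in them (a single scale factor for the whole
#' diagram), ordered within each column by decreasing size. Streamlines
#' between adjacent columns visualize the between-week confusion matrix:
#' the streamline from community \eqn{k} of one week to community \eqn{l}
#' of the next carries the number of students placed in both. Boxes are
#' colored by per-community segregation significance: dark red when
#' segregated by section only, green by gender only, purple by both.
#'
#' @param partitions ordered list (>= 2) of named membership vectors or
#'   \code{partition} objects; adjacent node sets must overlap.
#' @param seg_flags optional list, one element per column, each a data
#'   frame with columns \code{community}, \code{gender}, \code{section}
#'   (logical significance flags), e.g. derived from
#'   [segregation_zscore()] \code{groups} tables.
#' @param scale box height per student, in user units.
#' @param gap vertical gap between boxes, in user units.
#' @param week_labels labels for the columns.
#' @return list of class \code{alluvial_diagram}: \code{boxes} (data
#'   frame: column, community, size, y0, y1, color_class), \code{streams}
#'   (data frame: column pair, source/target community, count),
#'   \code{scale}.
#' @export
build_alluvial <- function(partitions, seg_flags = NULL, scale = 1, gap = 0.5,
                           week_labels = seq_along(partitions)) {
  if (length(partitions) < 2L) stop("need at least two partitions", call. = FALSE)
  pvs <- lapply(partitions, partition_vector)
  boxes <- list()
  for (j in seq_along(pvs)) {
    sizes <- sort(table(pvs[[j]]), decreasing = TRUE)
    y1 <- cumsum(as.integer(sizes) * scale + gap)
    y0 <- y1 - as.integer(sizes) * scale
    cls <- rep("none", length(sizes))
    if (!is.null(seg_flags)) {
      fl <- seg_flags[[j]]
      idx <- match(names(sizes), as.character(fl$community))
      sec <- !is.na(idx) & fl$section[idx] %in% TRUE
      gen <- !is.na(idx) & fl$gender[idx] %in% TRUE
      cls[sec & !gen] <- "section"
      cls[gen & !sec] <- "gender"
      cls[sec & gen] <- "both"
    }
    boxes[[j]] <- data.frame(column = j, week = week_labels[j],
                             community = as.character(names(sizes)),
                             size = as.integer(sizes),
                             y0 = unname(y0), y1 = unname(y1),
                             color_class = cls,
                             row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  streams <- list()
  for (j in seq_len(length(pvs) - 1L)) {
    N <- confusion_matrix(pvs[[j]], pvs[[j + 1L]])
    nz <- which(N > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) stop("adjacent partitions share no nodes", call. = FALSE)
    df <- data.frame(from_column = j, to_column = j + 1L,
                     from_community = rownames(N)[nz[, 1]],
                     to_community = colnames(N)[nz[, 2]],
                     count = N[nz],
                     stringsAsFactors = FALSE)
    streams[[j]] <- df[order(-df$count), , drop = FALSE]
  }
  structure(list(boxes = do.call(rbind, boxes),
                 streams = do.call(rbind, streams),
                 scale = scale, gap = gap),
            class = "alluvial_diagram")
}

#' Number of streamlines between two adjacent columns
#'
#' A streamline is a strictly positive confusion-matrix entry, i.e. one
#' between-week movement of a block of students.
#'
#' @param diagram an \code{alluvial_diagram}.
#' @param between index of the left column of the adjacent pair.
#' @return integer count of streamlines.
#' @export
streamline_count <- function(diagram, between = 1L) {
  stopifnot(inherits(diagram, "alluvial_diagram"))
  sum(diagram$streams$from_column == between)
}

#' @export
print.alluvial_diagram <- function(x, ...) {
  cols <- unique(x$boxes$column)
  cat(sprintf("alluvial diagram: %d columns, %d boxes, %d streamlines\n",
              length(cols), nrow(x$boxes), nrow(x$streams)))
  invisible(x)
}

#' Community-level flow map
#'
#' Aggregates the teleporting random walk to the community level: each
#' community's accumulated visit rate \eqn{\sum_{i \in C} p_i} (node
#' size in a flow map) and the walk flow between every ordered pair of
#' communities, \eqn{\sum_{i \in C, j \in C'} p_i T_{ij}} including
#' teleportation flow (arrow size).
#'
#' @param net directed network.
#' @param partition membership vector or \code{partition} object.
#' @param p optional \code{visit_distribution}.
#' @param tau teleportation rate.
#' @return list of class \code{flow_map}: \code{communities} (data
#'   frame: community, size, visit_rate), \code{flows} (data frame:
#'   from, to, flow; ordered pairs with from != to).
#' @export
aggregate_flow <- function(net, partition, p = NULL, tau = 0.15) {
  memb <- as_membership(partition, net)
  pv <- partition_vector(if (inherits(partition, "partition")) partition$membership else partition)
  labels <- vapply(split(as.character(pv[igraph::V(net)$name]), memb),
                   function(x) x[1], character(1))
  if (!is.null(p) && inherits(p, "visit_distribution")) p <- p$p
  prep <- me_prepare(net, tau = tau, p = p)
  m <- max(memb)
  n <- prep$n
  sp <- as.vector(rowsum(prep$p, memb, reorder = TRUE))
  spt <- as.vector(rowsum(prep$p * prep$tt, memb, reorder = TRUE))
  cnt <- tabulate(memb, m)
  ## teleportation flow k -> l (k != l): mass spt_k spread uniformly
  flow <- outer(spt, cnt / n)
  ## link-following flow
  for (i in seq_len(n)) {
    tgt <- prep$fout_idx[[i]]
    if (length(tgt)) {
      ag <- rowsum(prep$fout_w[[i]], memb[tgt])
      ids <- as.integer(rownames(ag))
      flow[memb[i], ids] <- flow[memb[i], ids] + ag[, 1]
    }
  }
  diag(flow) <- 0
  nz <- which(flow > 0, arr.ind = TRUE)
  flows <- data.frame(from = labels[nz[, 1]], to = labels[nz[, 2]],
                      flow = flow[nz], stringsAsFactors = FALSE)
  structure(list(communities = data.frame(community = labels,
                                          size = cnt,
                                          visit_rate = sp,
                                          stringsAsFactors = FALSE),
                 flows = flows[order(-flows$flow), , drop = FALSE]),
            class = "flow_map")
}

alluvial_colors <- c(none = "#bdbdbd", section = "#8b0000",
                     gender = "#2e8b57", both = "#800080")

#' Render an alluvial diagram or flow map to SVG
#'
#' Writes a plain SVG file with geometry proportional to the counts or
#' flows: boxes as rectangles with heights proportional to community
#' size, streamlines as translucent bands whose thickness is the student
#' count; flow-map nodes as circles with area proportional to visit rate
#' and arrows with width proportional to flow.
#'
#' @param x an \code{alluvial_diagram} or \code{flow_map}.
#' @param path output file path.
#' @param width,height canvas size in pixels.
#' @return \code{path}, invisibly.
#' @export
render_svg <- function(x, path, width = 800, height = 600) {
  if (inherits(x, "alluvial_diagram")) {
    svg_alluvial(x, path, width, height)
  } else if (inherits(x, "flow_map")) {
    svg_flowmap(x, path, width, height)
  } else {
    stop("cannot render object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}

svg_header <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height))
}

svg_alluvial <- function(x, path, width, height) {
  if (is.null(x$boxes) || nrow(x$boxes) == 0L) stop("empty diagram", call. = FALSE)
  cols <- sort(unique(x$boxes$column))
  xw <- width / length(cols)
  bw <- 0.25 * xw
  ymax <- max(x$boxes$y1)
  sy <- (height - 20) / ymax
  lines <- svg_header(width, height)
  pos <- function(col, comm) {
    b <- x$boxes[x$boxes$column == col & x$boxes$community == comm, ]
    c(y0 = b$y0[1] * sy + 10, y1 = b$y1[1] * sy + 10)
  }
  for (s in seq_len(nrow(x$streams))) {
    st <- x$streams[s, ]
    xl <- (match(st$from_column, cols) - 0.5) * xw + bw / 2
    xr <- (match(st$to_column, cols) - 0.5) * xw - bw / 2
    yl <- mean(pos(st$from_column, st$from_community))
    yr <- mean(pos(st$to_column, st$to_community))
    th <- max(st$count * x$scale * sy, 0.5)
    lines <- c(lines, sprintf(
      '<path d="M %.2f %.2f L %.2f %.2f" stroke="#999999" stroke-opacity="0.5" stroke-width="%.2f" fill="none" data-count="%d"/>',
      xl, yl, xr, yr, th, st$count))
  }
  for (b in seq_len(nrow(x$boxes))) {
    bx <- x$boxes[b, ]
    x0 <- (match(bx$column, cols) - 0.5) * xw - bw / 2
    lines <- c(lines, sprintf(
      '<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" data-community="%s" data-size="%d"/>',
      x0, bx$y0 * sy + 10, bw, (bx$y1 - bx$y0) * sy,
      alluvial_colors[[bx$color_class]], bx$community, bx$size))
  }
  writeLines(c(lines, "</svg>"), path)
}

svg_flowmap <- function(x, path, width, height) {
  if (is.null(x$communities) || nrow(x$communities) == 0L) {
    stop("empty flow map", call. = FALSE)
  }
  m <- nrow(x$communities)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  cx <- width / 2 + 0.35 * width * cos(theta)
  cy <- height / 2 + 0.35 * height * sin(theta)
  rad <- 40 * sqrt(x$communities$visit_rate / max(x$communities$visit_rate))
  lines <- svg_header(width, height)
  if (nrow(x$flows)) {
    wmax <- max(x$flows$flow)
    for (f in seq_len(nrow(x$flows))) {
      i <- match(x$flows$from[f], x$communities$community)
      j <- match(x$flows$to[f], x$communities$community)
      lines <- c(lines, sprintf(
        '<path d="M %.2f %.2f L %.2f %.2f" stroke="#555555" stroke-width="%.3f" fill="none" marker-end="none" data-flow="%.6g"/>',
        cx[i], cy[i], cx[j], cy[j], 6 * x$flows$flow[f] / wmax, x$flows$flow[f]))
    }
  }
  for (k in seq_len(m)) {
    lines <- c(lines, sprintf(
      '<circle cx="%.2f" cy="%.2f" r="%.2f" fill="#4682b4" data-community="%s" data-rate="%.6g"/>',
      cx[k], cy[k], rad[k], x$communities$community[k],
      x$communities$visit_rate[k]))
  }
  writeLines(c(lines, "</svg>"), path)
}
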