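#' Assembly graph container
#'
#' A light S3 container for a unitig graph: a `segments` tibble
#' (`unitig`, `length`, `coverage`) and a `links` tibble
#' (`from`, `from_orient`, `to`, `to_orient`). Link orientations are kept
#' for round-tripping but connectivity analysis treats links as
#' undirected edges.
#'
#' @param segments tibble with columns `unitig` (character, unique),
#'   `length` (bp, > 0) and optionally `coverage` (mean depth, defaults 0).
#' @param links tibble with columns `from`, `from_orient`, `to`,
#'   `to_orient`; both endpoints must exist in `segments`.
#' @return an object of class `assembly_graph`.
#' @export
assembly_graph <- function(segments, links = NULL) {
  segments <- as_tibble(segments)
  check_columns(segments, c("unitig", "length"), "segments")
  if (!"coverage" %in% names(segments)) segments$coverage <- 0
  if (anyDuplicated(segments$unitig)) {
    up_abort("duplicate unitig ids in segments")
  }
  if (any(segments$length <= 0)) up_abort("unitig lengths must be > 0")
  if (is.null(links)) {
    links <- tibble(
      from = character(), from_orient = character(),
      to = character(), to_orient = character()
    )
  }
  links <- as_tibble(links)
  check_columns(links, c("from", "from_orient", "to", "to_orient"), "links")
  bad <- setdiff(c(links$from, links$to), segments$unitig)
  if (length(bad) > 0) {
    up_abort(sprintf(
      "links reference unknown segments: %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  structure(
    list(segments = segments, links = links, excised = character()),
    class = "assembly_graph"
  )
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf(
    "<assembly_graph> %d unitigs (%.1f Mbp), %d links",
    nrow(x$segments), sum(x$segments$length) / 1e6, nrow(x$links)
  ))
  if (length(x$excised) > 0) {
    cat(sprintf(", %d excised tangle nodes", length(x$excised)))
  }
  cat("\n")
  invisible(x)
}

# Parse the optional tag fields of a GFA line into a named character vector.
parse_gfa_tags <- function(fields) {
  if (length(fields) == 0) return(character())
  parts <- strsplit(fields, ":", fixed = TRUE)
  vals <- vapply(parts, function(p) paste(p[-(1:2)], collapse = ":"), character(1))
  names(vals) <- vapply(parts, `[`, character(1), 1)
  vals
}

#' Read a GFA1 assembly graph
#'
#' Reads S (segment) and L (link) lines of a GFA1 file. Segments may carry
#' `*` in place of sequence, in which case an `LN:i` length tag is
#' required. Coverage is taken from an `rd:f` tag (mean depth) or, failing
#' that, an `RC:i` read-count tag divided by the segment length; absent
#' both, coverage is 0.
#'
#' @param path path to a GFA1 file.
#' @return an [assembly_graph].
#' @export
read_gfa <- function(path) {
  if (!file.exists(path)) up_abort(sprintf("GFA file not found: %s", path))
  lines <- readLines(path)
  rec_type <- substr(lines, 1, 1)

  seg_lines <- which(rec_type == "S")
  seg_list <- vector("list", length(seg_lines))
  for (i in seq_along(seg_lines)) {
    ln <- seg_lines[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) up_abort(sprintf("malformed S-line at line %d", ln))
    id <- f[2]
    seq <- f[3]
    tags <- parse_gfa_tags(f[-(1:3)])
    if (seq != "*") {
      len <- nchar(seq)
    } else if ("LN" %in% names(tags)) {
      len <- as.numeric(tags[["LN"]])
    } else {
      up_abort(sprintf(
        "segment '%s' at line %d has no sequence and no LN:i tag", id, ln
      ))
    }
    cov <- if ("rd" %in% names(tags)) {
      as.numeric(tags[["rd"]])
    } else if ("RC" %in% names(tags)) {
      as.numeric(tags[["RC"]]) / len
    } else {
      0
    }
    seg_list[[i]] <- tibble(unitig = id, length = len, coverage = cov)
  }
  segments <- if (length(seg_list) > 0) {
    dplyr::bind_rows(seg_list)
  } else {
    tibble(unitig = character(), length = numeric(), coverage = numeric())
  }
  if (anyDuplicated(segments$unitig)) {
    dup <- segments$unitig[duplicated(segments$unitig)][1]
    up_abort(sprintf("duplicate segment id '%s'", dup))
  }

  link_lines <- which(rec_type == "L")
  if (length(link_lines) > 0) {
    f <- strsplit(lines[link_lines], "\t", fixed = TRUE)
    short <- which(lengths(f) < 5)
    if (length(short) > 0) {
      up_abort(sprintf("malformed L-line at line %d", link_lines[short[1]]))
    }
    links <- tibble(
      from = vapply(f, `[`, character(1), 2),
      from_orient = vapply(f, `[`, character(1), 3),
      to = vapply(f, `[`, character(1), 4),
      to_orient = vapply(f, `[`, character(1), 5)
    )
    bad <- which(!(links$from %in% segments$unitig) |
                   !(links$to %in% segments$unitig))
    if (length(bad) > 0) {
      up_abort(sprintf(
        "L-line at line %d references unknown segment", link_lines[bad[1]]
      ))
    }
  } else {
    links <- NULL
  }
  assembly_graph(segments, links)
}

#' Write a GFA1 assembly graph
#'
#' Writes segments as `*`-sequence S-lines with `LN:i` length tags (and an
#' `rd:f` coverage tag when coverage is non-zero) and links as L-lines
#' with `0M` overlaps. Together with [read_gfa()] this round-trips unitig
#' ids, lengths and link records.
#'
#' @param graph an [assembly_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  seg <- graph$segments
  s <- sprintf("S\t%s\t*\tLN:i:%s", seg$unitig, fmt_int(seg$length))
  has_cov <- seg$coverage > 0
  s[has_cov] <- paste0(s[has_cov], sprintf("\trd:f:%g", seg$coverage[has_cov]))
  l <- graph$links
  ll <- sprintf("L\t%s\t%s\t%s\t%s\t0M", l$from, l$from_orient, l$to, l$to_orient)
  writeLines(c("H\tVN:Z:1.0", s, ll), path)
  invisible(path)
}

# igraph over unitig ids; isolated nodes included.
graph_as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$links[, c("from", "to")],
    directed = FALSE,
    vertices = graph$segments$unitig
  )
}

# Component membership as a named integer vector, labels ordered by the
# lexicographically smallest member id so results do not depend on
# igraph's internal ordering.
component_membership <- function(graph) {
  comp <- igraph::components(graph_as_igraph(graph))
  member <- comp$membership
  smallest <- tapply(names(member), member, min)
  relabel <- match(smallest, sort(smallest))
  out <- relabel[match(member, as.integer(names(smallest)))]
  names(out) <- names(member)
  out
}

#' Label connected components
#'
#' Standard undirected connected components, ignoring link orientations.
#' Component ids are integers assigned in order of each component's
#' lexicographically smallest unitig id, so labels are deterministic.
#'
#' @param graph an [assembly_graph] (typically after
#'   [excise_rdna_tangle()]).
#' @return a tibble with columns `unitig`, `component`.
#' @export
component_labels <- function(graph) {
  member <- component_membership(graph)
  tibble(unitig = names(member), component = as.integer(member)) |>
    dplyr::arrange(.data$unitig)
}

#' Excise the rDNA tangle
#'
#' The acrocentric chromosomes are typically fused into one connected
#' component by a dense tangle of short nodes arising from the rDNA
#' arrays. This identifies the largest component by summed base pairs as
#' the putative acrocentric component, finds the maximal connected
#' subgraphs induced by nodes strictly shorter than `short_len` within
#' it, and removes the largest such tangle (by summed bp; ties broken by
#' node count, then smallest id) together with all incident links.
#'
#' @param graph an [assembly_graph].
#' @param short_len nodes strictly shorter than this many bp (default
#'   50000) can belong to the tangle.
#' @return the pruned [assembly_graph]; removed ids are recorded in its
#'   `excised` element. Graphs with no short nodes are returned unchanged.
#' @export
excise_rdna_tangle <- function(graph, short_len = 50000) {
  if (nrow(graph$segments) == 0) up_abort("graph is empty")
  member <- component_membership(graph)
  seg <- graph$segments
  comp_bp <- tapply(seg$length, member[seg$unitig], sum)
  big <- as.integer(names(comp_bp)[which.max(comp_bp)])
  short_ids <- seg$unitig[seg$length < short_len & member[seg$unitig] == big]
  if (length(short_ids) == 0) return(graph)

  sub <- igraph::induced_subgraph(graph_as_igraph(graph), short_ids)
  scomp <- igraph::components(sub)$membership
  lens <- seg$length[match(names(scomp), seg$unitig)]
  cand <- tibble(id = names(scomp), tangle = as.integer(scomp), len = lens) |>
    dplyr::group_by(.data$tangle) |>
    dplyr::summarise(
      bp = sum(.data$len),
      n = dplyr::n(),
      min_id = min(.data$id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$bp), dplyr::desc(.data$n), .data$min_id)
  winner <- cand$tangle[1]
  removed <- sort(names(scomp)[scomp == winner])

  out <- graph
  out$segments <- seg[!seg$unitig %in% removed, , drop = FALSE]
  out$links <- graph$links[
    !(graph$links$from %in% removed) & !(graph$links$to %in% removed), ,
    drop = FALSE
  ]
  out$excised <- removed
  out
}

#' Length-filter unitigs
#'
#' Unitigs strictly shorter than `min_len` are excluded from clustering
#' and phasing (they remain in the graph object for reporting); ids with
#' length >= `min_len` are returned.
#'
#' @param graph an [assembly_graph].
#' @param min_len minimum retained length in bp (default 50000).
#' @return character vector of retained unitig ids.
#' @export
filter_by_length <- function(graph, min_len = 50000) {
  graph$segments$unitig[graph$segments$length >= min_len]
}
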