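#' Read a neuron reconstruction from an SWC file
#'
#' Parses the standard 7-column SWC dialect (id, type, x, y, z, radius,
#' parent) into a validated `neuron_tree`. SWC structure type 1 is kept as
#' soma; every other structure type (axon, dendrite, custom) is collapsed to
#' neurite, since the morphometry treats all processes uniformly. Node ids
#' are remapped to contiguous integers in file order.
#'
#' @param path Path to an SWC file. Lines starting with `#` are comments.
#' @param neuron_id,ploidy,brain_region Optional metadata attached to the
#'   tree (default: file name, `NA`, `NA`).
#' @return A `neuron_tree`: a data.frame with columns `node_id`, `parent_id`
#'   (`NA` for the root), `node_type` (`"soma"`/`"neurite"`), `x`, `y`, `z`,
#'   `radius` (micrometres), with metadata in attributes.
#' @seealso [write_swc()], [compartment_summary()]
#' @export
read_swc <- function(path, neuron_id = NULL, ploidy = NA_character_,
                     brain_region = NA_character_) {
  if (!file.exists(path)) stop("SWC file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) == 0L) stop("SWC file has no data lines: ", path, call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    stop(sprintf("SWC format error in %s line %d: expected 7 columns", path,
                 line_no[bad[1]]), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop(sprintf("SWC format error in %s line %d: non-numeric field", path,
                 line_no[which(rowSums(is.na(m)) > 0)[1]]), call. = FALSE)
  nodes <- data.frame(
    node_id   = as.integer(m[, 1]),
    node_type = ifelse(m[, 2] == 1, "soma", "neurite"),
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius    = m[, 6],
    parent_id = as.integer(m[, 7])
  )
  bad_r <- which(nodes$radius <= 0)
  if (length(bad_r))
    stop(sprintf("SWC format error in %s line %d: non-positive radius", path,
                 line_no[bad_r[1]]), call. = FALSE)
  # remap ids to contiguous integers in file order
  id_map <- match(nodes$parent_id, nodes$node_id)
  roots <- which(nodes$parent_id < 0)
  orphan <- which(is.na(id_map) & nodes$parent_id >= 0)
  if (length(orphan))
    stop(sprintf("SWC format error in %s line %d: parent %d not defined", path,
                 line_no[orphan[1]], nodes$parent_id[orphan[1]]), call. = FALSE)
  nodes$parent_id <- id_map
  nodes$node_id <- seq_len(nrow(nodes))
  nodes$parent_id[roots] <- NA_integer_
  if (is.null(neuron_id)) neuron_id <- sub("\\.swc$", "", basename(path))
  new_neuron_tree(nodes, neuron_id = neuron_id, ploidy = ploidy,
                  brain_region = brain_region)
}

#' Write a neuron tree to an SWC file
#'
#' @param tree A `neuron_tree`.
#' @param path Output path.
#' @param digits Significant digits for coordinates and radii.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path, digits = 9) {
  stopifnot(inherits(tree, "neuron_tree"))
  n <- tree$nodes
  type_code <- ifelse(n$node_type == "soma", 1L, 3L)
  parent <- ifelse(is.na(n$parent_id), -1L, n$parent_id)
  num <- function(v) formatC(v, digits = digits, format = "g")
  lines <- sprintf("%d %d %s %s %s %s %d", n$node_id, type_code,
                   num(n$x), num(n$y), num(n$z), num(n$radius), parent)
  writeLines(c("# SWC generated by ploidyscale", lines), path)
  invisible(path)
}

# Construct + validate a neuron_tree from a node table.
new_neuron_tree <- function(nodes, neuron_id = NA_character_,
                            ploidy = NA_character_, brain_region = NA_character_) {
  req <- c("node_id", "parent_id", "node_type", "x", "y", "z", "radius")
  if (!all(req %in% names(nodes)))
    stop("node table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots), call. = FALSE)
  if (!any(nodes$node_type == "soma"))
    stop("tree must contain at least one soma node", call. = FALSE)
  if (any(nodes$radius <= 0)) stop("all radii must be positive", call. = FALSE)
  # connectivity/acyclicity: every node must reach the root by parent hops
  parent <- nodes$parent_id
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    reach <- which(is.na(depth) & !is.na(depth[parent]))
    if (length(reach)) {
      depth[reach] <- depth[parent[reach]] + 1L
      changed <- TRUE
    }
  }
  if (anyNA(depth))
    stop("tree is not connected/acyclic: nodes unreachable from root", call. = FALSE)
  structure(
    list(nodes = nodes,
         metadata = list(neuron_id = neuron_id, ploidy = ploidy,
                         brain_region = brain_region)),
    class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  n <- x$nodes
  cat(sprintf("<neuron_tree> %s (%s): %d nodes (%d soma, %d neurite)\n",
              x$metadata$neuron_id, x$metadata$ploidy, nrow(n),
              sum(n$node_type == "soma"), sum(n$node_type == "neurite")))
  invisible(x)
}
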