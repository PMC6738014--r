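# Plain-text I/O: node/element mesh format, legacy-VTK snapshots, trace CSV.

#' Write / read a mesh in the node/element text format
#'
#' Simple whitespace-separated format: a header line \code{nodes <n> <dim>},
#' n coordinate lines, a header \code{elements <m> <k>}, m connectivity
#' lines (1-based), and an optional \code{cell_type} block.
#'
#' @param mesh A \code{tissueModel}, or a list with \code{nodes} and
#'   \code{elements} (and optionally \code{cell_type}).
#' @param path File path.
#' @return \code{path} invisibly (write); a list or \code{tissueModel}
#'   (read).
#' @export
writeMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nodes <- as.matrix(mesh$nodes)
  el <- as.matrix(mesh$elements)
  writeLines(sprintf("nodes %d %d", nrow(nodes), ncol(nodes)), con)
  utils::write.table(format(nodes, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("elements %d %d", nrow(el), ncol(el)), con)
  utils::write.table(el, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(mesh$cell_type)) {
    writeLines(sprintf("cell_type %d", length(mesh$cell_type)), con)
    writeLines(mesh$cell_type, con)
  }
  invisible(path)
}

#' @rdname writeMesh
#' @param D,d_time_unit Diffusion settings used to reconstruct a
#'   \code{tissueModel} when the file carries a cell-type block.
#' @export
readMesh <- function(path, D = 0.00154, d_time_unit = "ms") {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n <- as.integer(hdr[2]); d <- as.integer(hdr[3])
  nodes <- matrix(as.numeric(unlist(strsplit(lines[2:(1 + n)], "\\s+"))),
                  n, d, byrow = TRUE)
  pos <- 2 + n
  hdr <- strsplit(lines[pos], "\\s+")[[1]]
  m <- as.integer(hdr[2]); k <- as.integer(hdr[3])
  el <- matrix(as.integer(unlist(strsplit(lines[(pos + 1):(pos + m)], "\\s+"))),
               m, k, byrow = TRUE)
  pos <- pos + m + 1
  if (pos <= length(lines) && startsWith(lines[pos], "cell_type")) {
    ct <- lines[(pos + 1):(pos + n)]
    return(tissueModel(nodes, el, ct, D = D, d_time_unit = d_time_unit))
  }
  list(nodes = nodes, elements = el)
}

#' Export a Vm snapshot as legacy ASCII VTK
#'
#' Unstructured-grid legacy VTK with one point scalar field (\code{Vm}),
#' suitable for ParaView-style visualization.
#'
#' @param model A \code{tissueModel}.
#' @param vm Per-node scalar (e.g. one column of a recording's \code{vm}).
#' @param path Output path.
#' @return \code{path} invisibly.
#' @export
writeVtkSnapshot <- function(model, vm, path) {
  nodes3 <- .embed3(model$nodes)
  el <- model$elements
  nv <- ncol(el)
  vtk_type <- c("3", "5", "10")[nv - 1] # line, triangle, tetra
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioscreen Vm snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(nodes3))), con)
  utils::write.table(nodes3, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(el), nrow(el) * (nv + 1)), con)
  utils::write.table(cbind(nv, el - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(el)), con)
  writeLines(rep(vtk_type, nrow(el)), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(nodes3)),
               "SCALARS Vm double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(vm, digits = 10), con)
  invisible(path)
}

#' Write an AP trace or ECG trace as CSV
#'
#' @param trace An \code{apTrace} (columns \code{time_ms, Vm_mV, Cai_mM}) or
#'   \code{ecgTrace} (columns \code{time_ms} plus one \code{<lead>_mV} per
#'   lead).
#' @param path Output path.
#' @return \code{path} invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  df <- if (inherits(trace, "apTrace")) {
    data.frame(time_ms = trace$time, Vm_mV = trace$vm, Cai_mM = trace$cai)
  } else if (inherits(trace, "ecgTrace")) {
    out <- data.frame(time_ms = trace$time)
    for (nm in rownames(trace$leads)) out[[paste0(nm, "_mV")]] <- trace$leads[nm, ]
    out
  } else stop("unsupported trace class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  utils::read.csv(path)
}
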