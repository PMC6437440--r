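#' Read a cell-by-species matrix from file
#'
#' Delimited tables (CSV/TSV: header row = species names, one row per
#' cell) and FCS 3.0/3.1 files (see [read_fcs()]). Missing values are
#' rejected. Cell identifiers default to 0-based row indices of the
#' input file.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"fcs"`.
#' @param channels optional include-list of species/channel names; an
#'   error listing the available names is raised if any is absent.
#' @param label_column optional column holding per-cell labels (CSV/TSV
#'   only); removed from the abundance matrix.
#' @return A [cell_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "fcs"),
                        channels = NULL, label_column = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fcs = "fcs", tsv = "tsv", txt = "tsv", "csv")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fcs") {
    x <- read_fcs(path, channels = channels)
    return(x)
  }
  if (file.size(path) == 0) stop("parse error: ", path, " is empty")
  dt <- data.table::fread(path, sep = if (format == "tsv") "\t" else ",",
                          header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) == 0) stop("parse error: no data rows in ", path)
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(dt))
      stop("label column '", label_column, "' not found; available: ",
           paste(names(dt), collapse = ", "))
    labels <- as.character(dt[[label_column]])
    dt[[label_column]] <- NULL
  }
  if (!is.null(channels)) {
    missing <- setdiff(channels, names(dt))
    if (length(missing))
      stop("channels not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(names(dt), collapse = ", "))
    dt <- dt[, channels, drop = FALSE]
  }
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop("parse error: non-numeric columns in ", path,
                           " (use label_column or channels to exclude them)")
  if (anyNA(m)) stop("matrix contains missing values; imputation is not supported")
  cell_matrix(m, labels = labels)
}

#' Write analysis results to a directory
#'
#' Writes `scores.csv` (node, node cell id, raw score, relative score on
#' the branch-node row), `branches.csv` (cell id, branch label), a
#' nested `hierarchy.json` for recursive results plus a flat
#' `branch_paths.csv` (cell id, `/`-separated path of branch labels),
#' and `manifest.json` (package version, seed, key parameters, and an
#' md5 checksum per output file). Output is deterministic: identical
#' results produce byte-identical files. Existing files are overwritten.
#'
#' @param result a `branching_result` or `branch_hierarchy`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a data.frame registry of files and checksums.
#' @export
write_results <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(result, "branch_hierarchy")) {
    res <- result$result
    hpath <- file.path(outdir, "hierarchy.json")
    jsonlite::write_json(.hierarchy_to_list(result), hpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, hpath)
    paths <- .hierarchy_cell_paths(result)
    ppath <- file.path(outdir, "branch_paths.csv")
    data.table::fwrite(paths, ppath)
    files <- c(files, ppath)
  } else {
    res <- result
  }
  ens <- res$ensemble
  scores <- data.frame(node = seq_along(res$raw_scores),
                       cell_id = res$cell_ids[ens$nodes$node_cells],
                       raw_score = res$raw_scores,
                       relative_score = ifelse(
                         seq_along(res$raw_scores) == res$branch_node,
                         res$relative_score, NA_real_))
  spath <- file.path(outdir, "scores.csv")
  data.table::fwrite(scores, spath)
  branches <- data.frame(cell_id = res$cell_ids,
                         branch = res$cell_branches)
  bpath <- file.path(outdir, "branches.csv")
  data.table::fwrite(branches, bpath)
  files <- c(files, spath, bpath)
  manifest <- list(
    package = "treetop",
    version = as.character(utils::packageVersion("treetop")),
    seed = res$seed,
    parameters = list(k = res$config$k, n_trees = res$config$n_trees,
                      metric = res$config$metric, sigma = res$sigma,
                      min_cells = res$config$min_cells),
    files = lapply(setNames(basename(files), basename(files)),
                   function(f) unname(tools::md5sum(file.path(outdir, f)))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mpath)
  invisible(data.frame(file = files, md5 = unname(tools::md5sum(files))))
}

.hierarchy_to_list <- function(h) {
  res <- h$result
  out <- list(depth = h$depth, n_cells = h$n_cells,
              branch_node = res$branch_node,
              max_raw_score = max(res$raw_scores),
              relative_score = res$relative_score,
              n_branches = length(res$branches))
  kids <- lapply(h$children, .hierarchy_to_list)
  leaves <- as.list(h$leaf_reasons)
  out$children <- kids
  out$leaves <- leaves
  out
}

# cell_id -> "1/2"-style path of branch labels through the hierarchy
.hierarchy_cell_paths <- function(h, prefix = character(0)) {
  res <- h$result
  ids <- h$cell_ids
  path_here <- if (length(prefix)) paste(prefix, collapse = "/") else ""
  lab <- res$cell_branches
  out <- data.table::data.table(cell_id = ids, path = NA_character_)
  for (b in seq_along(res$branches)) {
    sel <- which(lab == as.character(b))
    out$path[sel] <- paste(c(prefix, b), collapse = "/")
  }
  out$path[lab == "branch point"] <- paste(c(prefix, "branch point"), collapse = "/")
  for (nm in names(h$children)) {
    child <- .hierarchy_cell_paths(h$children[[nm]], prefix = c(prefix, nm))
    out[match(child$cell_id, out$cell_id), "path"] <- child$path
  }
  out
}
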