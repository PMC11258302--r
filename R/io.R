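#' Construct an annotated expression dataset
#'
#' Lightweight container holding a cells x genes abundance matrix together
#' with optional per-cell labels, a 2D embedding, and neighbor-smoothed
#' moments. All downstream steps of the package operate on this container.
#'
#' @param matrix numeric cells x genes matrix of non-negative abundances.
#' @param gene_names,cell_names unique identifiers; default to dimnames.
#' @param cell_labels optional per-cell categorical labels.
#' @param embedding optional cells x 2 coordinate matrix.
#' @param smoothed,smoothed_sq optional first/second-order moment matrices of
#'   the same shape as `matrix` (see [compute_moments()]).
#' @param normalized logical, whether per-cell normalization was applied.
#' @return an object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(matrix, gene_names = NULL, cell_names = NULL,
                               cell_labels = NULL, embedding = NULL,
                               smoothed = NULL, smoothed_sq = NULL,
                               normalized = FALSE) {
  matrix <- as.matrix(matrix)
  if (length(matrix) == 0L) stop("expression matrix is empty", call. = FALSE)
  if (anyNA(matrix) || any(matrix < 0))
    stop("expression matrix must be non-negative and finite", call. = FALSE)
  gene_names <- as.character(gene_names %||% colnames(matrix) %||%
                               paste0("gene", seq_len(ncol(matrix))))
  cell_names <- as.character(cell_names %||% rownames(matrix) %||%
                               paste0("cell", seq_len(nrow(matrix))))
  if (length(gene_names) != ncol(matrix) || anyDuplicated(gene_names))
    stop("gene_names must be unique and match ncol(matrix)", call. = FALSE)
  if (length(cell_names) != nrow(matrix) || anyDuplicated(cell_names))
    stop("cell_names must be unique and match nrow(matrix)", call. = FALSE)
  dimnames(matrix) <- list(cell_names, gene_names)
  if (!is.null(cell_labels) && length(cell_labels) != nrow(matrix))
    stop("cell_labels must have one entry per cell", call. = FALSE)
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nrow(matrix) || ncol(embedding) != 2L)
      stop("embedding must be a cells x 2 matrix", call. = FALSE)
  }
  for (m in list(smoothed, smoothed_sq))
    if (!is.null(m) && !identical(dim(as.matrix(m)), dim(matrix)))
      stop("moment matrices must match the expression matrix shape",
           call. = FALSE)
  structure(list(matrix = matrix, gene_names = gene_names,
                 cell_names = cell_names, cell_labels = cell_labels,
                 embedding = embedding, smoothed = smoothed,
                 smoothed_sq = smoothed_sq, normalized = normalized),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  normalized: %s | smoothed: %s | labels: %s | embedding: %s\n",
              x$normalized, !is.null(x$smoothed), !is.null(x$cell_labels),
              !is.null(x$embedding)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Read an expression matrix from file
#'
#' Reads a cells x genes abundance table. For annotated containers (h5ad,
#' loom) the layers named `"spliced"` and `"unspliced"`, when both present,
#' are summed into total counts; otherwise the main matrix is used as total
#' counts. The original count scale is preserved (no normalization here).
#' Reading HDF5-backed formats requires the `rhdf5` package.
#'
#' @param path input file.
#' @param format one of `"csv"`, `"tsv"`, `"h5ad"`, `"loom"`. Defaults to the
#'   file extension.
#' @return an [expression_dataset()].
#' @export
load_expression <- function(path, format = c("auto", "csv", "tsv", "h5ad", "loom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     h5ad = "h5ad", loom = "loom",
                     stop("cannot infer format from extension '", ext, "'",
                          call. = FALSE))
  }
  switch(format,
         csv = read_dense_expression(path, sep = ","),
         tsv = read_dense_expression(path, sep = "\t"),
         h5ad = read_h5ad_expression(path),
         loom = read_loom_expression(path))
}

read_dense_expression <- function(path, sep) {
  df <- tryCatch(read.delim(path, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty expression table: ", path, call. = FALSE)
  cell_names <- NULL
  if (!is.numeric(df[[1]])) {            # leading cell-identifier column
    cell_names <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  mat <- as.matrix(df)
  if (!is.numeric(mat)) stop("non-numeric entries in ", path, call. = FALSE)
  mode(mat) <- "double"
  expression_dataset(mat, gene_names = colnames(df), cell_names = cell_names)
}

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("reading HDF5-backed formats requires the 'rhdf5' package; ",
         "export the matrix to CSV/TSV instead", call. = FALSE)
}

h5_names <- function(path, group) {
  ls <- rhdf5::h5ls(path)
  ls$name[ls$group == group]
}

# minimal h5ad reader: dense or CSR/CSC X and layers, var/_index, obs/_index,
# optional categorical obs column and obsm/X_umap
read_h5ad_expression <- function(path) {
  need_rhdf5()
  read_x <- function(name) {
    x <- rhdf5::h5read(path, name, read.attributes = TRUE)
    if (is.list(x)) {                    # sparse group: data/indices/indptr
      at <- rhdf5::h5readAttributes(path, name)
      shape <- as.integer(at$shape)
      enc <- as.character(at[["encoding-type"]] %||% "csr_matrix")
      dense_from_compressed(x, shape, startsWith(enc, "csr"))
    } else {
      # HDF5 row-major storage arrives transposed (genes x cells)
      t(as.matrix(x))
    }
  }
  mat <- read_x("X")
  layers <- tryCatch(h5_names(path, "/layers"), error = function(e) character())
  if (all(c("spliced", "unspliced") %in% layers))
    mat <- read_x("layers/spliced") + read_x("layers/unspliced")
  gene_names <- as.character(rhdf5::h5read(path, "var/_index"))
  cell_names <- as.character(rhdf5::h5read(path, "obs/_index"))
  obs <- h5_names(path, "/obs")
  labcol <- intersect(c("clusters", "cell_type", "celltype"), obs)
  labels <- if (length(labcol)) read_h5ad_categorical(path, paste0("obs/", labcol[1]))
  obsm <- tryCatch(h5_names(path, "/obsm"), error = function(e) character())
  emb <- if ("X_umap" %in% obsm) t(as.matrix(rhdf5::h5read(path, "obsm/X_umap")))
  expression_dataset(mat, gene_names = gene_names, cell_names = cell_names,
                     cell_labels = labels, embedding = emb)
}

read_h5ad_categorical <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  if (is.list(x) && all(c("categories", "codes") %in% names(x)))
    as.character(x$categories)[as.integer(x$codes) + 1L]
  else as.character(x)
}

dense_from_compressed <- function(x, shape, by_row) {
  out <- matrix(0, shape[1], shape[2])
  ptr <- as.integer(x$indptr); idx <- as.integer(x$indices)
  val <- as.numeric(x$data)
  for (i in seq_len(length(ptr) - 1L)) {
    if (ptr[i + 1L] > ptr[i]) {
      j <- (ptr[i] + 1L):ptr[i + 1L]
      if (by_row) out[i, idx[j] + 1L] <- val[j] else out[idx[j] + 1L, i] <- val[j]
    }
  }
  out
}

# loom convention: main matrix is genes x cells
read_loom_expression <- function(path) {
  need_rhdf5()
  mat <- as.matrix(rhdf5::h5read(path, "matrix"))
  layers <- tryCatch(h5_names(path, "/layers"), error = function(e) character())
  if (all(c("spliced", "unspliced") %in% layers))
    mat <- as.matrix(rhdf5::h5read(path, "layers/spliced")) +
      as.matrix(rhdf5::h5read(path, "layers/unspliced"))
  # h5read returns column-major view of the row-major file: cells x genes here
  gene_names <- as.character(rhdf5::h5read(path, "row_attrs/Gene"))
  cell_names <- tryCatch(as.character(rhdf5::h5read(path, "col_attrs/CellID")),
                         error = function(e) NULL)
  if (nrow(mat) == length(gene_names)) mat <- t(mat)
  expression_dataset(mat, gene_names = gene_names, cell_names = cell_names)
}

#' Filter genes, select highly variable genes and normalize per cell
#'
#' Removes genes detected (count > 0) in fewer than `min_cell_fraction` of
#' cells, keeps the `n_top` genes with the highest mean-binned normalized
#' dispersion, then normalizes each cell by its total count over the
#' retained genes (rescaled to the median library size).
#'
#' @param ds an [expression_dataset()] of raw counts.
#' @param min_cell_fraction minimum detection fraction (default 0.02).
#' @param n_top number of highly variable genes to keep (default 2000).
#' @param n_bins number of gene-mean bins for dispersion normalization.
#' @return a normalized [expression_dataset()] restricted to selected genes.
#' @export
filter_and_select <- function(ds, min_cell_fraction = 0.02, n_top = 2000,
                              n_bins = 20) {
  stopifnot(inherits(ds, "expression_dataset"))
  mat <- ds$matrix
  frac <- colMeans(mat > 0)
  keep <- frac >= min_cell_fraction
  if (!any(keep)) stop("all genes removed by detection filter", call. = FALSE)
  mat <- mat[, keep, drop = FALSE]

  if (ncol(mat) > n_top) {
    disp <- normalized_dispersion(mat, n_bins = n_bins)
    ord <- order(-disp, colnames(mat))      # ties broken by gene name
    mat <- mat[, sort(ord[seq_len(n_top)]), drop = FALSE]
  }

  totals <- rowSums(mat)
  if (any(totals == 0)) stop("cells with zero total count after gene selection",
                             call. = FALSE)
  norm <- mat * (median(totals) / totals)
  expression_dataset(norm, cell_labels = ds$cell_labels,
                     embedding = ds$embedding, normalized = TRUE)
}

# mean-binned normalized dispersion (dispersion = var/mean, z-scored within
# 20 quantile bins of the gene mean)
normalized_dispersion <- function(mat, n_bins = 20) {
  mu <- colMeans(mat)
  v <- apply(mat, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  out <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- sd(disp[i])
    out[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  out
}

#' Smooth expression over the nearest-neighbor graph
#'
#' Builds a kNN graph from Euclidean distances in the top principal
#' components of the log1p-transformed normalized matrix, then replaces each
#' cell's expression by the mean over its neighbor set (which includes the
#' cell itself): first-order moments. Second-order (uncentered) moments are
#' computed analogously from squared values.
#'
#' @param ds a normalized [expression_dataset()].
#' @param n_pcs number of principal components (default 30).
#' @param n_neighbors neighborhood size including the cell itself (default 30).
#' @return the dataset with `smoothed` and `smoothed_sq` filled in.
#' @export
compute_moments <- function(ds, n_pcs = 30, n_neighbors = 30) {
  stopifnot(inherits(ds, "expression_dataset"))
  n <- nrow(ds$matrix)
  if (n_neighbors >= n)
    stop("n_neighbors must be smaller than the number of cells", call. = FALSE)
  pcs <- pca_coords(log1p(ds$matrix), n_pcs)
  nn <- knn_indices(pcs, k = n_neighbors, include_self = TRUE)
  ds$smoothed <- neighbor_mean(ds$matrix, nn)
  ds$smoothed_sq <- neighbor_mean(ds$matrix^2, nn)
  ds$neighbors <- nn
  ds
}

pca_coords <- function(mat, n_pcs) {
  n_pcs <- min(n_pcs, ncol(mat), nrow(mat) - 1L)
  prcomp(mat, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
}

# exact kNN by brute-force distance ranking; rows of the result index the
# k nearest cells (optionally counting the cell itself as one of them)
knn_indices <- function(coords, k, include_self = FALSE) {
  d <- as.matrix(stats::dist(coords))
  if (!include_self) diag(d) <- Inf
  n <- nrow(d)
  m <- vapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)], integer(k))
  if (k == 1) matrix(m, ncol = 1) else t(m)
}

neighbor_mean <- function(mat, nn) {
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat)))
    out[i, ] <- colMeans(mat[nn[i, ], , drop = FALSE])
  out
}

#' Load TF-to-target regulatory prior tables
#'
#' Reads one or more two-column (tf, target) edge lists (tab- or
#' whitespace-separated; `#` comment lines and an optional `tf target`
#' header allowed) and returns their deduplicated union. Matching against
#' expression data is case-insensitive, so names are stored uppercased.
#'
#' @param paths character vector of file paths. Names, if set, are used as
#'   the per-file source tag (e.g. `c(ENCODE = "encode.tsv", ChEA = "chea.tsv")`).
#' @return a data.frame with columns `tf`, `target`, `source`.
#' @examples
#' paths <- c(ENCODE = system.file("extdata", "encode_synthetic.tsv",
#'                                 package = "velotf"),
#'            ChEA = system.file("extdata", "chea_synthetic.tsv",
#'                               package = "velotf"))
#' load_tf_target_priors(paths)
#' @export
load_tf_target_priors <- function(paths) {
  tags <- names(paths) %||% basename(paths)
  if (is.null(names(paths))) names(paths) <- tags
  out <- list()
  for (i in seq_along(paths)) {
    lines <- readLines(paths[[i]], warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- list()
    for (ln in which(keep)) {
      fields <- strsplit(trimws(lines[ln]), "[\t ]+")[[1]]
      if (length(fields) != 2L)
        stop(sprintf("malformed line %d in %s: expected 2 fields, got %d",
                     ln, paths[[i]], length(fields)), call. = FALSE)
      rows[[length(rows) + 1L]] <- fields
    }
    if (!length(rows)) next
    m <- do.call(rbind, rows)
    if (tolower(m[1, 1]) %in% c("tf", "regulator") ) m <- m[-1, , drop = FALSE]
    if (nrow(m))
      out[[i]] <- data.frame(tf = toupper(m[, 1]), target = toupper(m[, 2]),
                             source = tags[i], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tf = character(), target = character(),
                      source = character(), stringsAsFactors = FALSE))
  edges <- do.call(rbind, out)
  edges[!duplicated(edges[, c("tf", "target")]), , drop = FALSE]
}

#' Assemble the fitting problem for one target gene
#'
#' Collects the prior TFs of `target` present in the dataset, drops cells in
#' which the target is not expressed, and scales the target vector and every
#' TF row to unit standard deviation (the scale the fitter operates on).
#' Smoothed moments are used when available.
#'
#' @param ds an [expression_dataset()].
#' @param priors prior table from [load_tf_target_priors()].
#' @param target gene identifier (case-insensitive).
#' @param min_cells minimum number of expressing cells required (default 10).
#' @return an object of class `"gene_problem"` with elements `X` (n_TF x
#'   n_cell, unit-sd rows), `y` (unit-sd), `tf_names`, `kept_cell_indices`,
#'   and the scale factors `sd_y`, `sd_x` needed to map back to input units.
#'   Signals a `velotf_skip` condition when the gene cannot be fitted.
#' @export
assemble_gene_problem <- function(ds, priors, target, min_cells = 10) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes_uc <- toupper(ds$gene_names)
  ti <- match(toupper(target), genes_uc)
  if (is.na(ti)) stop("target gene not present: ", target, call. = FALSE)
  tfs <- unique(toupper(priors$tf[toupper(priors$target) == toupper(target)]))
  tfs <- setdiff(tfs, toupper(target))
  tfi <- match(tfs, genes_uc)
  tfi <- tfi[!is.na(tfi)]
  if (!length(tfi)) skip_gene(paste0("no prior TFs present for ", target))

  mat <- ds$smoothed %||% ds$matrix
  y_all <- mat[, ti]
  keep <- unname(which(y_all != 0))
  if (length(keep) < min_cells)
    skip_gene(paste0("fewer than ", min_cells, " expressing cells for ", target))
  y <- y_all[keep]
  X <- t(mat[keep, tfi, drop = FALSE])
  sd_x <- apply(X, 1, sd)
  ok <- sd_x > 0
  if (!any(ok)) skip_gene(paste0("all TFs constant for ", target))
  X <- X[ok, , drop = FALSE]; sd_x <- sd_x[ok]
  sd_y <- sd(y)
  if (sd_y == 0) skip_gene(paste0("constant target expression for ", target))
  structure(list(target_name = ds$gene_names[ti],
                 X = X / sd_x, y = y / sd_y,
                 tf_names = ds$gene_names[tfi][ok],
                 kept_cell_indices = keep, sd_y = sd_y, sd_x = sd_x),
            class = "gene_problem")
}

#' @export
print.gene_problem <- function(x, ...) {
  cat(sprintf("<gene_problem> target %s: %d TFs x %d cells\n",
              x$target_name, nrow(x$X), ncol(x$X)))
  invisible(x)
}
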