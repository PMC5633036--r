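#' Construct a count matrix container
#'
#' Bundles a gene x sample matrix of non-negative expression values with
#' optional per-sample class labels. Genes are rows and samples are columns
#' throughout the package (the p x n convention of the RNA-seq classification
#' literature). Raw counts are integers; normalized counts may be fractional.
#'
#' @param counts numeric matrix (or coercible), genes in rows, samples in
#'   columns. All entries must be finite and >= 0. Row and column names are
#'   used as gene and sample identifiers; defaults are generated if absent.
#' @param labels optional per-sample class labels (character or factor,
#'   length `ncol(counts)`). Arbitrary strings are mapped to classes
#'   1..K in first-appearance order. Every class must contain at least two
#'   samples.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix with dimnames) and `labels` (factor or `NULL`).
#' @examples
#' m <- count_matrix(matrix(rpois(12, 10), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))),
#'   labels = c("A", "A", "B", "B"))
#' m
#' @export
count_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts))) {
    stop("count matrix contains missing or non-finite entries")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene %d, sample %d", bad[1], bad[2]))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%0*d", nchar(nrow(counts)), seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample%0*d", nchar(ncol(counts)), seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample identifiers must be unique")
  if (!is.null(labels)) {
    labels <- as_class_factor(labels)
    if (length(labels) != ncol(counts)) {
      stop("labels must have one entry per sample")
    }
    if (any(table(labels) < 2)) {
      stop("every class must contain at least two samples")
    }
    names(labels) <- colnames(counts)
  }
  structure(list(counts = counts, labels = labels), class = "count_matrix")
}

# Map arbitrary labels to a factor whose levels follow first appearance,
# so classes are numbered 1..K in the order they occur in the input.
as_class_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  factor(labels, levels = unique(labels))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("classes:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("classes: none\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' `m[i, j]` subsets genes (`i`) and/or samples (`j`), carrying labels along.
#' Class-size invariants are not re-checked on subsets used internally for
#' cross-validation; subsetting to a single sample per class is allowed.
#'
#' @param x a `count_matrix`
#' @param i gene index (integer, logical or character)
#' @param j sample index
#' @param ... ignored
#' @return a `count_matrix`
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  labels <- if (!is.null(x$labels)) {
    l <- x$labels[j]
    factor(l, levels = levels(x$labels)[levels(x$labels) %in% unique(as.character(l))])
  }
  out <- list(counts = counts, labels = labels)
  class(out) <- "count_matrix"
  out
}

#' Read a count matrix (and optional labels) from a delimited file
#'
#' Expects a rectangular table whose first column holds gene identifiers and
#' whose header row holds sample identifiers. The delimiter is inferred from
#' the extension (`.csv` comma, otherwise tab) unless given explicitly.
#'
#' @param path path to the count table
#' @param label_path optional path to a two-column table with columns
#'   `sample` and `class`; labels are joined to the counts by sample ID
#' @param sep field separator; `NULL` to infer from the extension
#' @return a [count_matrix()]
#' @export
read_counts <- function(path, label_path = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("count table needs a gene-ID column and at least one sample")
  genes <- tab[[1]]
  body <- tab[, -1, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(genes, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   body[[j]][i], genes[i], colnames(body)[j]))
    }
    mat[, j] <- v
  }
  labels <- if (!is.null(label_path)) read_labels(label_path, colnames(mat))
  count_matrix(mat, labels)
}

#' Read a sample-to-class label table
#'
#' @param path two-column delimited file with header `sample`, `class`
#' @param samples sample identifiers the labels must cover, in the order the
#'   returned labels should follow
#' @param sep field separator; `NULL` to infer from the extension
#' @return factor of classes, one per element of `samples`
#' @export
read_labels <- function(path, samples, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (!all(c("sample", "class") %in% colnames(tab))) {
    stop("label table must have columns 'sample' and 'class'")
  }
  unknown <- setdiff(tab$sample, samples)
  if (length(unknown)) {
    stop(sprintf("label given for unknown sample(s): %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  missing <- setdiff(samples, tab$sample)
  if (length(missing)) {
    stop(sprintf("no label for sample(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  cls <- tab$class[match(samples, tab$sample)]
  as_class_factor(cls)
}

#' Write a count matrix to a delimited file
#'
#' Inverse of [read_counts()]: writes a header row of sample IDs and a first
#' column of gene IDs. Integer-valued matrices are written without decimals
#' so that a write/read round trip is exact.
#'
#' @param m a `count_matrix`
#' @param path output path; `.csv` writes comma-separated, otherwise tabs
#' @param label_path optional path for a `sample`/`class` label table
#' @return `path`, invisibly
#' @export
write_counts <- function(m, path, label_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  counts <- m$counts
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(label_path)) {
    if (is.null(m$labels)) stop("count matrix has no labels to write")
    lsep <- if (grepl("\\.csv$", label_path, ignore.case = TRUE)) "," else "\t"
    ldf <- data.frame(sample = colnames(counts), class = as.character(m$labels))
    utils::write.table(ldf, label_path, sep = lsep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Filter genes with near-zero variance
#'
#' Removes genes whose value distribution is nearly degenerate in the
#' training samples. A gene is removed when BOTH hold: (i) the ratio of the
#' frequency of its most common value to that of its second most common
#' value exceeds `freq_cut` (default 19, i.e. a 95/5 split), and (ii) the
#' number of unique values divided by the sample size is below `unique_cut`
#' (default 10%). Constant genes (a single unique value) are always removed.
#'
#' @param m a `count_matrix` with at least two samples
#' @param freq_cut threshold on the most-frequent / second-most-frequent
#'   value ratio
#' @param unique_cut threshold on the proportion of unique values
#' @return list with `kept` (filtered `count_matrix`, original gene order
#'   preserved) and `removed` (character vector of dropped gene IDs)
#' @export
near_zero_filter <- function(m, freq_cut = 19, unique_cut = 0.10) {
  counts <- m$counts
  n <- ncol(counts)
  if (n < 2) stop("near-zero filtering needs at least two samples")
  drop <- vapply(seq_len(nrow(counts)), function(g) {
    tab <- sort(tabulate(factor(counts[g, ])), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)          # zero variance
    freq_ratio <- tab[1] / tab[2]
    uniq_prop <- length(tab) / n
    freq_ratio > freq_cut && uniq_prop < unique_cut
  }, logical(1))
  list(kept = m[!drop, ], removed = rownames(counts)[drop])
}

#' Keep the genes with the largest variance on a stabilized scale
#'
#' Ranks genes by the variance of `log2(count / size_factor + 1)` across
#' samples and keeps the top `k`, returned in decreasing-variance order.
#' The original (untransformed) counts of the selected genes are returned;
#' the transformation is used only for ranking. Ties are broken by input
#' gene order for determinism.
#'
#' @param m a `count_matrix`
#' @param k number of genes to keep (`k <= nrow(m$counts)`)
#' @param size_factors optional per-sample size factors used in the ranking
#'   transform (e.g. from [deseq_size_factors()]); defaults to 1
#' @return a `count_matrix` of the `k` selected genes
#' @export
variance_filter <- function(m, k, size_factors = NULL) {
  counts <- m$counts
  p <- nrow(counts)
  if (k > p) stop(sprintf("k = %d exceeds the %d available genes", k, p))
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  if (!is.null(names(size_factors))) size_factors <- size_factors[colnames(counts)]
  lv <- log2(sweep(counts, 2, size_factors, "/") + 1)
  vars <- rowVars_(lv)
  ord <- order(-vars, seq_len(p))
  m[ord[seq_len(k)], ]
}

# Row variances with divisor n - 1, without matrixStats.
rowVars_ <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
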