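#' Construct an expression study
#'
#' Container for a gene x sample matrix of log2 intensities together with the
#' sample-to-state design. Gene symbols are uppercased; duplicate symbols are
#' an error (collapse them first, see [read_expression()]).
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids). All values must be finite.
#' @param design either a named character vector (names = sample ids, values
#'   = state labels) or a two-column data frame `sample`, `state`.
#' @param states optional ordering of state labels; defaults to order of
#'   first appearance in `design`.
#' @return an object of class `expression_study` with elements `values`,
#'   `design` (named character vector), `states`.
#' @export
expression_study <- function(values, design, states = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs gene rownames and sample colnames")
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols; collapse before constructing the study")
  if (is.data.frame(design)) {
    d <- as.character(design[[2L]])
    names(d) <- as.character(design[[1L]])
    design <- d
  }
  missing <- setdiff(colnames(values), names(design))
  if (length(missing))
    stop("sample(s) absent from design: ", paste(missing, collapse = ", "))
  design <- design[colnames(values)]
  if (is.null(states)) states <- unique(unname(design))
  if (!setequal(states, unique(design)))
    stop("'states' must cover exactly the states present in the design")
  cnt <- table(factor(design, levels = states))
  if (any(cnt < 2L))
    stop("every state needs >= 2 samples; offending: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  structure(list(values = values, design = design, states = states),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n  states:",
      paste(sprintf("%s(%d)", x$states,
                    as.integer(table(factor(x$design, levels = x$states)))),
            collapse = " "), "\n")
  invisible(x)
}

#' Samples belonging to one state
#' @param study an `expression_study`
#' @param state a state label present in the design
#' @return character vector of sample ids
#' @export
state_samples <- function(study, state) {
  if (!state %in% study$states) stop("unknown state: ", state)
  names(study$design)[study$design == state]
}

#' Subset a study to selected samples
#' @param study an `expression_study`
#' @param samples sample ids to keep
#' @return a new `expression_study`; note the >=2-samples-per-state rule
#'   still applies to the retained states.
#' @export
subset_samples <- function(study, samples) {
  miss <- setdiff(samples, colnames(study$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  d <- study$design[samples]
  expression_study(study$values[, samples, drop = FALSE], d,
                   states = unique(unname(d)))
}

#' Read a gene x sample expression matrix plus sample sheet
#'
#' The matrix is a TSV with a header row of sample ids and gene/probe symbols
#' in the first column; the design TSV maps `sample` to `state` (two columns,
#' header optional). Duplicate symbols (after uppercasing) are collapsed.
#'
#' @param matrix_path path to the expression TSV.
#' @param design_path path to the sample sheet TSV.
#' @param collapse_rule how to collapse duplicate symbols: `"max_mean"`
#'   (keep the row with highest mean intensity, the default microarray
#'   convention) or `"mean"` (average the rows).
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` to raw intensities.
#' @return an [expression_study()]
#' @export
read_expression <- function(matrix_path, design_path,
                            collapse_rule = c("max_mean", "mean"),
                            log2_transform = FALSE) {
  collapse_rule <- match.arg(collapse_rule)
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty expression matrix: ", matrix_path)
  sym <- toupper(as.character(tab[[1L]]))
  num <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(num)) {
    conv <- suppressWarnings(matrix(as.numeric(num), nrow(num), ncol(num)))
    bad <- which(is.na(conv), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad[1L, 1L], colnames(num)[bad[1L, 2L]]))
    storage.mode(num) <- "double"
  }
  if (log2_transform) num <- log2(num + 1)
  rownames(num) <- sym
  if (anyDuplicated(sym)) {
    if (collapse_rule == "max_mean") {
      mu <- rowMeans(num)
      keep <- unlist(lapply(split(seq_along(sym), sym), function(i) i[which.max(mu[i])]))
      num <- num[sort(keep), , drop = FALSE]
    } else {
      num <- do.call(rbind, lapply(split(seq_len(nrow(num)), sym), function(i)
        colMeans(num[i, , drop = FALSE])))
    }
  }
  des <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(des) < 2L) stop("design must have two columns: sample, state")
  if (!all(c("sample", "state") %in% names(des))) {
    # headerless two-column sheet: first data row was consumed as header
    des <- utils::read.delim(design_path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
  } else {
    des <- des[, c("sample", "state")]
  }
  d <- as.character(des[[2L]])
  names(d) <- as.character(des[[1L]])
  expression_study(num, d)
}

#' Write an expression study to TSV
#' @param study an `expression_study`
#' @param matrix_path,design_path output paths
#' @export
write_expression <- function(study, matrix_path, design_path) {
  tab <- data.frame(gene = rownames(study$values), study$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- data.frame(sample = names(study$design), state = unname(study$design),
                    stringsAsFactors = FALSE)
  utils::write.table(des, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Construct a protein-protein interaction graph
#'
#' A simple undirected graph over gene symbols: self-loops are dropped and
#' duplicate edges (in either orientation) merged.
#'
#' @param edges two-column data frame / matrix of symbol pairs.
#' @return an object of class `ppi_graph` with `edges` (data frame `a`, `b`,
#'   canonical order a < b), `nodes`, and attributes `n_self_dropped`,
#'   `n_dup_dropped`.
#' @export
ppi_graph <- function(edges) {
  a <- toupper(as.character(edges[[1L]]))
  b <- toupper(as.character(edges[[2L]]))
  self <- a == b
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  o <- order(lo, hi)  # canonical edge order: input order never matters
  out <- structure(
    list(edges = data.frame(a = lo[o], b = hi[o], stringsAsFactors = FALSE),
         nodes = sort(unique(c(lo, hi)))),
    class = "ppi_graph")
  attr(out, "n_self_dropped") <- sum(self)
  attr(out, "n_dup_dropped") <- sum(dup)
  out
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("ppi_graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a PPI edge list (HPRD-style two-column TSV)
#'
#' Extra columns are ignored; counts of dropped self-loops and duplicates are
#' reported via [message()].
#'
#' @param path path to the TSV (no header).
#' @return a [ppi_graph()]
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(ppi_graph(data.frame(a = character(), b = character())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 2L)
  if (length(short))
    stop(sprintf("line %d of '%s' has fewer than 2 fields", short[1L], path))
  g <- ppi_graph(data.frame(a = vapply(fields, `[`, "", 1L),
                            b = vapply(fields, `[`, "", 2L),
                            stringsAsFactors = FALSE))
  nd <- attr(g, "n_self_dropped") + attr(g, "n_dup_dropped")
  if (nd > 0)
    message(sprintf("read_ppi: dropped %d self-loop(s) and %d duplicate line(s)",
                    attr(g, "n_self_dropped"), attr(g, "n_dup_dropped")))
  g
}

#' Write a PPI graph as a two-column TSV
#' @param ppi a `ppi_graph`
#' @param path output path
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ppi)
}

#' Construct a gene catalog
#' @param symbols character vector of gene symbols (case-insensitive).
#' @param category optional category label per symbol.
#' @return object of class `gene_catalog`: `symbols` (unique, uppercased)
#'   and `category` (named by symbol, possibly NA).
#' @export
gene_catalog <- function(symbols, category = NULL) {
  sym <- toupper(as.character(symbols))
  if (is.null(category)) category <- rep(NA_character_, length(sym))
  keep <- !duplicated(sym)
  cat_ <- as.character(category)[keep]
  names(cat_) <- sym[keep]
  structure(list(symbols = sym[keep], category = cat_), class = "gene_catalog")
}

#' Read a one-or-two-column gene list (symbol, optional category)
#' @param path path to the TSV (no header).
#' @return a [gene_catalog()]
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sym <- vapply(fields, `[`, "", 1L)
  cat_ <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_, "")
  gene_catalog(sym, cat_)
}

#' Construct a gene-set collection (GMT semantics)
#' @param sets named list of character vectors (members, non-empty).
#' @param descriptions optional character vector parallel to `sets`.
#' @return object of class `gene_sets`: a named list with a `descriptions`
#'   attribute.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  if (length(sets) == 0L)
    return(structure(stats::setNames(list(), character()),
                     descriptions = stats::setNames(character(), character()),
                     class = "gene_sets"))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(vapply(sets, length, 1L) == 0L))
    stop("gene set with no members")
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_sets")
}

#' Read a GMT file (set name TAB description TAB member...)
#' @param path path to the GMT file.
#' @return a [gene_sets()] collection
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, "", 1L)
  desc <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "", "")
  members <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  empty <- which(vapply(members, length, 1L) == 0L)
  if (length(empty))
    stop(sprintf("GMT set '%s' (line %d) has no members", nm[empty[1L]], empty[1L]))
  gene_sets(stats::setNames(members, nm), desc)
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_sets` collection
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}

# TSV writer with '#'-prefixed header lines recording parameters/seed
.write_tsv <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
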