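#' Configuration of the trend-of-progression (ToP) predicate
#'
#' @param min_hub_degree exclusive degree threshold for the hub criterion
#'   (a gene must exceed it, default 4).
#' @param require_positive_C the hub state must also have C > 0.
#' @param trend_mode `"into_final_strict"` (default): the final state's D
#'   strictly exceeds every earlier state's D and its C is at least every
#'   earlier C minus `c_tolerance` -- transitions among the earlier states
#'   are unconstrained; `"into_final_weak"`: as above with D compared
#'   weakly (>=); `"monotone"`: D and C non-decreasing across every
#'   consecutive transition.
#' @param c_tolerance slack epsilon for the C comparison (>= 0, default 0).
#' @param hub_joint if `TRUE` (default) the degree and C conditions of the
#'   hub criterion must hold in the same state.
#' @return an object of class `top_config`
#' @export
top_config <- function(min_hub_degree = 4, require_positive_C = TRUE,
                       trend_mode = c("into_final_strict", "into_final_weak",
                                      "monotone"),
                       c_tolerance = 0, hub_joint = TRUE) {
  stopifnot(min_hub_degree >= 0, c_tolerance >= 0)
  structure(list(min_hub_degree = min_hub_degree,
                 require_positive_C = require_positive_C,
                 trend_mode = match.arg(trend_mode),
                 c_tolerance = c_tolerance, hub_joint = hub_joint),
            class = "top_config")
}

#' Configuration of the early-detection-marker rule
#'
#' @param degree_fold minimum fold increase of network degree from the
#'   first (healthy) state to the intermediate state (default 5). A gene
#'   absent from the healthy networks (D = 0) passes when its intermediate
#'   degree reaches `degree_fold`.
#' @param deg_p_threshold raw differential-expression p-value bound in the
#'   intermediate state versus healthy (default 1e-4).
#' @param exclusivity require the gene NOT to be a tps-DEG in the other
#'   intermediate state versus healthy.
#' @return an object of class `early_marker_config`
#' @export
early_marker_config <- function(degree_fold = 5, deg_p_threshold = 1e-4,
                                exclusivity = TRUE) {
  stopifnot(degree_fold > 1, deg_p_threshold > 0, deg_p_threshold < 1)
  structure(list(degree_fold = degree_fold,
                 deg_p_threshold = deg_p_threshold,
                 exclusivity = exclusivity),
            class = "early_marker_config")
}

#' Assemble per-gene trend records across a state sequence
#'
#' @param stats_list named list of per-state gene statistics (one
#'   [aggregate_gene_stats()] data frame per state of the sequence).
#' @param sequence ordered state labels (>= 3), e.g. `c("Nor","Ade","CRC")`.
#' @return a data frame `gene`, `D_<state>...`, `C_<state>...` of class
#'   `trend_records` with a `sequence` attribute
#' @export
trend_records <- function(stats_list, sequence) {
  if (length(sequence) < 3L) stop("a sequence needs >= 3 states")
  miss <- setdiff(sequence, names(stats_list))
  if (length(miss)) stop("missing per-state stats for: ", paste(miss, collapse = ", "))
  genes <- stats_list[[sequence[1L]]]$gene
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in sequence) {
    st <- stats_list[[s]]
    i <- match(genes, st$gene)
    if (any(is.na(i))) stop("gene universes differ between states")
    out[[paste0("D_", s)]] <- st$D[i]
    out[[paste0("C_", s)]] <- st$C[i]
  }
  structure(out, sequence = sequence, class = c("trend_records", "data.frame"))
}

.dmat <- function(records, what = "D") {
  seqs <- attr(records, "sequence")
  as.matrix(records[paste0(what, "_", seqs)])
}

#' Select genes whose network prominence grows toward the final state
#'
#' A gene is selected iff (a) it appears in at least one network of the
#' sequence (some D > 0); (b) in at least one state it is a hub
#' (`D > min_hub_degree`) with positive clustering coefficient; and (c)
#' its degree and clustering coefficient trend into the final state (see
#' [top_config()] for the trend modes; transitions among non-final states
#' are deliberately unconstrained in the default mode).
#'
#' @param records a [trend_records()] table spanning the full sequence.
#' @param config a [top_config()].
#' @return an object of class `selection_result`: `genes`, `evidence` (the
#'   records of the selected genes plus per-criterion flags), `sequence`,
#'   `config`, `summary`
#' @export
top_select <- function(records, config = top_config()) {
  sequence <- attr(records, "sequence")
  if (is.null(sequence) || length(sequence) < 3L)
    stop("records must span a sequence of >= 3 states")
  D <- .dmat(records, "D")
  C <- .dmat(records, "C")
  ns <- length(sequence)
  present <- rowSums(D > 0) > 0
  hubD <- D > config$min_hub_degree
  if (config$require_positive_C) {
    hub <- if (config$hub_joint) rowSums(hubD & C > 0) > 0
           else (rowSums(hubD) > 0) & (rowSums(C > 0) > 0)
  } else {
    hub <- rowSums(hubD) > 0
  }
  eps <- config$c_tolerance
  trend <- switch(config$trend_mode,
    into_final_strict = {
      ok <- rep(TRUE, nrow(D))
      for (s in seq_len(ns - 1L))
        ok <- ok & D[, ns] > D[, s] & C[, ns] >= C[, s] - eps
      ok
    },
    into_final_weak = {
      ok <- rep(TRUE, nrow(D))
      for (s in seq_len(ns - 1L))
        ok <- ok & D[, ns] >= D[, s] & C[, ns] >= C[, s] - eps
      ok
    },
    monotone = {
      ok <- rep(TRUE, nrow(D))
      for (s in seq_len(ns - 1L))
        ok <- ok & D[, s + 1L] >= D[, s] & C[, s + 1L] >= C[, s] - eps
      ok
    })
  sel <- present & hub & trend
  ev <- records[sel, , drop = FALSE]
  ev$pass_present <- present[sel]
  ev$pass_hub <- hub[sel]
  ev$pass_trend <- trend[sel]
  structure(list(genes = records$gene[sel],
                 evidence = ev,
                 sequence = sequence,
                 config = config,
                 summary = list(n_selected = sum(sel),
                                n_candidates = nrow(records))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d gene(s)\n",
              paste(x$sequence, collapse = "-"), length(x$genes)))
  invisible(x)
}

#' Restrict a ToP selection to differentially expressed genes (TPS)
#'
#' Keeps the ToP genes that pass the tps differential-expression filter in
#' at least one of the two contrasts (intermediate vs healthy, final vs
#' healthy).
#'
#' @param top_result a [top_select()] result.
#' @param deg_x_vs_nor,deg_final_vs_nor [two_class_test()] tables for the
#'   two contrasts; together they must cover every ToP gene.
#' @param config a [deg_config()].
#' @return a `selection_result`
#' @export
tps_select <- function(top_result, deg_x_vs_nor, deg_final_vs_nor,
                       config = deg_config()) {
  genes <- top_result$genes
  in_x <- match(genes, deg_x_vs_nor$gene)
  in_f <- match(genes, deg_final_vs_nor$gene)
  orphan <- is.na(in_x) & is.na(in_f)
  if (any(orphan))
    stop("ToP gene(s) missing from both DEG tables: ",
         paste(genes[orphan], collapse = ", "))
  pass_x <- rep(FALSE, length(genes))
  pass_f <- rep(FALSE, length(genes))
  pass_x[!is.na(in_x)] <-
    is_deg(deg_x_vs_nor[in_x[!is.na(in_x)], , drop = FALSE], config, "tps")
  pass_f[!is.na(in_f)] <-
    is_deg(deg_final_vs_nor[in_f[!is.na(in_f)], , drop = FALSE], config, "tps")
  keep <- pass_x | pass_f
  ev <- top_result$evidence[keep, , drop = FALSE]
  ev$deg_in_x <- pass_x[keep]
  ev$deg_in_final <- pass_f[keep]
  structure(list(genes = genes[keep], evidence = ev,
                 sequence = top_result$sequence,
                 config = list(top = top_result$config, deg = config),
                 summary = list(n_selected = sum(keep),
                                n_top = length(genes))),
            class = "selection_result")
}

#' Combine selections from two state sequences
#'
#' @param result_a,result_b two `selection_result`s (or plain character
#'   vectors) over the same gene universe.
#' @return a list of class `combined_selection`: `genes` (union),
#'   `exclusive_a`, `common`, `exclusive_b`, and a `summary` with the
#'   partition counts (which always sum to the union size).
#' @export
combine_sequences <- function(result_a, result_b) {
  ga <- if (inherits(result_a, "selection_result")) result_a$genes else result_a
  gb <- if (inherits(result_b, "selection_result")) result_b$genes else result_b
  common <- intersect(ga, gb)
  ea <- setdiff(ga, gb)
  eb <- setdiff(gb, ga)
  structure(list(genes = union(ga, gb),
                 exclusive_a = ea, common = common, exclusive_b = eb,
                 summary = list(n_a = length(ga), n_b = length(gb),
                                n_union = length(union(ga, gb)),
                                n_exclusive_a = length(ea),
                                n_common = length(common),
                                n_exclusive_b = length(eb))),
            class = "combined_selection")
}

#' Hit rate against an annotated gene catalog
#'
#' `100 * |selected intersect catalog| / |selected|`.
#'
#' @param selected a `selection_result`, `combined_selection`, or character
#'   vector of gene symbols (non-empty).
#' @param catalog a [gene_catalog()].
#' @return the percentage at full precision, with attributes `n_hit`,
#'   `n_selected`, and `percent_int` (integer-rounded, as usually printed)
#' @export
hit_rate <- function(selected, catalog) {
  genes <- if (inherits(selected, c("selection_result", "combined_selection")))
    selected$genes else selected
  if (!length(genes)) stop("empty selection")
  genes <- toupper(genes)
  hits <- sum(genes %in% catalog$symbols)
  pct <- 100 * hits / length(genes)
  out <- pct
  attr(out, "n_hit") <- hits
  attr(out, "n_selected") <- length(genes)
  attr(out, "percent_int") <- as.integer(round(pct))
  out
}

#' Screen a TPS selection for early-detection markers
#'
#' A marker for the intermediate state X of the sequence is a TPS gene
#' whose network degree increases at least `degree_fold`-fold from the
#' healthy state to X (absence from the healthy networks counts as passing
#' when D_X reaches the fold), that is strongly differentially expressed in
#' X vs healthy (raw p below `deg_p_threshold`), and -- when `exclusivity`
#' is set -- is not a tps-DEG in the other intermediate state vs healthy.
#'
#' @param tps_result a [tps_select()] result for a sequence containing X.
#' @param records the [trend_records()] table of the sequence.
#' @param deg_x_vs_nor [two_class_test()] table, X vs healthy.
#' @param deg_other_vs_nor table for the other intermediate state vs
#'   healthy (may be `NULL` when `exclusivity` is off).
#' @param config an [early_marker_config()].
#' @param state intermediate state X; defaults to the second state of the
#'   sequence.
#' @param deg_tps_config [deg_config()] used for the exclusivity check.
#' @return a `selection_result` of markers for state X
#' @export
early_markers <- function(tps_result, records, deg_x_vs_nor,
                          deg_other_vs_nor = NULL,
                          config = early_marker_config(),
                          state = NULL, deg_tps_config = deg_config()) {
  sequence <- tps_result$sequence
  if (is.null(state)) state <- sequence[2L]
  if (!state %in% sequence[-c(1L, length(sequence))])
    stop("state '", state, "' is not an intermediate state of the sequence")
  first <- sequence[1L]
  genes <- tps_result$genes
  i <- match(genes, records$gene)
  d_nor <- records[[paste0("D_", first)]][i]
  d_x <- records[[paste0("D_", state)]][i]
  fold_ok <- ifelse(d_nor == 0, d_x >= config$degree_fold,
                    d_x >= config$degree_fold * d_nor)
  px <- deg_x_vs_nor$p[match(genes, deg_x_vs_nor$gene)]
  p_ok <- !is.na(px) & px < config$deg_p_threshold
  if (config$exclusivity) {
    if (is.null(deg_other_vs_nor))
      stop("exclusivity check needs the other intermediate's DEG table")
    j <- match(genes, deg_other_vs_nor$gene)
    other_deg <- rep(FALSE, length(genes))
    other_deg[!is.na(j)] <-
      is_deg(deg_other_vs_nor[j[!is.na(j)], , drop = FALSE],
             deg_tps_config, "tps")
    excl_ok <- !other_deg
  } else {
    excl_ok <- rep(TRUE, length(genes))
  }
  keep <- fold_ok & p_ok & excl_ok
  ev <- data.frame(gene = genes[keep],
                   D_first = d_nor[keep], D_intermediate = d_x[keep],
                   deg_p = px[keep], stringsAsFactors = FALSE)
  structure(list(genes = genes[keep], evidence = ev,
                 sequence = sequence, state = state, config = config,
                 summary = list(n_selected = sum(keep),
                                n_tps = length(genes))),
            class = "selection_result")
}
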