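#' Thresholds for differential-expression calls
#'
#' @param p_threshold raw p-value threshold (signature mode).
#' @param p_adj_threshold adjusted-p threshold (tps mode).
#' @param fc_threshold linear-scale fold-change threshold.
#' @param fdr_threshold permutation-FDR threshold (signature mode).
#' @param n_permutations label permutations for the permutation FDR.
#' @param seed seed for label permutations.
#' @return an object of class `deg_config`
#' @export
deg_config <- function(p_threshold = 0.05, p_adj_threshold = 0.05,
                       fc_threshold = 1.5, fdr_threshold = 0.001,
                       n_permutations = 200L, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            p_adj_threshold > 0, p_adj_threshold <= 1,
            fc_threshold > 1)
  structure(list(p_threshold = p_threshold,
                 p_adj_threshold = p_adj_threshold,
                 fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "deg_config")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement; order-preserving in the input.
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values, same order as the input
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# vectorised per-row Welch (or pooled) t; returns t, df, p
.row_t <- function(xa, xb, var_equal = FALSE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  tt <- (ma - mb) / sqrt(se2)
  p <- ifelse(se2 == 0, ifelse(ma == mb, 1, 0),
              2 * stats::pt(-abs(tt), df))
  list(t = tt, p = p, diff = ma - mb)
}

#' Two-class unpaired differential expression test
#'
#' Per gene: a Welch (unequal-variance) two-sample t-test on the log2
#' intensities, the linear-scale fold change `2^(meanA - meanB)`, BH
#' adjustment, and optionally a permutation null by group-label shuffling:
#' `perm_p` is the pooled-null add-one p-value and `perm_fdr` the
#' plug-in permutation FDR at each gene's |t| cutoff (the stand-in for
#' SAM-style significance testing).
#'
#' @param study an `expression_study`.
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#' @param var_equal use the pooled-variance t instead of Welch.
#' @param n_perm number of label permutations (0 = skip).
#' @param seed seed for the permutations.
#' @return a data frame `gene`, `p`, `p_adj`, `fc` (+ `perm_p`, `perm_fdr`)
#'   with a `contrast` attribute
#' @export
two_class_test <- function(study, group_a, group_b, var_equal = FALSE,
                           n_perm = 0L, seed = 1L) {
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(study$values))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  xa <- study$values[, group_a, drop = FALSE]
  xb <- study$values[, group_b, drop = FALSE]
  obs <- .row_t(xa, xb, var_equal)
  out <- data.frame(gene = rownames(study$values),
                    p = obs$p, p_adj = bh_adjust(obs$p),
                    fc = 2^obs$diff, stringsAsFactors = FALSE)
  if (n_perm > 0L) {
    set.seed(seed)
    x <- cbind(xa, xb)
    na <- length(group_a)
    m <- nrow(x)
    tobs <- abs(obs$t)
    tobs[is.na(tobs)] <- 0
    perm_stats <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      idx <- sample.int(ncol(x))
      tp <- abs(.row_t(x[, idx[seq_len(na)], drop = FALSE],
                       x[, idx[-seq_len(na)], drop = FALSE], var_equal)$t)
      tp[is.na(tp)] <- 0
      perm_stats[[b]] <- tp
    }
    pooled <- sort(unlist(perm_stats))
    # pooled add-one permutation p per gene
    cnt <- length(pooled) - findInterval(tobs - 1e-12, pooled)
    out$perm_p <- (1 + cnt / m) / (1 + n_perm)
    # plug-in FDR: E[#null >= cut] / #observed >= cut, cutoff = each |t_i|
    sobs <- sort(tobs)
    n_ge_obs <- length(tobs) - findInterval(tobs - 1e-12, sobs)
    fdr <- pmin(1, (cnt / n_perm) / pmax(n_ge_obs, 1))
    # enforce monotone non-increase in |t|
    ordt <- order(tobs, decreasing = TRUE)
    fdr[ordt] <- cummax(fdr[ordt])
    out$perm_fdr <- fdr
  }
  attr(out, "contrast") <- "A_vs_B"
  out
}

#' One-way ANOVA across >= 3 states
#'
#' @param study an `expression_study`.
#' @param states states to compare (default: all states of the design).
#' @return a data frame `gene`, `p`, `p_adj` with a `contrast` attribute
#' @export
multi_class_anova <- function(study, states = NULL) {
  if (is.null(states)) states <- study$states
  if (length(states) < 3L) stop("need >= 3 states for the multi-class test")
  groups <- lapply(states, function(s) state_samples(study, s))
  if (any(lengths(groups) < 2L)) stop("every state needs >= 2 samples")
  x <- study$values[, unlist(groups), drop = FALSE]
  grp <- rep(seq_along(groups), lengths(groups))
  k <- length(groups); N <- ncol(x)
  gm <- rowMeans(x)
  ssb <- 0; ssw <- 0
  for (j in seq_len(k)) {
    xj <- x[, grp == j, drop = FALSE]
    mj <- rowMeans(xj)
    ssb <- ssb + ncol(xj) * (mj - gm)^2
    ssw <- ssw + rowSums((xj - mj)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- ifelse(ssw == 0, ifelse(ssb == 0, 1, 0),
              stats::pf(f, k - 1, N - k, lower.tail = FALSE))
  out <- data.frame(gene = rownames(study$values), p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "contrast") <- paste(states, collapse = ":")
  out
}

#' Differential-expression predicate
#'
#' Mode `"tps"` implements the network-pipeline filter: adjusted p below
#' `p_adj_threshold` and fold change above `fc_threshold` or below its
#' reciprocal. Mode `"signature"` implements the expression-signature
#' criterion: raw p below `p_threshold`, permutation FDR below
#' `fdr_threshold`, and fold change above `fc_threshold` (requires a
#' `perm_fdr` column from [two_class_test()] with `n_perm > 0`).
#'
#' @param records a data frame from [two_class_test()] (rows are recycled
#'   predicates, so this is vectorised).
#' @param config a [deg_config()].
#' @param mode `"tps"` or `"signature"`.
#' @return a logical vector, one entry per record row
#' @export
is_deg <- function(records, config = deg_config(), mode = c("tps", "signature")) {
  if (!is.character(mode) || !mode[1L] %in% c("tps", "signature"))
    stop("unknown mode '", mode[1L], "'")
  mode <- match.arg(mode)
  if (mode == "tps") {
    records$p_adj < config$p_adj_threshold &
      (records$fc > config$fc_threshold |
         records$fc < 1 / config$fc_threshold)
  } else {
    if (is.null(records$perm_fdr))
      stop("signature mode needs a 'perm_fdr' column (run two_class_test with n_perm > 0)")
    records$p < config$p_threshold &
      records$perm_fdr < config$fdr_threshold &
      records$fc > config$fc_threshold
  }
}
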