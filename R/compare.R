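#' Match internal patterns between two datasets by trajectory class
#'
#' Pairs patterns greedily by identical class label in eigenvalue order:
#' the i-th decaying pattern of A is matched with the i-th decaying pattern
#' of B, and so on. Matching is purely spectral/class-based; time grids are
#' never interpolated, which is what lets datasets with different numbers
#' of samples be compared. An explicit index pairing can override the rule.
#'
#' @param ipdps_a,ipdps_b Classified pattern lists ([extract_ipdps()]).
#' @param pairs Optional two-column matrix of (index in A, index in B)
#'   overriding the class rule.
#' @return List with \code{matches} (list of pairs, each with \code{a},
#'   \code{b} pattern indices and \code{class_label}), \code{unmatched_a},
#'   \code{unmatched_b} (indices).
#' @export
match_patterns <- function(ipdps_a, ipdps_b, pairs = NULL) {
  la <- vapply(ipdps_a, function(p) as.character(p$class_label), character(1L))
  lb <- vapply(ipdps_b, function(p) as.character(p$class_label), character(1L))
  matches <- list()
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    for (i in seq_len(nrow(pairs))) {
      matches[[i]] <- list(a = pairs[i, 1L], b = pairs[i, 2L],
                           class_label = la[pairs[i, 1L]])
    }
    used_a <- pairs[, 1L]; used_b <- pairs[, 2L]
  } else {
    used_a <- integer(0); used_b <- integer(0)
    for (i in seq_along(la)) {
      cand <- setdiff(which(lb == la[i]), used_b)
      if (length(cand)) {
        j <- cand[1L]
        matches[[length(matches) + 1L]] <- list(a = i, b = j,
                                                class_label = la[i])
        used_a <- c(used_a, i); used_b <- c(used_b, j)
      }
    }
  }
  list(matches = matches,
       unmatched_a = setdiff(seq_along(la), used_a),
       unmatched_b = setdiff(seq_along(lb), used_b))
}

#' Spearman correlation of gene coefficients across datasets
#'
#' Rank-correlates the per-gene coefficients of a matched pattern pair over
#' the genes shared by both datasets. Ties are mid-ranked; the p-value uses
#' the asymptotic t approximation \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2
#' degrees of freedom.
#'
#' @param coeffs_a,coeffs_b Named numeric vectors of per-gene coefficients
#'   (names are gene identifiers). Under \code{mode = "absolute"} pass
#'   magnitudes (see [coef_values()]); merged-conjugate patterns use
#'   \eqn{2|C|} there.
#' @param mode Label recording which coefficient convention the inputs use.
#' @return List with \code{spearman_r}, \code{p_value}, \code{n} (shared
#'   genes used).
#' @export
coefficient_correlation <- function(coeffs_a, coeffs_b,
                                    mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (is.null(names(coeffs_a)) || is.null(names(coeffs_b))) {
    stop("coefficient vectors must be named by gene identifier")
  }
  shared <- intersect(names(coeffs_a), names(coeffs_b))
  n <- length(shared)
  if (n < 5L) stop("need at least 5 shared genes; found ", n)
  r <- stats::cor(rank(coeffs_a[shared]), rank(coeffs_b[shared]))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(spearman_r = r, p_value = p, n = n, mode = mode)
}

#' Compare a gene set's internal vs external coefficient ranks
#'
#' Within each pattern column, all genes are ranked in ascending order of
#' coefficient (ties mid-ranked); the set's ranks are pooled across all
#' internal-pattern columns and, separately, across all external-pattern
#' columns, and the two pooled samples are compared by Welch's two-sample
#' t-test. A positive t means the set sits higher in the internal ranking,
#' i.e. the set's expression is more strongly driven by the internal
#' network than by the external regulators.
#'
#' @param ipdp_coeffs,epdp_coeffs Genes x patterns coefficient matrices with
#'   gene identifiers as row names (see [coef_values()]), or
#'   \code{ssd_gene_coef} tables.
#' @param gene_set Character vector of gene identifiers.
#' @param mode \code{"absolute"} ranks coefficient magnitudes,
#'   \code{"signed"} ranks signed values.
#' @param per_pattern If \code{TRUE}, additionally return one test per
#'   (iPDP, ePDP) column pair is not meaningful; instead a per-column mean
#'   rank table is attached.
#' @return List with \code{mean_rank_ipdp}, \code{mean_rank_epdp},
#'   \code{t_stat}, \code{p_value}, \code{n_genes} (set genes found) and,
#'   when \code{per_pattern}, \code{per_pattern_means}.
#' @export
gene_set_rank_test <- function(ipdp_coeffs, epdp_coeffs, gene_set,
                               mode = c("absolute", "signed"),
                               per_pattern = FALSE) {
  mode <- match.arg(mode)
  as_mat <- function(x) {
    if (inherits(x, "ssd_gene_coef")) coef_values(x, mode)
    else if (mode == "absolute") abs(as.matrix(x)) else as.matrix(x)
  }
  ic <- as_mat(ipdp_coeffs)
  ec <- as_mat(epdp_coeffs)
  if (is.null(rownames(ic)) || is.null(rownames(ec))) {
    stop("coefficient matrices must have gene identifiers as row names")
  }
  set <- intersect(gene_set, rownames(ic))
  if (!length(set)) stop("gene set does not intersect the dataset's genes")
  if (length(gene_set) < 2L) stop("gene set must contain at least 2 genes")
  rank_cols <- function(m) apply(m, 2L, rank)  # ascending, ties mid-ranked
  ri <- rank_cols(ic)[set, , drop = FALSE]
  re <- rank_cols(ec)[set, , drop = FALSE]
  x <- as.numeric(ri)
  y <- as.numeric(re)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
  }
  out <- list(mean_rank_ipdp = mean(x), mean_rank_epdp = mean(y),
              t_stat = unname(tt$statistic), p_value = tt$p.value,
              n_genes = length(set), mode = mode)
  if (per_pattern) {
    out$per_pattern_means <- c(colMeans(ri), colMeans(re))
  }
  out
}

#' Extract the top-ranked genes of one pattern
#'
#' Deterministic selection of the k most extreme genes of one pattern
#' column, suitable for export to external enrichment tools. Ties are
#' broken by gene identifier (C-locale lexicographic), so output is
#' platform independent.
#'
#' @param coeffs Genes x patterns coefficient matrix with gene identifiers
#'   as row names, or an \code{ssd_gene_coef} table (signed values used).
#' @param pattern_index Column to rank.
#' @param direction \code{"most-negative"}, \code{"most-positive"} or
#'   \code{"largest-magnitude"}.
#' @param k Number of genes, \code{1 <= k <= N}.
#' @return Character vector of k gene identifiers, most extreme first.
#' @export
top_gene_extraction <- function(coeffs, pattern_index,
                                direction = c("largest-magnitude",
                                              "most-negative",
                                              "most-positive"),
                                k) {
  direction <- match.arg(direction)
  m <- if (inherits(coeffs, "ssd_gene_coef")) coeffs$signed else as.matrix(coeffs)
  if (pattern_index < 1L || pattern_index > ncol(m)) {
    stop("pattern_index out of range")
  }
  if (k < 1L || k > nrow(m)) stop("k must lie in 1..N")
  v <- m[, pattern_index]
  ids <- rownames(m)
  key <- switch(direction,
                "most-negative" = v,
                "most-positive" = -v,
                "largest-magnitude" = -abs(v))
  ord <- order(key, ids, method = "radix")
  ids[ord][seq_len(k)]
}
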