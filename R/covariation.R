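# Covariation scoring: weighted column statistics, shrinkage
# inverse-covariance couplings, block norms, APC, external-score
# adapters.

#' Weighted, pseudocounted column statistics
#'
#' Single and pair frequencies over the 21-state alphabet (20 amino
#' acids + gap), mixed with a uniform pseudocount:
#' `f = (1 - lambda) * empirical + lambda / 21` for singles and
#' `lambda / 441` for pairs.
#'
#' @param a alignment with weights set (see [sequence_weights()]).
#' @param pseudocount_weight mixing fraction lambda in `[0, 1]`
#'   (default 0.5, the mean-field DCA convention; the inverse of the
#'   pseudocounted covariance needs this much regularisation when the
#'   number of effective sequences is comparable to 20 L).
#' @return object of class `column_stats`: `f1` (21 x L single
#'   frequencies), `pair` (21L x 21L pair-frequency matrix; the
#'   diagonal blocks carry `diag(f1)`), `n_eff`, `L`, `lambda`.
#' @export
column_stats <- function(a, pseudocount_weight = 0.5) {
  if (is.null(a$weights)) stop("alignment weights not set; ",
                               "run sequence_weights() first")
  lam <- pseudocount_weight
  stopifnot(lam >= 0, lam <= 1)
  L <- ncol(a$ali)
  if (L == 0L) stop("alignment has zero columns")
  w <- a$weights
  neff <- sum(w)
  X <- one_hot(a)
  f1_emp <- matrix(as.numeric(Matrix::crossprod(X, w)) / neff,
                   nrow = N_STATES)
  f1 <- (1 - lam) * f1_emp + lam / N_STATES
  Xw <- X * sqrt(w)
  P_emp <- as.matrix(Matrix::crossprod(Xw)) / neff
  P <- (1 - lam) * P_emp + lam / (N_STATES^2)
  # same-column blocks are degenerate: f_ii(a,b) = delta_ab f_i(a)
  for (i in seq_len(L)) {
    idx <- (i - 1L) * N_STATES + seq_len(N_STATES)
    P[idx, idx] <- diag(f1[, i])
  }
  structure(list(f1 = f1, pair = P, n_eff = neff, L = L, lambda = lam),
            class = "column_stats")
}

#' Raw couplings from the shrunken inverse covariance
#'
#' Builds the covariance `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)` over
#' the 20 amino-acid states of every column (the gap state is dropped
#' as the gauge reference, fixing its couplings to zero and removing
#' the per-column sum-to-one degeneracy), shrinks it towards its
#' diagonal (`C <- (1 - rho) C + rho diag(C)`, rho grown geometrically
#' from `shrink_start` until the matrix is positive definite), and
#' inverts.  The off-diagonal 20 x 20 blocks of the inverse are the
#' raw coupling blocks.
#'
#' @param stats a [column_stats()] object.
#' @param shrink_start initial shrinkage intensity (default 0.001).
#' @param shrink_factor geometric growth factor (default 2).
#' @return object of class `coupling_blocks`: the inverse matrix `M`
#'   (20L x 20L), `L`, and the shrinkage `rho` used.
#' @export
invcov_couplings <- function(stats, shrink_start = 0.001,
                             shrink_factor = 2) {
  L <- stats$L
  keep <- as.vector(vapply(seq_len(L), function(i)
    (i - 1L) * N_STATES + seq_len(N_STATES - 1L), integer(N_STATES - 1L)))
  f <- as.numeric(stats$f1)
  C <- (stats$pair - tcrossprod(f))[keep, keep]
  d <- diag(C)
  rho <- shrink_start
  repeat {
    Cs <- (1 - rho) * C
    diag(Cs) <- d
    ch <- tryCatch(chol(Cs), error = function(e) NULL)
    if (!is.null(ch)) break
    rho <- rho * shrink_factor
    if (rho > 1)
      stop("covariance not positive definite even at full shrinkage; ",
           "degenerate alignment")
  }
  M <- chol2inv(ch)
  structure(list(M = M, L = stats$L, rho = rho),
            class = "coupling_blocks")
}

#' Reduce coupling blocks to per-pair scores
#'
#' The coupling block of a column pair is reduced over its 20 x 20
#' non-gap states: `l21` sums the Euclidean norms of the rows;
#' `frobenius` is the root sum of squares.  The output is symmetrised
#' (blocks (i,j) and (j,i) are transposes, so the L2,1 reduction of the
#' two is averaged) with a zero diagonal.
#'
#' @param blocks a [invcov_couplings()] result.
#' @param norm `"l21"` (default) or `"frobenius"`.
#' @return L x L symmetric matrix of raw (pre-APC) scores.
#' @export
pair_score <- function(blocks, norm = c("l21", "frobenius")) {
  norm <- match.arg(norm)
  L <- blocks$L
  S <- blocks$M^2
  # A: (20L x L) indicator of the 20 states of each column
  A <- Matrix::sparseMatrix(i = seq_len(20L * L),
                            j = rep(seq_len(L), each = 20L),
                            x = 1, dims = c(20L * L, L))
  if (norm == "frobenius") {
    out <- sqrt(as.matrix(Matrix::crossprod(A, S %*% A)))
  } else {
    T_ <- sqrt(as.matrix(S %*% A))      # row norms per (state,col_i) x col_j
    out <- as.matrix(Matrix::crossprod(A, T_))
    out <- (out + t(out)) / 2
  }
  diag(out) <- 0
  out
}

# region means helper used by apc(); NA entries (unscored pairs, or an
# undefined diagonal) are left out of the means and stay NA
apc_region <- function(sub) {
  ri <- rowMeans(sub, na.rm = TRUE)
  cj <- colMeans(sub, na.rm = TRUE)
  all_mean <- mean(sub, na.rm = TRUE)
  if (!is.finite(all_mean) || all_mean == 0)
    return(list(corr = sub, skipped = TRUE))
  corr <- sub - outer(ri, cj) / all_mean
  list(corr = corr, skipped = FALSE)
}

#' Average product correction, optionally block-wise
#'
#' `corrected(i, j) = raw(i, j) - mean_i * mean_j / mean_all`, removing
#' the product-structured background from phylogeny and column entropy.
#' For concatenated hetero-oligomer alignments the correction is
#' computed separately within each block-pair region (intra-A, intra-B,
#' inter-AB, ...), so the weaker interchain signal is not corrected
#' against the stronger intrachain background.  Region means run over
#' every non-`NA` entry; pass an `NA` diagonal to keep undefined
#' self-scores out of the background estimate.
#'
#' @param raw symmetric L x L raw score matrix (NA = no score).
#' @param chain_boundaries integer vector of last columns of each chain
#'   block; empty for a single global region.
#' @param method provenance tag stored on the result.
#' @return object of class `coupling_matrix`: `scores` (L x L,
#'   APC-corrected, zero/NA diagonal), `method`, `apc_applied`,
#'   `block_structure`, `skipped_regions`.
#' @export
apc <- function(raw, chain_boundaries = integer(),
                method = "builtin_invcov") {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (max(abs(raw - t(raw)), na.rm = TRUE) > 1e-8)
    stop("raw score matrix is not symmetric")
  L <- nrow(raw)
  bounds <- sort(unique(as.integer(chain_boundaries)))
  if (length(bounds) && bounds[length(bounds)] != L)
    bounds <- c(bounds, L)
  blocks <- if (length(bounds) <= 1L) list(seq_len(L)) else {
    starts <- c(1L, head(bounds, -1) + 1L)
    Map(seq, starts, bounds)
  }
  out <- raw
  skipped <- 0L
  for (u in seq_along(blocks)) for (v in u:length(blocks)) {
    iu <- blocks[[u]]; iv <- blocks[[v]]
    res <- apc_region(raw[iu, iv, drop = FALSE])
    out[iu, iv] <- res$corr
    out[iv, iu] <- t(res$corr)
    if (res$skipped) skipped <- skipped + 1L
  }
  diag(out) <- 0
  if (skipped > 0)
    warning(skipped, " APC region(s) had zero mean; correction skipped there")
  structure(list(scores = out, method = method, apc_applied = TRUE,
                 block_structure = bounds, skipped_regions = skipped),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("<coupling_matrix> L = ", nrow(x$scores), ", method = ", x$method,
      ", APC ", if (isTRUE(x$apc_applied)) "applied" else "not applied",
      if (length(x$block_structure) > 1)
        paste0(", ", length(x$block_structure), " chain blocks"),
      "\n", sep = "")
  invisible(x)
}

#' Coupling scores for an alignment (end-to-end)
#'
#' Convenience wrapper: weighting (if absent), column statistics,
#' shrinkage inverse-covariance, block norm, APC with the alignment's
#' chain boundaries.
#'
#' @param a alignment.
#' @param pseudocount_weight lambda for [column_stats()].
#' @param norm passed to [pair_score()].
#' @param identity_threshold clustering threshold for
#'   [sequence_weights()] when weights are absent.
#' @return a `coupling_matrix`.
#' @export
coupling_scores <- function(a, pseudocount_weight = 0.5, norm = "l21",
                            identity_threshold = 62) {
  if (is.null(a$weights)) a <- sequence_weights(a, identity_threshold)
  st <- column_stats(a, pseudocount_weight)
  bl <- invcov_couplings(st)
  raw <- pair_score(bl, norm)
  diag(raw) <- NA  # self-scores are undefined, keep them out of APC means
  apc(raw, chain_boundaries = a$chain_boundaries)
}

#' Read PSICOV-format coupling scores
#'
#' Whitespace-separated lines `i j reserved reserved score` with
#' 1-based column indices.  Pairs absent from the file carry no score
#' (`NA`).
#'
#' @param path file.
#' @param L alignment length; inferred from the largest index when
#'   omitted.
#' @return a `coupling_matrix` with `method = "psicov_file"` and
#'   `apc_applied = TRUE` (the tool emits corrected scores).
#' @export
read_psicov_scores <- function(path, L = NULL) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("malformed PSICOV file: expected 5 columns")
  i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]])
  sc <- as.numeric(tab[[5]])
  if (any(i == j)) stop("PSICOV file lists i = j entries")
  if (is.null(L)) L <- max(i, j)
  if (any(i < 1 | j < 1 | i > L | j > L))
    stop("PSICOV file has out-of-range indices for L = ", L)
  m <- matrix(NA_real_, L, L)
  m[cbind(i, j)] <- sc
  m[cbind(j, i)] <- sc
  diag(m) <- 0
  structure(list(scores = m, method = "psicov_file", apc_applied = TRUE,
                 block_structure = integer(), skipped_regions = 0L),
            class = "coupling_matrix")
}

#' Read a CCMpred dense score matrix
#'
#' Whitespace-separated L x L matrix.
#'
#' @param path file.
#' @return a `coupling_matrix` with `method = "ccmpred_file"`.
#' @export
read_ccmpred_scores <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("CCMpred matrix is not square")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(list(scores = m, method = "ccmpred_file", apc_applied = TRUE,
                 block_structure = integer(), skipped_regions = 0L),
            class = "coupling_matrix")
}

#' Write a coupling matrix as TSV
#'
#' Columns `i`, `j` (1-based, i < j), `score`, `apc` — the native dump
#' format; `NA` scores are omitted.
#'
#' @param cm coupling matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coupling_tsv <- function(cm, path) {
  L <- nrow(cm$scores)
  ut <- which(upper.tri(cm$scores), arr.ind = TRUE)
  sc <- cm$scores[ut]
  keep <- !is.na(sc)
  df <- data.frame(i = ut[keep, 1], j = ut[keep, 2], score = sc[keep],
                   apc = cm$apc_applied)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Length-normalised rank of a column pair
#'
#' 1-based descending rank of the pair among all scored pairs (upper
#' triangle), ties broken by (i, j) lexicographic order, divided by L.
#'
#' @param cm coupling matrix.
#' @param i,j column indices.
#' @return normalised rank, or `NA` for an unscored pair.
#' @export
rank_of_pair <- function(cm, i, j) {
  L <- nrow(cm$scores)
  stopifnot(i >= 1, j >= 1, i <= L, j <= L, i != j)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  ut <- which(upper.tri(cm$scores), arr.ind = TRUE)
  sc <- cm$scores[ut]
  keep <- !is.na(sc)
  ut <- ut[keep, , drop = FALSE]; sc <- sc[keep]
  hit <- which(ut[, 1] == i & ut[, 2] == j)
  if (!length(hit)) return(NA_real_)
  ord <- order(-sc, ut[, 1], ut[, 2])
  match(hit, ord) / L
}

#' Top-ranked scored column pairs
#'
#' @param cm coupling matrix.
#' @param k number of pairs.
#' @return data frame `i`, `j`, `score` ordered by descending score
#'   (lexicographic tie-break).
#' @export
top_pairs <- function(cm, k) {
  ut <- which(upper.tri(cm$scores), arr.ind = TRUE)
  sc <- cm$scores[ut]
  keep <- !is.na(sc)
  ut <- ut[keep, , drop = FALSE]; sc <- sc[keep]
  ord <- order(-sc, ut[, 1], ut[, 2])
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(i = ut[ord, 1], j = ut[ord, 2], score = sc[ord])
}
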