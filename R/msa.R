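# Multiple sequence alignments: reading, weighting, the diversity
# criterion, and polishing.

#' Construct an alignment object
#'
#' Sequences live on the 21-state alphabet (20 amino acids + gap).
#' Non-standard residue letters are mapped to the gap state.
#'
#' @param seqs character vector of aligned sequences (equal length) or a
#'   character matrix (rows = sequences).
#' @param ids sequence identifiers.
#' @param query_index row index of the query sequence (default 1).
#' @param chain_boundaries integer vector of last columns of each chain
#'   block for concatenated hetero-oligomer alignments; empty for
#'   monomers/homomers.
#' @return object of class `msa_alignment` with fields `ali` (character
#'   matrix), `ids`, `query_index`, `weights` (NULL until
#'   [sequence_weights()]), `chain_boundaries`.
#' @export
new_alignment <- function(seqs, ids = NULL, query_index = 1L,
                          chain_boundaries = integer()) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ")
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  m <- toupper(m)
  m[!(m %in% AA1)] <- GAP
  dimnames(m) <- NULL
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  stopifnot(query_index >= 1, query_index <= nrow(m))
  structure(list(ali = m, ids = as.character(ids),
                 query_index = as.integer(query_index),
                 weights = NULL,
                 chain_boundaries = as.integer(chain_boundaries)),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("<msa_alignment> ", nrow(x$ali), " sequences x ", ncol(x$ali),
      " columns", if (!is.null(x$weights))
        paste0(", n_clusters = ", round(sum(x$weights), 2)), "\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param a alignment.
#' @return integer L.
#' @export
alignment_length <- function(a) ncol(a$ali)

#' Read a multiple sequence alignment
#'
#' FASTA is read with Biostrings; A3M lowercase insertion states
#' (columns absent from the query's match states) are removed;
#' Stockholm (single- or multi-block) is parsed directly since no
#' installed reader covers it.
#'
#' @param path alignment file.
#' @param format `"fasta"`, `"a3m"`, `"stockholm"` or `"auto"` (by
#'   extension).
#' @param ... passed to [new_alignment()].
#' @return an `msa_alignment`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "a3m",
                                            "stockholm"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m"
    else if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm"
    else "fasta"
  }
  recs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      list(ids = names(ss), seqs = as.character(ss))
    },
    a3m = {
      ss <- Biostrings::readBStringSet(path)
      # lowercase letters are insertions relative to the query match
      # states; '.' is the matching gap filler
      seqs <- gsub("[a-z.]", "", as.character(ss))
      list(ids = names(ss), seqs = seqs)
    },
    stockholm = read_stockholm(path))
  if (!length(recs$seqs)) stop("no sequences in ", path)
  lens <- nchar(recs$seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment after normalization")
  new_alignment(recs$seqs, ids = recs$ids, ...)
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file: ", path)
  lines <- lines[!grepl("^(#|//)", lines) & nzchar(trimws(lines))]
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  seqs <- trimws(substring(lines, nchar(parts) + 1))
  agg <- tapply(seqs, factor(parts, levels = unique(parts)), paste,
                collapse = "")
  list(ids = names(agg), seqs = unname(gsub("\\.", "-", agg)))
}

#' Write an alignment as aligned FASTA
#'
#' @param a alignment.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  seqs <- apply(a$ali, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", a$ids), seqs)), path)
  invisible(path)
}

# one-hot encoding (sparse): N x 21L, state-major within column
one_hot <- function(a) {
  m <- a$ali
  n <- nrow(m); L <- ncol(m)
  st <- match(m, STATES)            # column-major over m
  col_idx <- rep(seq_len(L), each = n)
  Matrix::sparseMatrix(i = rep(seq_len(n), L),
                       j = (col_idx - 1L) * N_STATES + st,
                       x = 1, dims = c(n, L * N_STATES))
}

# percent-identity matrix: matches / columns where both are non-gap
pairwise_identity <- function(a) {
  m <- a$ali
  n <- nrow(m)
  X <- one_hot(a)
  gap_cols <- seq(N_STATES, ncol(X), by = N_STATES)
  Xng <- X[, -gap_cols, drop = FALSE]
  matches <- as.matrix(Matrix::tcrossprod(Xng))
  B <- matrix(as.numeric(m != GAP), n)
  comparable <- tcrossprod(B)
  id <- matrix(0, n, n)
  nz <- comparable > 0
  id[nz] <- 100 * matches[nz] / comparable[nz]
  id
}

#' Sequence weighting by identity clustering
#'
#' Weight of a sequence is the reciprocal of the number of sequences
#' (itself included) at or above `identity_threshold` percent identity
#' to it; the effective cluster count is the sum of weights.
#'
#' @param a alignment.
#' @param identity_threshold percent identity (default 62, the default
#'   clustering threshold of the inverse-covariance scorer).
#' @return the alignment with `weights` set and a `diversity_report`
#'   attribute (see [check_diversity()]).
#' @export
sequence_weights <- function(a, identity_threshold = 62) {
  stopifnot(identity_threshold > 0, identity_threshold < 100)
  id <- pairwise_identity(a)
  nsim <- rowSums(id >= identity_threshold)
  a$weights <- 1 / nsim
  n_clusters <- sum(a$weights)
  attr(a, "diversity_report") <- structure(
    list(n_sequences = nrow(a$ali), n_clusters = n_clusters,
         threshold_used = identity_threshold,
         passes = n_clusters >= ncol(a$ali)),
    class = "diversity_report")
  a
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("<diversity_report> ", x$n_sequences, " sequences, ",
      round(x$n_clusters, 2), " clusters at ", x$threshold_used,
      "% identity: ", if (x$passes) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Diversity criterion with threshold escalation
#'
#' An alignment qualifies for coupling estimation when it contains at
#' least as many non-redundant sequence clusters as its length L.  If
#' the criterion fails at `start_threshold`, the clustering threshold is
#' raised in `step`-percent increments up to `max_threshold` or until
#' the criterion is met.
#'
#' @param a alignment.
#' @param start_threshold,max_threshold,step percent identity schedule
#'   (defaults 62, 80, 1).
#' @return a `diversity_report`: `n_sequences`, `n_clusters` (at the
#'   last threshold tried), `threshold_used`, `passes`.
#' @export
check_diversity <- function(a, start_threshold = 62, max_threshold = 80,
                            step = 1) {
  stopifnot(start_threshold <= max_threshold, step > 0)
  th <- start_threshold
  repeat {
    rep_ <- attr(sequence_weights(a, th), "diversity_report")
    if (rep_$passes || th >= max_threshold) return(rep_)
    th <- min(th + step, max_threshold)
  }
}

#' Polish an alignment by trimming distant sequences
#'
#' Removes non-query sequences whose identity to the query falls below
#' `identity_floor`, one at a time in ascending identity order, stopping
#' before a removal would break the diversity criterion.  This trims
#' homologs likely to carry a different oligomeric state, which act as
#' noise in interchain coupling estimation.
#'
#' @param a alignment.
#' @param identity_floor percent identity to the query below which a
#'   sequence is a removal candidate.
#' @param ... passed to [check_diversity()].
#' @return the polished alignment; if even the first removal would break
#'   the criterion the input is returned unchanged with a warning.
#' @export
polish_alignment <- function(a, identity_floor, ...) {
  id <- pairwise_identity(a)[a$query_index, ]
  cand <- setdiff(which(id < identity_floor), a$query_index)
  if (!length(cand)) return(a)
  cand <- cand[order(id[cand])]
  subset_rows <- function(keep) {
    out <- a
    out$ali <- a$ali[keep, , drop = FALSE]
    out$ids <- a$ids[keep]
    out$query_index <- sum(keep[seq_len(a$query_index)])
    out$weights <- NULL
    out
  }
  keep <- rep(TRUE, nrow(a$ali))
  removed_any <- FALSE
  for (s in cand) {
    trial_keep <- keep
    trial_keep[s] <- FALSE
    if (!check_diversity(subset_rows(trial_keep), ...)$passes) break
    keep <- trial_keep
    removed_any <- TRUE
  }
  if (!removed_any) {
    warning("no sequence could be removed without breaking the ",
            "diversity criterion; alignment returned unchanged")
    return(a)
  }
  subset_rows(keep)
}
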