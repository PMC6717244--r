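# Desk-scale fixtures: toy two-chain complexes with controllable
# contact geometry, and alignments with planted pairwise couplings.

CA_SPACING <- 3.8  # Angstrom between consecutive residues along x

#' Build a toy two-chain complex with designed contacts
#'
#' Two identical extended chains (N, CA, C, O, CB per residue; a
#' poly-alanine-like backbone with randomly assigned residue
#' identities) face each other along z with their Cbeta atoms pointing
#' inwards.  Chain B is shifted by `offset` residues along the chain
#' axis, so residue `i` of A faces residue `i + offset` of B, and the
#' facing Cbeta pair sits exactly `spacing` apart — the only atom pair
#' able to satisfy the 5.5 A interface definition.  With
#' `spacing < 5.5` the designed contacts are exactly the aligned pairs;
#' with `spacing > 5.5` there is no interface.
#'
#' @param n_res residues per chain.
#' @param spacing Cbeta-Cbeta distance of facing residues (Angstrom,
#'   must be >= 3).
#' @param offset residue shift between the chains (0 <= offset <
#'   n_res).
#' @param seed RNG seed for residue identities and jitter.
#' @param jitter sd of Gaussian coordinate noise (Angstrom).
#' @param sequence optional one-letter sequence (length `n_res`)
#'   instead of random identities; glycine is excluded from random
#'   draws since every toy residue carries a real CB atom.
#' @return list: `query` (chain A), `partner` (chain B), `true_pairs`
#'   (data frame `res_query`, `res_partner`), `spec` (the parameters).
#' @export
make_toy_complex <- function(n_res = 12, spacing = 4.8, offset = 0,
                             seed = 1, jitter = 0, sequence = NULL) {
  if (spacing < 3) stop("infeasible spacing: chains would clash")
  stopifnot(n_res >= 1, offset >= 0, offset < n_res)
  set.seed(seed)
  aa1 <- sequence %||%
    sample(setdiff(AA1, "G"), n_res, replace = TRUE)
  if (length(aa1) == 1L && nchar(aa1) > 1)
    aa1 <- strsplit(aa1, "")[[1]]
  stopifnot(length(aa1) == n_res)
  res3 <- names(AA3)[match(aa1, AA3)]
  build_chain <- function(chain, x0, z0, cb_dir) {
    one <- function(i) {
      ca <- c(x0 + (i - 1) * CA_SPACING, 0, z0)
      data.frame(chain = chain, resno = i, ins = "", resid = res3[i],
                 elety = c("N", "CA", "C", "O", "CB"),
                 element = c("N", "C", "C", "O", "C"),
                 x = ca[1] + c(-1.25, 0, 1.25, 1.25, 0),
                 y = ca[2] + c(0.5, 0, 0.5, 1.73, 0),
                 z = ca[3] + c(0, 0, 0, 0, cb_dir * 1.53),
                 occ = 1, stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(seq_len(n_res), one))
  }
  dz <- spacing + 2 * 1.53
  a <- build_chain("A", 0, 0, +1)
  b <- build_chain("B", -offset * CA_SPACING, dz, -1)
  if (jitter > 0) {
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
      rnorm(3L * nrow(a), sd = jitter)
    b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] +
      rnorm(3L * nrow(b), sd = jitter)
  }
  i <- seq_len(n_res - offset)
  list(query = new_structure(a), partner = new_structure(b),
       true_pairs = data.frame(res_query = i, res_partner = i + offset),
       spec = list(n_res = n_res, spacing = spacing, offset = offset,
                   seed = seed, jitter = jitter,
                   sequence = paste(aa1, collapse = "")))
}

#' Residue-to-column map of a toy complex
#'
#' Both chains are copies of the same molecule, so residue `i` of
#' either chain maps to alignment column `i` (single-gene, homomeric
#' mapping).
#'
#' @param toy a [make_toy_complex()] result.
#' @return named integer vector usable with [set_column_map()].
#' @export
toy_column_map <- function(toy) {
  n <- toy$spec$n_res
  setNames(rep(seq_len(n), 2),
           c(residue_key("A", seq_len(n), ""),
             residue_key("B", seq_len(n), "")))
}

#' Sample an alignment with planted pairwise couplings
#'
#' Columns are sampled independently from per-column background
#' distributions (a random subset of residues with random
#' proportions).  Each planted column pair is restricted to a
#' two-residue support and, with probability equal to the coupling
#' strength, its two states are co-assigned from one of two joint
#' states — a transparent stand-in for Potts sampling that drives
#' inverse-covariance recovery.  A final mutation step substitutes
#' every cell with a uniform random residue at `mutation_rate`.
#'
#' @param L alignment length.
#' @param n_seq number of sequences.
#' @param planted_pairs data frame `i`, `j`, `strength` (all pairs must
#'   satisfy `|i - j| > 5` so the artifact filters cannot erase them,
#'   and no column may appear twice).
#' @param mutation_rate per-cell substitution rate (default 0.05).
#' @param seed RNG seed; identical spec + seed gives an identical
#'   alignment.
#' @param background_states residues in each unplanted column's support
#'   (default 8).
#' @return an `msa_alignment` with attribute `planted` (the truth
#'   table).
#' @export
make_coupled_msa <- function(L = 60, n_seq = 1500,
                             planted_pairs = NULL, mutation_rate = 0.05,
                             seed = 1, background_states = 8) {
  stopifnot(n_seq >= 2, L >= 1)
  if (is.null(planted_pairs))
    planted_pairs <- data.frame(i = integer(), j = integer(),
                                strength = numeric())
  if (nrow(planted_pairs)) {
    if (any(abs(planted_pairs$i - planted_pairs$j) <= 5))
      stop("planted pairs must satisfy |i - j| > 5")
    cols <- c(planted_pairs$i, planted_pairs$j)
    if (anyDuplicated(cols) || any(cols < 1) || any(cols > L))
      stop("planted columns must be distinct and within 1..L")
  }
  set.seed(seed)
  ali <- matrix(GAP, n_seq, L)
  planted_cols <- c(planted_pairs$i, planted_pairs$j)
  support <- vector("list", L)
  for (col in seq_len(L)) {
    if (col %in% planted_cols) next
    k <- min(background_states, 20L)
    st <- sample(AA1, k)
    pr <- rgamma(k, 1); pr <- pr / sum(pr)
    support[[col]] <- list(states = st, probs = pr)
    ali[, col] <- sample(st, n_seq, replace = TRUE, prob = pr)
  }
  for (p in seq_len(nrow(planted_pairs))) {
    i <- planted_pairs$i[p]; j <- planted_pairs$j[p]
    strength <- planted_pairs$strength[p]
    ri <- sample(AA1, 2); rj <- sample(AA1, 2)
    xi <- sample(1:2, n_seq, replace = TRUE)
    xj <- sample(1:2, n_seq, replace = TRUE)
    co <- runif(n_seq) < strength
    xj[co] <- xi[co]
    ali[, i] <- ri[xi]
    ali[, j] <- rj[xj]
  }
  if (mutation_rate > 0) {
    mut <- which(runif(n_seq * L) < mutation_rate)
    ali[mut] <- sample(AA1, length(mut), replace = TRUE)
  }
  a <- new_alignment(ali, ids = paste0("syn", seq_len(n_seq)))
  attr(a, "planted") <- planted_pairs
  a
}

#' Generate a labelled synthetic interface dataset
#'
#' Biological interfaces pair toy complexes with alignments carrying
#' planted couplings at their true contact columns; crystallographic
#' interfaces use geometrically matched complexes (same spacing/size
#' distributions) with coupling-free alignments, so only the
#' covariation-signal features separate the classes.  Feature
#' extraction runs end-to-end through the real interface, coupling and
#' feature code.
#'
#' @param n_bio,n_cry interfaces per class (defaults 20/20).
#' @param L chain length = alignment length (default 60).
#' @param n_seq sequences per alignment (default 1500).
#' @param n_contacts_range designed contact pairs per interface
#'   (sampled uniformly; default 6:10).
#' @param coupling_strength planted co-assignment probability
#'   (default 0.9).
#' @param spacing_range facing Cbeta distance range (default
#'   4.6-5.1 A).
#' @param mutation_rate alignment mutation rate (default 0.05).
#' @param seed master seed; every per-interface seed derives from it.
#' @param config feature configuration for [assemble_features()].
#' @return object of class `labeled_dataset`: `features` (matrix n x
#'   69), `labels` (factor), `ids`, `meta` (per-interface geometry and
#'   truth).
#' @export
make_labeled_dataset <- function(n_bio = 20, n_cry = 20, L = 60,
                                 n_seq = 1500, n_contacts_range = 6:10,
                                 coupling_strength = 0.9,
                                 spacing_range = c(4.6, 5.1),
                                 mutation_rate = 0.05, seed = 1,
                                 config = list()) {
  n <- n_bio + n_cry
  labels <- c(rep("biological", n_bio), rep("crystallographic", n_cry))
  rows <- vector("list", n)
  meta <- vector("list", n)
  for (idx in seq_len(n)) {
    si <- seed + 37L * idx
    set.seed(si)
    k <- if (length(n_contacts_range) > 1)
      sample(n_contacts_range, 1) else n_contacts_range
    spacing <- runif(1, spacing_range[1], spacing_range[2])
    toy <- make_toy_complex(n_res = L, spacing = spacing, offset = L - k,
                            seed = si + 1L, jitter = 0.08)
    planted <- if (labels[idx] == "biological") {
      data.frame(i = toy$true_pairs$res_query,
                 j = toy$true_pairs$res_partner,
                 strength = coupling_strength)
    } else NULL
    msa <- make_coupled_msa(L = L, n_seq = n_seq, planted_pairs = planted,
                            mutation_rate = mutation_rate, seed = si + 2L)
    cm <- coupling_scores(msa)
    iface <- detect_interface(toy$query, toy$partner)
    if (is.null(iface))
      stop("synthetic interface ", idx, " failed geometry closure")
    iface <- assign_core(set_column_map(iface, toy_column_map(toy)))
    rows[[idx]] <- assemble_features(iface, cm, query = toy$query,
                                     config = config)
    meta[[idx]] <- list(spacing = spacing, n_contacts = k,
                        seed = si, planted = planted)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  structure(list(features = features,
                 labels = factor(labels, levels = c("crystallographic",
                                                    "biological")),
                 ids = sprintf("synthetic_%03d", seq_len(n)),
                 meta = meta, seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$features), " interfaces x ",
      ncol(x$features), " features (",
      paste(names(table(x$labels)), table(x$labels), sep = ": ",
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ...) {
  data.frame(id = x$ids, label = as.character(x$labels), x$features,
             check.names = FALSE, stringsAsFactors = FALSE)
}
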