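test_that("column statistics match a hand-rolled counting oracle", {
  # single column, all A, no pseudocount
  a <- sequence_weights(new_alignment(c("A", "A", "A")))
  st <- column_stats(a, 0)
  expect_equal(st$f1[1, 1], 1)
  expect_equal(sum(st$f1[, 1]), 1)
  # pure prior
  st1 <- column_stats(a, 1)
  expect_equal(st1$f1[, 1], rep(1 / 21, 21))
  # random 10 x 4 alignment, lambda 0.2, weighted: loop oracle
  set.seed(13)
  m <- matrix(sample(c(xtalface:::AA1[1:6], "-"), 40, TRUE), 10, 4)
  a2 <- sequence_weights(new_alignment(m), 50)
  st2 <- column_stats(a2, 0.2)
  w <- a2$weights; neff <- sum(w)
  states <- xtalface:::STATES
  for (col in 1:4) {
    emp <- vapply(states, function(s) sum(w[m[, col] == s]) / neff,
                  numeric(1))
    expect_equal(st2$f1[, col], unname(0.8 * emp + 0.2 / 21),
                 tolerance = 1e-12)
  }
  # a pair block against direct counting
  i <- 1; j <- 3
  for (abn in list(c(1, 1), c(2, 5), c(21, 21))) {
    sa <- states[abn[1]]; sb <- states[abn[2]]
    emp <- sum(w[m[, i] == sa & m[, j] == sb]) / neff
    got <- st2$pair[(i - 1) * 21 + abn[1], (j - 1) * 21 + abn[2]]
    expect_equal(got, 0.8 * emp + 0.2 / 441, tolerance = 1e-12)
  }
})

test_that("pair frequencies keep their single-frequency marginals", {
  a <- sequence_weights(make_coupled_msa(L = 6, n_seq = 40, seed = 2))
  st <- column_stats(a, 0.3)
  for (i in 1:6) for (j in setdiff(1:6, i)) {
    blk <- st$pair[(i - 1) * 21 + 1:21, (j - 1) * 21 + 1:21]
    expect_equal(rowSums(blk), st$f1[, i], tolerance = 1e-9)
    expect_equal(sum(blk), 1, tolerance = 1e-9)
  }
  expect_equal(colSums(st$f1), rep(1, 6), tolerance = 1e-9)
})

test_that("identical sequences give a degenerate covariance at zero pseudocount", {
  a <- sequence_weights(new_alignment(rep("ACDEF", 10)))
  st <- column_stats(a, 0)
  expect_error(invcov_couplings(st), "degenerate")
})

test_that("perfectly covarying columns dominate the coupling scores", {
  # columns 1 and 8 jointly take (A,C) or (C,A); others independent
  set.seed(3)
  n <- 2000
  z <- sample(1:2, n, TRUE)
  m <- matrix(sample(xtalface:::AA1[1:8], n * 10, TRUE), n, 10)
  m[, 1] <- c("A", "C")[z]
  m[, 8] <- c("C", "A")[z]
  a <- sequence_weights(new_alignment(m))
  cm <- coupling_scores(a)
  tp <- top_pairs(cm, 1)
  expect_equal(c(tp$i, tp$j), c(1, 8))
  # the coupled pair dwarfs the shuffled-column background
  bg <- cm$scores[upper.tri(cm$scores)]
  bg <- bg[rank(-cm$scores[upper.tri(cm$scores)]) > 1]
  expect_gt(tp$score, 5 * max(abs(bg)))
})

test_that("raw couplings agree with a dense solve() oracle on a tiny case", {
  set.seed(8)
  m <- matrix(sample(xtalface:::AA1[1:4], 60 * 3, TRUE), 60, 3)
  a <- sequence_weights(new_alignment(m))
  st <- column_stats(a, 0.5)
  bl <- invcov_couplings(st)
  # oracle: loop-built frequencies, explicit covariance, solve()
  w <- a$weights / sum(a$weights)
  states <- xtalface:::STATES
  L <- 3; q <- 21
  f1 <- matrix(0, q, L)
  for (col in 1:L) for (s in 1:q)
    f1[s, col] <- 0.5 * sum(w[m[, col] == states[s]]) + 0.5 / 21
  Cfull <- matrix(0, q * L, q * L)
  for (i in 1:L) for (j in 1:L) for (s in 1:q) for (t in 1:q) {
    fij <- if (i == j) { if (s == t) f1[s, i] else 0 } else
      0.5 * sum(w[m[, i] == states[s] & m[, j] == states[t]]) + 0.5 / 441
    Cfull[(i - 1) * q + s, (j - 1) * q + t] <- fij - f1[s, i] * f1[t, j]
  }
  keep <- as.vector(sapply(1:L, function(i) (i - 1) * q + 1:20))
  C <- Cfull[keep, keep]
  Cs <- (1 - bl$rho) * C; diag(Cs) <- diag(C)
  expect_equal(bl$M, solve(Cs), tolerance = 1e-6)
})

test_that("block norms have their closed forms", {
  # fake inverse with an identity block between columns 1 and 2
  L <- 3
  M <- diag(0, 20 * L)
  M[1:20, 21:40] <- diag(20)
  M[21:40, 1:20] <- diag(20)
  bl <- structure(list(M = M, L = L, rho = 0), class = "coupling_blocks")
  l21 <- pair_score(bl, "l21")
  fro <- pair_score(bl, "frobenius")
  expect_equal(l21[1, 2], 20)
  expect_equal(fro[1, 2], sqrt(20))
  expect_equal(l21[1, 3], 0)
  expect_equal(l21, t(l21))
  # random block: direct summation oracle
  set.seed(4)
  B <- matrix(rnorm(400), 20, 20)
  M2 <- diag(0, 40)
  M2[1:20, 21:40] <- B; M2[21:40, 1:20] <- t(B)
  bl2 <- structure(list(M = M2, L = 2, rho = 0), class = "coupling_blocks")
  expect_equal(pair_score(bl2, "frobenius")[1, 2], sqrt(sum(B^2)))
  l21_o <- (sum(sqrt(rowSums(B^2))) + sum(sqrt(rowSums(t(B)^2)))) / 2
  expect_equal(pair_score(bl2, "l21")[1, 2], l21_o)
})

test_that("APC annihilates product structure exactly", {
  cst <- matrix(3.7, 8, 8)
  expect_lt(max(abs(apc(cst)$scores)), 1e-9)
  v <- runif(8, 0.5, 2)
  r1 <- outer(v, v)
  expect_lt(max(abs(apc(r1)$scores)), 1e-9)
  # block-wise: product structure inside every region
  expect_lt(max(abs(apc(r1, chain_boundaries = c(3, 8))$scores)), 1e-9)
})

test_that("block-wise APC equals the hand-computed per-region correction", {
  set.seed(6)
  raw <- matrix(rnorm(36), 6, 6)
  raw <- (raw + t(raw)) / 2
  got <- apc(raw, chain_boundaries = c(2, 6))$scores
  blocks <- list(1:2, 3:6)
  want <- raw
  for (u in 1:2) for (v in u:2) {
    sub <- raw[blocks[[u]], blocks[[v]], drop = FALSE]
    corr <- sub - outer(rowMeans(sub), colMeans(sub)) / mean(sub)
    want[blocks[[u]], blocks[[v]]] <- corr
    want[blocks[[v]], blocks[[u]]] <- t(corr)
  }
  diag(want) <- 0
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("coupling scores are invariant to row order and duplication", {
  a <- make_coupled_msa(L = 8, n_seq = 150,
                        planted_pairs = data.frame(i = 1, j = 7,
                                                   strength = 0.9),
                        seed = 10)
  base <- coupling_scores(a)$scores
  set.seed(1)
  perm <- sample(nrow(a$ali))
  a2 <- new_alignment(a$ali[perm, ], ids = a$ids[perm])
  expect_equal(coupling_scores(a2)$scores, base, tolerance = 1e-6)
  a3 <- new_alignment(rbind(a$ali, a$ali))
  expect_equal(coupling_scores(a3)$scores, base, tolerance = 1e-6)
})

test_that("PSICOV files load as sparse symmetric matrices", {
  p <- withr::local_tempfile()
  writeLines(c("1 5 0 8 0.73", "2 6 0 8 0.41", "3 4 0 8 0.22"), p)
  cm <- read_psicov_scores(p, L = 6)
  expect_equal(cm$scores[1, 5], 0.73)
  expect_equal(cm$scores[5, 1], 0.73)
  expect_true(is.na(cm$scores[1, 2]))
  expect_equal(sum(!is.na(cm$scores[upper.tri(cm$scores)])), 3L)
  # i > j rewrite gives the same matrix
  p2 <- withr::local_tempfile()
  writeLines(c("5 1 0 8 0.73", "6 2 0 8 0.41", "4 3 0 8 0.22"), p2)
  expect_equal(read_psicov_scores(p2, L = 6)$scores, cm$scores)
  # malformed inputs
  p3 <- withr::local_tempfile()
  writeLines("2 2 0 8 0.5", p3)
  expect_error(read_psicov_scores(p3), "i = j")
  p4 <- withr::local_tempfile()
  writeLines("1 9 0 8 0.5", p4)
  expect_error(read_psicov_scores(p4, L = 6), "out-of-range")
})

test_that("CCMpred matrices load and the native TSV round-trips", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  m <- m + t(m)
  p <- withr::local_tempfile()
  write.table(m, p, row.names = FALSE, col.names = FALSE)
  cm <- read_ccmpred_scores(p)
  expect_equal(cm$scores, m)
  expect_error(read_ccmpred_scores({
    p2 <- withr::local_tempfile()
    write.table(matrix(1, 2, 3), p2, row.names = FALSE, col.names = FALSE)
    p2
  }), "square")
  tsv <- withr::local_tempfile()
  write_coupling_tsv(cm, tsv)
  tab <- read.table(tsv, header = TRUE)
  expect_equal(nrow(tab), 6L)
  back <- matrix(0, 4, 4)
  back[cbind(tab$i, tab$j)] <- tab$score
  expect_equal(back[upper.tri(back)], m[upper.tri(m)])
})

test_that("pair ranks agree with a full sort oracle", {
  set.seed(2)
  raw <- matrix(rnorm(100), 10, 10)
  raw <- (raw + t(raw)) / 2; diag(raw) <- 0
  cm <- apc(raw)
  ut <- which(upper.tri(cm$scores), arr.ind = TRUE)
  sc <- cm$scores[ut]
  ord <- order(-sc, ut[, 1], ut[, 2])
  for (r in c(1, 7, 20)) {
    i <- ut[ord[r], 1]; j <- ut[ord[r], 2]
    expect_equal(rank_of_pair(cm, i, j), r / 10)
    expect_equal(rank_of_pair(cm, j, i), r / 10)
  }
  # unscored pair reports the no-rank sentinel
  p <- withr::local_tempfile()
  writeLines("1 7 0 8 0.5", p)
  cm2 <- read_psicov_scores(p, L = 10)
  expect_equal(rank_of_pair(cm2, 1, 7), 1 / 10)
  expect_true(is.na(rank_of_pair(cm2, 2, 3)))
})
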