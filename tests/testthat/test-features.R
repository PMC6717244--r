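test_that("amino-acid composition is BSA-normalised with degenerate flags", {
  toy <- make_toy_complex(n_res = 6, spacing = 4.8, seed = 3,
                          sequence = rep("A", 6))
  iface <- assign_core(detect_interface(toy$query, toy$partner,
                                        n_points = 1000))
  aa <- aa_composition(iface)
  expect_equal(unname(aa["A"]), 1)
  expect_equal(sum(aa), 1)
  # bookkeeping oracle on a mixed interface
  toy2 <- make_toy_complex(n_res = 6, spacing = 4.8, seed = 17)
  if2 <- assign_core(detect_interface(toy2$query, toy2$partner,
                                      n_points = 1000))
  aa2 <- aa_composition(if2)
  rr <- if2$residue_records
  ledger <- tapply(rr$bsa, aa_three_to_one(rr$resid), sum) / sum(rr$bsa)
  expect_equal(unname(aa2[names(ledger)]), as.numeric(ledger),
               tolerance = 1e-12)
  # no cores in the flat toy: AAc flagged all-zero
  aac <- aa_composition(if2, core_only = TRUE)
  expect_equal(sum(aac), 0)
  expect_equal(attr(aac, "flag"), "empty")
})

test_that("group-pair frequencies land in the documented bins", {
  mk <- function(ra, rb) data.frame(resid_query = ra, resid_partner = rb)
  f1 <- aa_pair_frequency(mk("ALA", "SER"))
  expect_equal(length(f1), 21L)
  expect_equal(unname(f1["small:small"]), 1)
  f2 <- aa_pair_frequency(mk("ASP", "LYS"))
  expect_equal(unname(f2["negative:positive"]), 1)
  # unordered: (K, D) falls in the same bin
  f3 <- aa_pair_frequency(mk("LYS", "ASP"))
  expect_equal(f3, f2)
  f0 <- aa_pair_frequency(NULL)
  expect_equal(sum(f0), 0)
  expect_equal(attr(f0, "flag"), "empty")
  # the partition is total and disjoint
  g <- aa_groups()
  expect_equal(sort(unlist(g, use.names = FALSE)), sort(xtalface:::AA1))
  expect_equal(length(unlist(g)), 20L)
})

test_that("local density counts neighbours within the radius", {
  fi <- fake_iface("A|1|.", "B|1|.", c("A|1|." = 1, "B|1|." = 10))
  fi$atoms_query$x <- 0; fi$atoms_partner$x <- 5
  expect_equal(local_density(fi, 12), 1)
  fi$atoms_partner$x <- 20
  expect_equal(local_density(fi, 12), 0)
  # O(n^2) oracle on a real toy interface
  toy <- make_toy_complex(n_res = 7, spacing = 4.6, seed = 5)
  iface <- detect_interface(toy$query, toy$partner, n_points = 1000)
  at <- rbind(iface$atoms_query[iface$atoms_query$bsa > 0,
                                c("x", "y", "z")],
              iface$atoms_partner[iface$atoms_partner$bsa > 0,
                                  c("x", "y", "z")])
  cnt <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) for (j in seq_len(nrow(at)))
    if (i != j && sqrt(sum((at[i, ] - at[j, ])^2)) <= 12)
      cnt[i] <- cnt[i] + 1
  expect_equal(local_density(iface, 12), mean(cnt))
})

test_that("residue propensity sums log propensities over interface residues", {
  toy <- make_toy_complex(n_res = 5, spacing = 4.8, seed = 7)
  iface <- detect_interface(toy$query, toy$partner, n_points = 1000)
  ones <- setNames(rep(1, 20), xtalface:::AA1)
  expect_equal(residue_propensity(iface, ones), 0)
  tab <- ones; tab[] <- exp(1)
  expect_equal(residue_propensity(iface, tab),
               nrow(iface$residue_records))
  expect_error(residue_propensity(iface, ones[1:5]), "misses")
})

test_that("gap volume grows when the interface is pulled apart", {
  tight <- make_toy_complex(n_res = 6, spacing = 4.2, seed = 2)
  apart <- make_toy_complex(n_res = 6, spacing = 5.2, seed = 2)
  gi_t <- gap_volume_index(detect_interface(tight$query, tight$partner,
                                            n_points = 1000))
  gi_a <- gap_volume_index(detect_interface(apart$query, apart$partner,
                                            n_points = 1000))
  expect_gt(gi_a, gi_t)
  # refined grid agrees within 20%
  iface <- detect_interface(apart$query, apart$partner, n_points = 1000)
  coarse <- gap_volume_index(iface, grid = 1.0)
  fine <- gap_volume_index(iface, grid = 0.5)
  expect_lt(abs(coarse - fine) / fine, 0.2)
  # external override takes precedence
  expect_equal(gap_volume_index(iface, gap_volume = 100),
               100 / iface$total_bsa)
})

test_that("CS counts apply thresholds and both artifact filters", {
  # three scored pairs at 0.5 / 0.3 / 0.7, far apart in sequence
  fi <- fake_iface(c("A|1|.", "A|10|.", "A|20|."),
                   c("B|40|.", "B|50|.", "B|60|."),
                   setNames(c(1, 10, 20, 40, 50, 60),
                            c("A|1|.", "A|10|.", "A|20|.",
                              "B|40|.", "B|50|.", "B|60|.")))
  raw <- matrix(0, 60, 60)
  raw[1, 40] <- raw[40, 1] <- 0.5
  raw[10, 50] <- raw[50, 10] <- 0.3
  raw[20, 60] <- raw[60, 20] <- 0.7
  cm <- structure(list(scores = raw, method = "builtin_invcov",
                       apc_applied = TRUE, block_structure = integer(),
                       skipped_regions = 0L), class = "coupling_matrix")
  counts <- cs_score(fi, cm, thresholds = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(as.integer(counts), c(3L, 2L, 1L, 0L))
  expect_true(all(diff(as.integer(counts)) <= 0))

  # positional difference <= 5 is excluded
  fi2 <- fake_iface("A|1|.", "B|5|.",
                    c("A|1|." = 1, "B|5|." = 5))
  raw2 <- matrix(0, 10, 10); raw2[1, 5] <- raw2[5, 1] <- 0.9
  cm2 <- structure(list(scores = raw2, method = "builtin_invcov",
                        apc_applied = TRUE, block_structure = integer(),
                        skipped_regions = 0L), class = "coupling_matrix")
  expect_equal(as.integer(cs_score(fi2, cm2, 0.2)), 0L)
  # difference 6 passes (homomeric map: the query chain carries copies
  # of both mapped positions)
  fi3 <- fake_iface("A|1|.", "B|7|.",
                    c("A|1|." = 1, "A|7|." = 7, "B|7|." = 7))
  raw3 <- matrix(0, 10, 10); raw3[1, 7] <- raw3[7, 1] <- 0.9
  cm3 <- structure(list(scores = raw3, method = "builtin_invcov",
                        apc_applied = TRUE, block_structure = integer(),
                        skipped_regions = 0L), class = "coupling_matrix")
  expect_equal(as.integer(cs_score(fi3, cm3, 0.2)), 1L)

  # intrachain Cbeta proximity (7.5 A <= 8) is excluded ...
  q_close <- cb_chain(c(1, 7), c(0, 7.5))
  expect_equal(as.integer(cs_score(fi3, cm3, 0.2, query = q_close)), 0L)
  # ... but 8.5 A passes
  q_far <- cb_chain(c(1, 7), c(0, 8.5))
  expect_equal(as.integer(cs_score(fi3, cm3, 0.2, query = q_far)), 1L)

  # unscored pairs never count
  raw4 <- matrix(NA_real_, 10, 10); diag(raw4) <- 0
  cm4 <- structure(list(scores = raw4, method = "psicov_file",
                        apc_applied = TRUE, block_structure = integer(),
                        skipped_regions = 0L), class = "coupling_matrix")
  expect_equal(as.integer(cs_score(fi3, cm4, c(0.2, 0.8))), c(0L, 0L))

  # unmapped residues: warning when partial, error when total
  fi5 <- fake_iface(c("A|1|.", "A|10|."), c("B|40|.", "B|50|."),
                    c("A|1|." = 1, "B|40|." = 40))
  expect_warning(cs_score(fi5, cm, 0.2), "unmapped")
  fi6 <- fake_iface("A|1|.", "B|40|.", c("Z|9|." = 9))
  expect_error(suppressWarnings(cs_score(fi6, cm, 0.2)), "no contact-pair")
})

test_that("cross-block pairs are exempt from the intrachain filters", {
  # hetero alignment: blocks 1..10 and 11..20; contact maps to columns
  # 3 (block 1) and 14 (block 2): positional difference |3-14| would
  # fail a naive filter but must pass across blocks
  fi <- fake_iface("A|3|.", "B|4|.", c("A|3|." = 3, "B|4|." = 14),
                   is_homomeric = FALSE)
  raw <- matrix(0, 20, 20); raw[3, 14] <- raw[14, 3] <- 0.9
  cm <- structure(list(scores = raw, method = "builtin_invcov",
                       apc_applied = TRUE, block_structure = c(10L, 20L),
                       skipped_regions = 0L), class = "coupling_matrix")
  expect_equal(as.integer(cs_score(fi, cm, 0.2)), 1L)
  # same two columns inside one block: filtered only by Cbeta geometry
  fi_mono <- fake_iface("A|3|.", "B|4|.",
                        c("A|3|." = 3, "A|14|." = 14, "B|4|." = 14))
  cm_mono <- cm; cm_mono$block_structure <- integer()
  q_close <- cb_chain(c(3, 14), c(0, 6))
  expect_equal(as.integer(cs_score(fi_mono, cm_mono, 0.2, query = q_close)), 0L)
})

test_that("the assembled feature vector is complete, deterministic and order-invariant", {
  toy <- make_toy_complex(n_res = 8, spacing = 4.8, offset = 0, seed = 19)
  a <- make_coupled_msa(L = 8, n_seq = 200, seed = 19)
  cm <- coupling_scores(a)
  iface <- set_column_map(detect_interface(toy$query, toy$partner,
                                           n_points = 1000),
                          toy_column_map(toy))
  fv <- assemble_features(iface, cm, query = toy$query)
  expect_length(fv, 69L)
  expect_true(all(is.finite(fv)))
  expect_equal(sum(fv[paste0("AA_", xtalface:::AA1)]), 1, tolerance = 1e-9)
  fv2 <- assemble_features(iface, cm, query = toy$query)
  expect_identical(fv, fv2)
  # shuffling atom row order changes nothing
  set.seed(1)
  q2 <- toy$query; q2$atoms <- q2$atoms[sample(nrow(q2$atoms)), ]
  p2 <- toy$partner; p2$atoms <- p2$atoms[sample(nrow(p2$atoms)), ]
  iface3 <- set_column_map(detect_interface(q2, p2, n_points = 1000),
                           toy_column_map(toy))
  fv3 <- assemble_features(iface3, cm, query = q2)
  expect_equal(fv3, fv, tolerance = 1e-9)
})

test_that("CS counts are monotone across thresholds on real interfaces", {
  toy <- make_toy_complex(n_res = 12, spacing = 4.8, offset = 7, seed = 23)
  pl <- data.frame(i = seq_len(5), j = seq_len(5) + 7, strength = 0.9)
  a <- make_coupled_msa(L = 12, n_seq = 400, planted_pairs = pl, seed = 23)
  cm <- coupling_scores(a)
  iface <- set_column_map(detect_interface(toy$query, toy$partner,
                                           n_points = 1000),
                          toy_column_map(toy))
  counts <- cs_score(iface, cm, c(0.2, 0.4, 0.6, 0.8), query = toy$query)
  expect_true(all(diff(as.integer(counts)) <= 0))
})

test_that("feature tables round-trip through the TSV writer", {
  d <- data.frame(id = c("a", "b"), label = c("biological",
                                              "crystallographic"),
                  AA_A = c(0.5, 0.1), CS_0.4 = c(3, 0),
                  check.names = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(d, p)
  back <- read_feature_table(p)
  expect_equal(back, d)
})
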