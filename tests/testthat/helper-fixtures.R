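# Fixtures and independent oracles shared across test files.

# -- tiny PDB fixture with waters, hydrogens and an altloc pair --------
write_messy_pdb <- function(path) {
  lines <- c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.450   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       1.450   0.300   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       3.200   1.500   0.000  1.00  0.00           O",
    "ATOM      6  H   ALA A   1       0.500   0.900   0.000  1.00  0.00           H",
    "ATOM      7  N   GLY A   2       1.500   2.600   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY A   2       2.000   3.900   0.000  1.00  0.00           C",
    "ATOM      9  C   GLY A   2       3.500   4.000   0.000  1.00  0.00           C",
    "ATOM     10  O   GLY A   2       4.100   5.100   0.000  1.00  0.00           O",
    "HETATM   11  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# structure of n isolated atoms given coordinates (single-atom residues)
atoms_structure <- function(xyz, element = "C", chain = "A",
                            resid = "ALA", elety = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  new_structure(data.frame(
    chain = chain, resno = seq_len(n), ins = "", resid = resid,
    elety = elety %||% rep("CA", n), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic SASA of two intersecting spheres with extended radii r1, r2
# at separation d: each loses the spherical cap cut by the radical
# plane
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1,
    4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# ---- brute-force interface oracle -----------------------------------
# independent recomputation of the interface definitions from raw
# coordinates: per-atom BSA from two compute_sasa() runs, exhaustive
# all-against-all distance scan, direct threshold checks
oracle_interface <- function(query, partner, cutoff = 5.5,
                             min_bsa = 0.1, rel_thr = 0.25,
                             core_thr = 0.95, n_points = 3000) {
  max_tab <- max_sasa_table()
  sasa_of <- function(s) compute_sasa(s, n_points = n_points)$per_atom_sasa
  both <- query
  both$atoms <- rbind(query$atoms, partner$atoms)
  sab <- sasa_of(both)
  nq <- nrow(query$atoms)
  bsa_q <- pmax(sasa_of(query) - sab[seq_len(nq)], 0)
  bsa_p <- pmax(sasa_of(partner) - sab[nq + seq_len(nrow(partner$atoms))], 0)
  aq <- query$atoms; ap <- partner$atoms
  contact <- list()
  for (i in seq_len(nrow(aq))) for (j in seq_len(nrow(ap))) {
    d <- sqrt(sum((c(aq$x[i], aq$y[i], aq$z[i]) -
                     c(ap$x[j], ap$y[j], ap$z[j]))^2))
    if (d < cutoff && bsa_q[i] >= min_bsa && bsa_p[j] >= min_bsa)
      contact[[length(contact) + 1L]] <- c(i, j)
  }
  if (!length(contact))
    return(list(atom_pairs = NULL, residue_pairs = NULL, core = NULL))
  atom_pairs <- do.call(rbind, contact)

  res_info <- function(at, bsa, sasa_alone) {
    key <- xtalface:::residue_key(at$chain, at$resno, at$ins)
    ukeys <- unique(key)
    data.frame(key = ukeys,
               resid = at$resid[match(ukeys, key)],
               sasa = as.numeric(tapply(sasa_alone, key, sum)[ukeys]),
               bsa = as.numeric(tapply(bsa, key, sum)[ukeys]),
               mc = vapply(ukeys, function(k)
                 all(c("N", "CA", "C", "O") %in% at$elety[key == k]),
                 logical(1)),
               stringsAsFactors = FALSE)
  }
  sq <- compute_sasa(query, n_points = n_points)$per_atom_sasa
  sp <- compute_sasa(partner, n_points = n_points)$per_atom_sasa
  rq <- res_info(aq, bsa_q, sq)
  rp <- res_info(ap, bsa_p, sp)
  keyq <- xtalface:::residue_key(aq$chain, aq$resno, aq$ins)
  keyp <- xtalface:::residue_key(ap$chain, ap$resno, ap$ins)
  rpairs <- unique(data.frame(
    key_query = keyq[atom_pairs[, 1]],
    key_partner = keyp[atom_pairs[, 2]], stringsAsFactors = FALSE))
  ok <- vapply(seq_len(nrow(rpairs)), function(r) {
    a <- rq[rq$key == rpairs$key_query[r], ]
    b <- rp[rp$key == rpairs$key_partner[r], ]
    rel_a <- a$sasa / max_tab[a$resid]
    rel_b <- b$sasa / max_tab[b$resid]
    a$mc && b$mc && rel_a > rel_thr && rel_b > rel_thr
  }, logical(1))
  # core: interface residues (any atom BSA >= min_bsa or in a pair)
  # with bsa/sasa > core_thr
  core_of <- function(rr, bsa_atoms, at, pair_keys) {
    key <- xtalface:::residue_key(at$chain, at$resno, at$ins)
    listed <- rr$key[vapply(rr$key, function(k)
      any(bsa_atoms[key == k] >= min_bsa), logical(1)) |
        rr$key %in% pair_keys]
    rr2 <- rr[rr$key %in% listed, ]
    rr2$key[rr2$sasa > 0 & rr2$bsa / rr2$sasa > core_thr]
  }
  list(atom_pairs = atom_pairs,
       residue_pairs = rpairs[ok, , drop = FALSE],
       core = list(query = core_of(rq, bsa_q, aq, keyq[atom_pairs[, 1]]),
                   partner = core_of(rp, bsa_p, ap, keyp[atom_pairs[, 2]])))
}

# ---- hand-made minimal interface for cs_score filter tests ----------
# residues of one chain A and one chain B; contact pairs as given;
# every residue surface-qualified and main-chain complete
fake_iface <- function(pair_keys_q, pair_keys_p, column_map,
                       is_homomeric = TRUE) {
  mk_rec <- function(keys, side) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(side = side, key = keys,
               chain = vapply(parts, `[`, "", 1),
               resno = as.integer(vapply(parts, `[`, "", 2)),
               ins = "", resid = "ALA",
               sasa_alone = 100, sasa_complex = 60, bsa = 40,
               rel_sasa = 0.8, mainchain_complete = TRUE, is_core = FALSE,
               stringsAsFactors = FALSE)
  }
  uq <- unique(pair_keys_q); up <- unique(pair_keys_p)
  cap <- data.frame(atom_query = match(pair_keys_q, uq),
                    atom_partner = match(pair_keys_p, up),
                    distance = 4.5)
  mk_atoms <- function(keys, chain) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(chain = vapply(parts, `[`, "", 1),
               resno = as.integer(vapply(parts, `[`, "", 2)),
               ins = "", resid = "ALA", elety = "CB", element = "C",
               x = seq_along(keys), y = 0, z = 0, occ = 1, bsa = 1,
               sasa_alone = 10, sasa_complex = 9,
               stringsAsFactors = FALSE)
  }
  structure(list(query_chain_ids = "A", partner_chain_ids = "B",
                 atoms_query = mk_atoms(uq, "A"),
                 atoms_partner = mk_atoms(up, "B"),
                 contact_atom_pairs = cap,
                 residue_records = rbind(mk_rec(uq, "query"),
                                         mk_rec(up, "partner")),
                 total_bsa = 40 * (length(uq) + length(up)),
                 is_homomeric = is_homomeric,
                 msa_column_map = column_map,
                 params = list(cutoff = 5.5, min_bsa = 0.1)),
            class = "xtal_interface")
}

# query structure with one CB atom per residue at given x positions
# (chain A), so intrachain CB distances are controllable
cb_chain <- function(resno, x, chain = "A") {
  new_structure(data.frame(
    chain = chain, resno = resno, ins = "", resid = "ALA", elety = "CB",
    element = "C", x = x, y = 0, z = 0, occ = 1,
    stringsAsFactors = FALSE))
}

# small labelled feature fixture for classifier tests: k_informative
# features shifted between classes, rest pure noise
sim_features <- function(n_per_class = 20, p = 10, k_informative = 2,
                         shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- sprintf("f%02d", seq_len(p))
  y <- rep(c("biological", "crystallographic"), each = n_per_class)
  x[y == "biological", seq_len(k_informative)] <-
    x[y == "biological", seq_len(k_informative)] + shift
  list(x = x, y = y)
}
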