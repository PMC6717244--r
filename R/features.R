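# Interface feature vector: compositional/geometric descriptors plus
# the covariation-signal counts.

#' The six amino-acid groups
#'
#' Partition used to reduce the 400 naive residue-pair combinations to
#' 21 unordered group pairs: small (A, C, G, P, S, T), negatively
#' charged (D, E), positively charged (H, K, R), aromatic (F, W, Y),
#' hydrophobic (I, L, M, V), other (N, Q).
#'
#' @return named list of character vectors (a total, disjoint partition
#'   of the 20 amino acids).
#' @export
aa_groups <- function() {
  list(small = c("A", "C", "G", "P", "S", "T"),
       negative = c("D", "E"),
       positive = c("H", "K", "R"),
       aromatic = c("F", "W", "Y"),
       hydrophobic = c("I", "L", "M", "V"),
       other = c("N", "Q"))
}

aa_group_of <- function(aa1) {
  g <- aa_groups()
  lut <- setNames(rep(names(g), lengths(g)), unlist(g))
  unname(lut[aa1])
}

group_pair_names <- function() {
  gn <- names(aa_groups())
  pairs <- t(utils::combn(gn, 2))
  c(paste(gn, gn, sep = ":"), paste(pairs[, 1], pairs[, 2], sep = ":"))
}

#' Amino-acid composition of an interface by buried area
#'
#' Per-residue-type BSA summed over the interface residues of both
#' sides, divided by the total BSA (of all interface residues, or of
#' core residues only).
#'
#' @param iface interface; for `core_only = TRUE` core assignment must
#'   be present (see [assign_core()]).
#' @param core_only restrict to core residues.
#' @return named numeric vector of 20 fractions (alphabetical
#'   one-letter order); all zeros with attribute `flag = "empty"` when
#'   the relevant total BSA is zero.
#' @export
aa_composition <- function(iface, core_only = FALSE) {
  rr <- iface$residue_records
  if (core_only) {
    if (anyNA(rr$is_core)) stop("run assign_core() first")
    rr <- rr[rr$is_core, , drop = FALSE]
  }
  out <- setNames(numeric(20), AA1)
  aa <- aa_three_to_one(rr$resid)
  tot <- sum(rr$bsa)
  if (nrow(rr) == 0L || tot <= 0) {
    attr(out, "flag") <- "empty"
    return(out)
  }
  agg <- tapply(rr$bsa, factor(aa, levels = AA1), sum)
  agg[is.na(agg)] <- 0
  out[] <- agg / tot
  out
}

#' Group-pair frequencies of residue contact pairs
#'
#' Each residue contact pair is mapped to an unordered pair of the six
#' amino-acid groups; counts are normalised by the number of pairs.
#'
#' @param pairs data frame from [residue_contact_pairs()] (columns
#'   `resid_query`, `resid_partner`).
#' @return named numeric vector of 21 frequencies; all zeros with
#'   attribute `flag = "empty"` when there are no pairs.
#' @export
aa_pair_frequency <- function(pairs) {
  nm <- group_pair_names()
  out <- setNames(numeric(length(nm)), nm)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    attr(out, "flag") <- "empty"
    return(out)
  }
  ga <- aa_group_of(aa_three_to_one(pairs$resid_query))
  gb <- aa_group_of(aa_three_to_one(pairs$resid_partner))
  if (anyNA(ga) || anyNA(gb)) stop("non-standard residue in contact pairs")
  key <- ifelse(paste(ga, gb, sep = ":") %in% nm,
                paste(ga, gb, sep = ":"), paste(gb, ga, sep = ":"))
  tab <- table(factor(key, levels = nm))
  out[] <- as.numeric(tab) / nrow(pairs)
  out
}

interface_atoms <- function(iface) {
  aq <- iface$atoms_query; ap <- iface$atoms_partner
  rbind(cbind(aq[aq$bsa > 0, c("x", "y", "z")], side = "query"),
        cbind(ap[ap$bsa > 0, c("x", "y", "z")], side = "partner"))
}

#' Local atomic density of an interface
#'
#' Mean, over the interface atoms of both sides (atoms with positive
#' BSA), of the number of other interface atoms within `radius`.
#'
#' @param iface interface.
#' @param radius neighbourhood radius in Angstrom (default 12).
#' @return a single density value.
#' @export
local_density <- function(iface, radius = 12) {
  at <- interface_atoms(iface)
  if (nrow(at) == 0L) stop("no interface atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  counts <- rowSums(d2 <= radius^2) - 1L  # exclude self
  mean(counts)
}

#' Residue propensity score of an interface
#'
#' Sum over interface residues (both sides) of the log propensity of
#' their amino-acid type.
#'
#' @param iface interface.
#' @param table named numeric vector of propensities (ratios, not logs)
#'   covering all residue types present; see
#'   [derive_propensity_table()].
#' @return a single score.
#' @export
residue_propensity <- function(iface, table = NULL) {
  if (is.null(table)) table <- default_propensity_table()
  rr <- iface$residue_records
  aa <- aa_three_to_one(rr$resid)
  if (any(!aa %in% names(table)))
    stop("propensity table misses residue type(s): ",
         paste(unique(aa[!aa %in% names(table)]), collapse = ", "))
  sum(log(table[aa]))
}

default_propensity_table <- function() {
  tab <- read.table(extdata_path("propensity_synthetic.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  setNames(tab$propensity, tab$aa)
}

#' Derive an interface propensity table from labelled structures
#'
#' Propensity of a residue type = its frequency among interface
#' residues / its frequency among surface residues (relative SASA above
#' `rel_sasa_threshold`) of the same structures, with add-one
#' smoothing.  The shipped default table was generated from the
#' synthetic fixture set and is regenerable.
#'
#' @param ifaces list of interfaces.
#' @param rel_sasa_threshold surface definition (default 0.25).
#' @return named numeric vector of 20 propensities.
#' @export
derive_propensity_table <- function(ifaces, rel_sasa_threshold = 0.25) {
  max_tab <- max_sasa_table()
  iface_aa <- character(); surf_aa <- character()
  for (f in ifaces) {
    rr <- f$residue_records
    iface_aa <- c(iface_aa, aa_three_to_one(rr$resid))
    for (at in list(f$atoms_query, f$atoms_partner)) {
      key <- residue_key(at$chain, at$resno, at$ins)
      first <- !duplicated(key)
      sasa <- tapply(at$sasa_alone, key, sum)[key[first]]
      rel <- sasa / max_tab[at$resid[first]]
      surf_aa <- c(surf_aa, aa_three_to_one(at$resid[first][
        !is.na(rel) & rel > rel_sasa_threshold]))
    }
  }
  fi <- (table(factor(iface_aa, levels = AA1)) + 1) /
    (length(iface_aa) + 20)
  fs <- (table(factor(surf_aa, levels = AA1)) + 1) /
    (length(surf_aa) + 20)
  setNames(as.numeric(fi / fs), AA1)
}

#' Gap volume index of an interface
#'
#' Grid estimator of the empty volume trapped between the two sides:
#' voxels outside every atom's van der Waals sphere whose nearest-atom
#' (centre) distance to each side is at most `gap_max`, scaled by the
#' voxel volume and divided by the total BSA.  A documented stand-in
#' for cavity-surface gap-volume programs; pass `gap_volume` to use an
#' externally computed volume instead.
#'
#' @param iface interface with positive total BSA.
#' @param grid voxel edge in Angstrom (default 1.0).
#' @param gap_max maximal centre distance to each side (default 5.0).
#' @param radii vdW radii, default [vdw_radii()].
#' @param gap_volume optional externally computed gap volume (A^3)
#'   overriding the grid estimate.
#' @return index in Angstrom (volume / area).
#' @export
gap_volume_index <- function(iface, grid = 1.0, gap_max = 5.0,
                             radii = NULL, gap_volume = NULL) {
  if (iface$total_bsa <= 0) stop("interface has zero total BSA")
  if (!is.null(gap_volume)) return(gap_volume / iface$total_bsa)
  if (is.null(radii)) radii <- vdw_radii()
  aq <- iface$atoms_query; ap <- iface$atoms_partner
  iq <- aq[aq$bsa > 0, , drop = FALSE]
  ip <- ap[ap$bsa > 0, , drop = FALSE]
  if (nrow(iq) == 0L || nrow(ip) == 0L) return(0)
  box <- rbind(as.matrix(iq[, c("x", "y", "z")]),
               as.matrix(ip[, c("x", "y", "z")]))
  # pad by gap_max so the scan covers all space that can qualify
  lo <- apply(box, 2, min) - gap_max
  hi <- apply(box, 2, max) + gap_max
  gx <- seq(lo[1], hi[1], by = grid)
  gy <- seq(lo[2], hi[2], by = grid)
  gz <- seq(lo[3], hi[3], by = grid)
  vox <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  all_at <- rbind(aq, ap)
  axyz <- as.matrix(all_at[, c("x", "y", "z")])
  arad <- radii[toupper(all_at$element)]
  arad[is.na(arad)] <- 1.8
  d2all <- outer(rowSums(vox^2), rowSums(axyz^2), "+") -
    2 * tcrossprod(vox, axyz)
  d2all[d2all < 0] <- 0
  outside <- rowSums(d2all < matrix(arad^2, nrow(vox), length(arad),
                                    byrow = TRUE)) == 0L
  nq <- nrow(aq)
  dq <- sqrt(apply(d2all[, seq_len(nq), drop = FALSE], 1, min))
  dp <- sqrt(apply(d2all[, nq + seq_len(nrow(ap)), drop = FALSE], 1, min))
  n_gap <- sum(outside & dq <= gap_max & dp <= gap_max)
  grid^3 * n_gap / iface$total_bsa
}

# Cbeta coordinates per residue key of a structure; for glycine (or a
# missing CB) a virtual Cbeta is built from N/CA/C ideal geometry
cbeta_coords <- function(s) {
  at <- s$atoms
  key <- residue_key(at$chain, at$resno, at$ins)
  out <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    sub <- at[i, , drop = FALSE]
    cb <- sub[sub$elety == "CB", c("x", "y", "z")]
    if (nrow(cb) >= 1L) {
      out[[k]] <- as.numeric(cb[1, ])
    } else {
      n <- sub[sub$elety == "N", c("x", "y", "z")]
      ca <- sub[sub$elety == "CA", c("x", "y", "z")]
      cc <- sub[sub$elety == "C", c("x", "y", "z")]
      if (nrow(n) && nrow(ca) && nrow(cc))
        out[[k]] <- virtual_cbeta(as.numeric(n[1, ]), as.numeric(ca[1, ]),
                                  as.numeric(cc[1, ]))
    }
  }
  out
}

# ideal virtual Cbeta from backbone N, CA, C (tetrahedral geometry,
# 1.53 A bond)
virtual_cbeta <- function(n, ca, cc) {
  b1 <- n - ca; b2 <- cc - ca
  b1 <- b1 / sqrt(sum(b1^2)); b2 <- b2 / sqrt(sum(b2^2))
  bisec <- -(b1 + b2); bisec <- bisec / sqrt(sum(bisec^2))
  perp <- pracma_cross(b1, b2); perp <- perp / sqrt(sum(perp^2))
  # 1.53 A along the direction opposite the N/C bisector, tilted out of
  # the N-CA-C plane by the tetrahedral half-angle
  ca + 1.53 * (cos(0.9) * bisec + sin(0.9) * perp)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Covariation-signal counts of an interface
#'
#' For each threshold, counts the residue contact pairs whose mapped
#' alignment columns have an APC-corrected coupling score above the
#' threshold (strict `>`).  Two artifact filters remove pairs whose
#' signal likely reflects intrachain structure rather than the
#' interface: pairs whose mapped columns are 5 or fewer positions apart
#' in the primary structure, and pairs whose intrachain copies' Cbeta
#' atoms lie within 8 A.  Both filters act within a chain block;
#' cross-block (hetero) pairs are exempt.  Unscored pairs never count.
#'
#' @param iface interface with `msa_column_map` set (see
#'   [set_column_map()]).
#' @param cm coupling matrix.
#' @param thresholds ascending score thresholds
#'   (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param query query structure (source of intrachain Cbeta geometry).
#' @param min_separation positional-difference filter (default 5:
#'   pairs with `|i - j| <= 5` are excluded).
#' @param min_cb_dist Cbeta-distance filter in Angstrom (default 8,
#'   pairs at `<= 8` are excluded).
#' @param rel_sasa_threshold passed to [residue_contact_pairs()].
#' @return named integer vector of counts, one per threshold
#'   (`CS_<t>`), with attribute `n_pairs_considered`.
#' @export
cs_score <- function(iface, cm, thresholds = c(0.2, 0.4, 0.6, 0.8),
                     query = NULL, min_separation = 5, min_cb_dist = 8,
                     rel_sasa_threshold = 0.25) {
  stopifnot(!is.unsorted(thresholds))
  map <- iface$msa_column_map
  if (is.null(map)) stop("interface has no msa_column_map")
  pairs <- residue_contact_pairs(iface, rel_sasa_threshold)
  out <- setNames(integer(length(thresholds)),
                  paste0("CS_", format(thresholds, trim = TRUE)))
  if (nrow(pairs) == 0L) {
    attr(out, "n_pairs_considered") <- 0L
    return(out)
  }
  ci <- map[pairs$key_query]
  cj <- map[pairs$key_partner]
  unmapped <- is.na(ci) | is.na(cj)
  if (all(unmapped)) stop("no contact-pair residue maps to an alignment column")
  if (any(unmapped))
    warning(sum(unmapped), " contact pair(s) skipped: unmapped residue")
  pairs <- pairs[!unmapped, , drop = FALSE]
  ci <- ci[!unmapped]; cj <- cj[!unmapped]

  L <- nrow(cm$scores)
  bounds <- cm$block_structure
  if (!length(bounds)) bounds <- L
  block_of <- findInterval(seq_len(L), c(0, bounds), left.open = TRUE)
  same_block <- block_of[ci] == block_of[cj]

  keep <- rep(TRUE, length(ci))
  keep[same_block & abs(ci - cj) <= min_separation] <- FALSE

  # intrachain Cbeta filter: distance between the same-chain copies of
  # the two mapped positions in the query structure
  if (any(keep & same_block)) {
    cb_str <- if (is.null(query)) NULL else cbeta_coords(query)
    col2key <- intrachain_column_lookup(iface, query)
    for (p in which(keep & same_block)) {
      ka <- col2key[as.character(ci[p])]
      kb <- col2key[as.character(cj[p])]
      if (is.na(ka) || is.na(kb)) next
      pa <- cb_str[[ka]]; pb <- cb_str[[kb]]
      if (is.null(pa) || is.null(pb)) next
      if (sqrt(sum((pa - pb)^2)) <= min_cb_dist) keep[p] <- FALSE
    }
  }
  sc <- cm$scores[cbind(ci[keep], cj[keep])]
  sc <- sc[!is.na(sc)]
  out[] <- vapply(thresholds, function(t) sum(sc > t), integer(1))
  attr(out, "n_pairs_considered") <- length(ci)
  out
}

# column -> query-side residue key lookup for the intrachain filter
intrachain_column_lookup <- function(iface, query) {
  if (is.null(query)) return(setNames(NA_character_, character()))
  map <- iface$msa_column_map
  qkeys <- residue_key(query$atoms$chain, query$atoms$resno,
                       query$atoms$ins)
  qmap <- map[names(map) %in% qkeys]
  setNames(names(qmap), as.character(unname(qmap)))[
    as.character(sort(unique(unname(qmap))))]
}

#' Assemble the full interface feature vector
#'
#' Fixed-order vector of the 65 classical descriptors (20 AA + 20 AAc +
#' 21 AApair + LD + RP + GVI + Ncore) plus one covariation-signal count
#' per threshold (4 by default), 69 components in total.
#'
#' @param iface interface (core assignment is performed if absent).
#' @param cm coupling matrix, or `NULL` to set the CS counts `NA`
#'   (e.g. when building a known-features-only table).
#' @param query query structure for the Cbeta filter.
#' @param config list of tunables: `thresholds`, `ld_radius`,
#'   `gvi_grid`, `gvi_gap_max`, `propensity_table`,
#'   `rel_sasa_threshold`; missing entries take the documented
#'   defaults.
#' @return named numeric vector of length 65 + number of thresholds,
#'   with attribute `flags` naming degenerate sub-vectors.
#' @export
assemble_features <- function(iface, cm = NULL, query = NULL,
                              config = list()) {
  cfg <- utils::modifyList(list(thresholds = c(0.2, 0.4, 0.6, 0.8),
                                ld_radius = 12, gvi_grid = 1.0,
                                gvi_gap_max = 5.0,
                                propensity_table = NULL,
                                rel_sasa_threshold = 0.25), config)
  if (anyNA(iface$residue_records$is_core)) iface <- assign_core(iface)
  pairs <- residue_contact_pairs(iface, cfg$rel_sasa_threshold)
  aa <- aa_composition(iface, core_only = FALSE)
  aac <- aa_composition(iface, core_only = TRUE)
  aap <- aa_pair_frequency(pairs)
  flags <- c(if (!is.null(attr(aac, "flag"))) "AAc",
             if (!is.null(attr(aap, "flag"))) "AApair")
  cs <- if (is.null(cm)) {
    setNames(rep(NA_real_, length(cfg$thresholds)),
             paste0("CS_", format(cfg$thresholds, trim = TRUE)))
  } else {
    cs_score(iface, cm, cfg$thresholds, query = query,
             rel_sasa_threshold = cfg$rel_sasa_threshold)
  }
  out <- c(setNames(as.numeric(aa), paste0("AA_", names(aa))),
           setNames(as.numeric(aac), paste0("AAc_", names(aac))),
           setNames(as.numeric(aap), paste0("AApair_", names(aap))),
           LD = local_density(iface, cfg$ld_radius),
           RP = residue_propensity(iface, cfg$propensity_table),
           GVI = gap_volume_index(iface, cfg$gvi_grid, cfg$gvi_gap_max),
           Ncore = sum(iface$residue_records$is_core),
           as.numeric(cs))
  names(out)[(length(out) - length(cs) + 1):length(out)] <- names(cs)
  attr(out, "flags") <- flags
  out
}

#' Names of the covariation-signal features
#' @param thresholds score thresholds.
#' @return character vector like `c("CS_0.2", ...)`.
#' @export
cs_feature_names <- function(thresholds = c(0.2, 0.4, 0.6, 0.8)) {
  paste0("CS_", format(thresholds, trim = TRUE))
}

#' Write/read an interface feature table
#'
#' TSV with a header of canonical feature names, one interface per row,
#' plus `id` and `label` columns.
#'
#' @param x data frame (rows = interfaces) whose columns include the
#'   features plus `id` and `label`.
#' @param path file.
#' @return `path` invisibly (writer); data frame (reader).
#' @export
write_feature_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}
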