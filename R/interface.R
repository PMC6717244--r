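# Interface detection, residue contact pairs, core/rim assignment.

#' Detect the interface between two structures
#'
#' An interface exists when at least one non-hydrogen atom pair between
#' query and partner lies closer than `cutoff` (strict `<`) and both
#' atoms lose at least `min_bsa` of accessible surface upon complex
#' formation.
#'
#' @param query,partner structures (hydrogens already dropped on read).
#' @param cutoff contact distance in Angstrom (default 5.5).
#' @param min_bsa minimum per-atom BSA in A^2 (default 0.1).
#' @inheritParams compute_sasa
#' @param max_sasa reference maximal-SASA table, default
#'   [max_sasa_table()], used to attach relative SASA to each residue.
#' @return an object of class `xtal_interface`, or `NULL` when no atom
#'   pair qualifies.  Fields: `atoms_query`/`atoms_partner` (atom tables
#'   with per-atom `sasa_alone`, `sasa_complex`, `bsa`),
#'   `contact_atom_pairs`, `residue_records`, `total_bsa`,
#'   `is_homomeric`, `msa_column_map` (filled by the caller).
#' @export
detect_interface <- function(query, partner, cutoff = 5.5, min_bsa = 0.1,
                             probe = 1.4, n_points = 3000, radii = NULL,
                             max_sasa = NULL) {
  if (is.null(max_sasa)) max_sasa <- max_sasa_table()
  bq <- compute_bsa(query, partner, probe, n_points, radii)
  bp <- compute_bsa(partner, query, probe, n_points, radii)
  aq <- query$atoms
  aq$sasa_alone <- bq$sasa_alone; aq$sasa_complex <- bq$sasa_complex
  aq$bsa <- bq$per_atom_bsa
  ap <- partner$atoms
  ap$sasa_alone <- bp$sasa_alone; ap$sasa_complex <- bp$sasa_complex
  ap$bsa <- bp$per_atom_bsa

  xq <- as.matrix(aq[, c("x", "y", "z")])
  xp <- as.matrix(ap[, c("x", "y", "z")])
  d2 <- outer(rowSums(xq^2), rowSums(xp^2), "+") - 2 * tcrossprod(xq, xp)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit)) {
    ok <- aq$bsa[hit[, 1]] >= min_bsa & ap$bsa[hit[, 2]] >= min_bsa
    hit <- hit[ok, , drop = FALSE]
  }
  if (nrow(hit) == 0L) return(NULL)
  cap <- data.frame(atom_query = hit[, 1], atom_partner = hit[, 2],
                    distance = sqrt(d2[hit]))
  cap <- cap[order(cap$atom_query, cap$atom_partner), , drop = FALSE]
  rownames(cap) <- NULL

  rec <- function(at, side, contact_atoms) {
    key <- residue_key(at$chain, at$resno, at$ins)
    in_contact <- seq_len(nrow(at)) %in% contact_atoms
    keep_keys <- unique(key[at$bsa >= min_bsa | in_contact])
    if (!length(keep_keys)) return(NULL)
    idx <- split(seq_len(nrow(at)), key)
    out <- lapply(keep_keys, function(k) {
      i <- idx[[k]]
      resid <- at$resid[i[1]]
      data.frame(side = side, key = k, chain = at$chain[i[1]],
                 resno = at$resno[i[1]], ins = at$ins[i[1]], resid = resid,
                 sasa_alone = sum(at$sasa_alone[i]),
                 sasa_complex = sum(at$sasa_complex[i]),
                 bsa = sum(at$bsa[i]),
                 rel_sasa = sum(at$sasa_alone[i]) /
                   unname(max_sasa[resid])[1],
                 mainchain_complete = all(c("N", "CA", "C", "O") %in%
                                            at$elety[i]),
                 is_core = NA, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  records <- rbind(rec(aq, "query", cap$atom_query),
                   rec(ap, "partner", cap$atom_partner))
  rownames(records) <- NULL

  iface <- structure(list(
    query_chain_ids = unique(aq$chain),
    partner_chain_ids = unique(ap$chain),
    atoms_query = aq, atoms_partner = ap,
    contact_atom_pairs = cap,
    residue_records = records,
    total_bsa = sum(records$bsa),
    is_homomeric = identical(structure_sequence(query),
                             structure_sequence(partner)),
    msa_column_map = NULL,
    params = list(cutoff = cutoff, min_bsa = min_bsa, probe = probe,
                  n_points = n_points)),
    class = "xtal_interface")
  iface
}

structure_sequence <- function(s) {
  paste(vapply(unique(s$atoms$chain), function(ch) chain_sequence(s, ch),
               character(1)), collapse = "/")
}

#' @export
print.xtal_interface <- function(x, ...) {
  cat("<xtal_interface> ", nrow(x$contact_atom_pairs), " contact atom pairs, ",
      nrow(x$residue_records), " interface residues, total BSA ",
      round(x$total_bsa, 1), " A^2",
      if (isTRUE(x$is_homomeric)) " (homomeric)" else "", "\n", sep = "")
  invisible(x)
}

#' Residue contact pairs of an interface
#'
#' Residue-level pairs underlying the atom contacts, restricted to
#' residues that (1) have all main-chain atoms (N, CA, C, O) and
#' (2) are surface residues, i.e. relative SASA of the unbound monomer
#' above `rel_sasa_threshold`.
#'
#' @param iface an interface from [detect_interface()].
#' @param rel_sasa_threshold surface-residue threshold as a fraction
#'   (default 0.25).
#' @return data frame with query/partner residue keys, residue types
#'   and the minimal atom-pair distance; zero rows when nothing
#'   qualifies.
#' @export
residue_contact_pairs <- function(iface, rel_sasa_threshold = 0.25) {
  cap <- iface$contact_atom_pairs
  aq <- iface$atoms_query; ap <- iface$atoms_partner
  kq <- residue_key(aq$chain, aq$resno, aq$ins)[cap$atom_query]
  kp <- residue_key(ap$chain, ap$resno, ap$ins)[cap$atom_partner]
  pair_id <- paste(kq, kp, sep = " :: ")
  first <- !duplicated(pair_id)
  pairs <- data.frame(key_query = kq[first], key_partner = kp[first],
                      stringsAsFactors = FALSE)
  pairs$min_distance <- as.numeric(
    tapply(cap$distance, pair_id, min)[pair_id[first]])
  rr <- iface$residue_records
  recq <- rr[rr$side == "query", ]; recp <- rr[rr$side == "partner", ]
  iq <- match(pairs$key_query, recq$key)
  ip <- match(pairs$key_partner, recp$key)
  stopifnot(!anyNA(iq), !anyNA(ip))
  if (anyNA(recq$rel_sasa[iq]) || anyNA(recp$rel_sasa[ip]))
    stop("residue type missing from the maximal-SASA table")
  keep <- recq$mainchain_complete[iq] & recp$mainchain_complete[ip] &
    recq$rel_sasa[iq] > rel_sasa_threshold &
    recp$rel_sasa[ip] > rel_sasa_threshold
  pairs$resid_query <- recq$resid[iq]
  pairs$resid_partner <- recp$resid[ip]
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign interface core residues
#'
#' A core residue is a surface residue almost fully buried by the
#' partner: BSA / SASA(unbound) strictly greater than 0.95.  Residues
#' with zero unbound SASA are never core.
#'
#' @param iface an interface.
#' @param core_ratio burial ratio threshold (default 0.95, strict `>`).
#' @return the interface with `residue_records$is_core` filled.
#' @export
assign_core <- function(iface, core_ratio = 0.95) {
  rr <- iface$residue_records
  ratio <- ifelse(rr$sasa_alone > 0, rr$bsa / rr$sasa_alone, 0)
  iface$residue_records$is_core <- ratio > core_ratio
  iface
}

#' Set the residue-to-alignment-column map of an interface
#'
#' @param iface an interface.
#' @param map named integer vector: residue key (`chain|resno|ins`) to
#'   1-based alignment column.
#' @return the updated interface.
#' @export
set_column_map <- function(iface, map) {
  stopifnot(is.numeric(map), !is.null(names(map)))
  iface$msa_column_map <- map
  iface
}

#' Dump an interface as JSON lines
#'
#' One meta line, one line per interface residue record, and one line
#' per residue contact pair with 0-based indices into the residue
#' records.
#'
#' @param iface an interface (core assignment included if present).
#' @param path output file.
#' @param ... passed to [residue_contact_pairs()].
#' @return `path`, invisibly.
#' @export
write_interface <- function(iface, path, ...) {
  rr <- iface$residue_records
  rcp <- residue_contact_pairs(iface, ...)
  con <- file(path, "w"); on.exit(close(con))
  wr <- function(x) writeLines(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                digits = NA, na = "null"), con)
  wr(list(type = "interface",
          query_chain_ids = as.list(iface$query_chain_ids),
          partner_chain_ids = as.list(iface$partner_chain_ids),
          total_bsa = iface$total_bsa,
          is_homomeric = iface$is_homomeric,
          n_contact_atom_pairs = nrow(iface$contact_atom_pairs)))
  for (i in seq_len(nrow(rr)))
    wr(c(list(type = "residue"), as.list(rr[i, , drop = FALSE])))
  key_all <- paste(rr$side, rr$key)
  for (i in seq_len(nrow(rcp)))
    wr(list(type = "contact_pair",
            a = match(paste("query", rcp$key_query[i]), key_all) - 1L,
            b = match(paste("partner", rcp$key_partner[i]), key_all) - 1L,
            min_distance = rcp$min_distance[i]))
  invisible(path)
}

#' Read an interface dump written by [write_interface()]
#'
#' @param path JSON-lines file.
#' @return list with `meta`, `residues` (data frame) and `contact_pairs`
#'   (data frame of 0-based indices).
#' @export
read_interface <- function(path) {
  lines <- readLines(path, warn = FALSE)
  objs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(objs, `[[`, "", "type")
  res <- do.call(rbind, lapply(objs[types == "residue"], function(o)
    as.data.frame(o[setdiff(names(o), "type")], stringsAsFactors = FALSE)))
  cp <- do.call(rbind, lapply(objs[types == "contact_pair"], function(o)
    data.frame(a = o$a, b = o$b, min_distance = o$min_distance)))
  list(meta = objs[[which(types == "interface")[1]]],
       residues = res, contact_pairs = cp)
}

#' Pick the largest interface by total BSA
#'
#' Detects the interface of the query against each candidate partner and
#' returns the one burying the most surface, mirroring the convention of
#' extracting the largest crystal interface per entry.
#'
#' @param query structure.
#' @param partners list of candidate partner structures (e.g. from
#'   [symmetry_mates()]).
#' @param ... passed to [detect_interface()].
#' @return the largest `xtal_interface`, or `NULL` when no partner makes
#'   an interface.
#' @export
largest_interface <- function(query, partners, ...) {
  best <- NULL
  for (p in partners) {
    i <- detect_interface(query, p, ...)
    if (!is.null(i) && (is.null(best) || i$total_bsa > best$total_bsa))
      best <- i
  }
  best
}
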