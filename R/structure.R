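# Structure parsing and crystal symmetry reconstruction.

#' Construct a structure object
#'
#' A structure is an atom table plus optional crystallographic metadata.
#' Columns of `atoms`: `chain`, `resno`, `ins`, `resid` (three-letter),
#' `elety` (atom name), `element`, `x`, `y`, `z`, `occ`.
#'
#' @param atoms data frame of non-hydrogen protein atoms.
#' @param cell numeric length-6 vector (a, b, c in Angstrom; alpha,
#'   beta, gamma in degrees) or `NULL`.
#' @param space_group Hermann-Mauguin symbol or `NULL`.
#' @return an object of class `xtal_structure`.
#' @export
new_structure <- function(atoms, cell = NULL, space_group = NULL) {
  needed <- c("chain", "resno", "ins", "resid", "elety", "element",
              "x", "y", "z", "occ")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stop("atom table misses columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no protein atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$ins[is.na(atoms$ins)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, space_group = space_group),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("<xtal_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(residue_key(x$atoms$chain, x$atoms$resno, x$atoms$ins))),
      " residues, chains: ", paste(ch, collapse = " "), "\n", sep = "")
  if (!is.null(x$space_group))
    cat("  space group ", x$space_group, ", cell ",
        paste(signif(x$cell, 6), collapse = " "), "\n", sep = "")
  invisible(x)
}

# shared post-read clean-up: drop waters/hydrogens/het, resolve altlocs
clean_atoms <- function(at) {
  at <- at[!(toupper(at$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) return(at)
  # altloc: highest occupancy wins, alphabetical tie-break
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(residue_key(at$chain, at$resno, at$ins), at$elety)
  ord <- order(key, -at$occ, alt)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]  # preserve file order
  at$alt <- NULL
  rownames(at) <- NULL
  at
}

#' Read a protein structure from PDB or mmCIF
#'
#' Only the first model is kept.  Waters, hydrogens and heteroatoms are
#' removed; alternate locations are resolved to the highest-occupancy
#' conformer (alphabetical tie-break).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return an [new_structure()] object carrying cell and space group
#'   when the file states them.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure: no ATOM records")
  el <- toupper(trimws(a$elesy %||% ""))
  el[is.na(el) | el == ""] <- guess_element(a$elety[is.na(el) | el == ""])
  at <- data.frame(chain = as.character(a$chain),
                   resno = as.integer(a$resno),
                   ins = ifelse(is.na(a$insert), "", as.character(a$insert)),
                   resid = toupper(a$resid),
                   elety = toupper(a$elety),
                   element = el,
                   x = a$x, y = a$y, z = a$z,
                   occ = ifelse(is.na(a$o), 1, a$o),
                   alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
                   stringsAsFactors = FALSE)
  at <- clean_atoms(at)
  if (nrow(at) == 0L) stop("empty structure after filtering")
  cell <- NULL; sg <- NULL
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                         substr(cr, 25, 33), substr(cr, 34, 40),
                         substr(cr, 41, 47), substr(cr, 48, 54)))
    sg <- trimws(substr(cr, 56, 66))
    if (!all(is.finite(cell))) cell <- NULL
    if (!is.null(sg) && !nzchar(sg)) sg <- NULL
  }
  new_structure(at, cell = cell, space_group = sg)
}

# minimal mmCIF reader: _atom_site loop plus cell/symmetry items.  No
# installed R package reads mmCIF, so the loop grammar is handled here
# (quoted tokens via scan()).
read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  item <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    v <- scan(text = ln[1], what = character(), quiet = TRUE,
              quote = "'\"")[2]
    if (is.na(v) || v %in% c(".", "?")) NULL else v
  }
  # locate the atom_site loop
  loop_starts <- grep("^loop_", lines)
  at <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_atom_site\\.", tags))) next
    rows <- character()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
      rows <- c(rows, l); i <- i + 1L
    }
    tok <- scan(text = rows, what = character(), quiet = TRUE, quote = "'\"")
    if (length(tok) %% length(tags) != 0L)
      stop("cannot parse mmCIF _atom_site loop: ragged token count")
    m <- matrix(tok, ncol = length(tags), byrow = TRUE)
    colnames(m) <- sub("^_atom_site\\.", "", tags)
    g <- function(nm, alt = NULL) {
      if (nm %in% colnames(m)) m[, nm]
      else if (!is.null(alt) && alt %in% colnames(m)) m[, alt]
      else rep(NA_character_, nrow(m))
    }
    model <- g("pdbx_PDB_model_num")
    keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1]
    m <- m[keep, , drop = FALSE]
    grp <- g("group_PDB")
    m <- m[is.na(grp[keep]) | grp[keep] == "ATOM", , drop = FALSE]
    if (nrow(m) == 0L) stop("empty structure: no ATOM records in mmCIF")
    g2 <- function(nm, alt = NULL) {
      v <- if (nm %in% colnames(m)) m[, nm]
      else if (!is.null(alt) && alt %in% colnames(m)) m[, alt]
      else rep(NA_character_, nrow(m))
      v[v %in% c(".", "?")] <- NA_character_
      v
    }
    el <- toupper(g2("type_symbol"))
    ety <- toupper(g2("auth_atom_id", "label_atom_id"))
    el[is.na(el)] <- guess_element(ety[is.na(el)])
    occ <- suppressWarnings(as.numeric(g2("occupancy")))
    at <- data.frame(chain = g2("auth_asym_id", "label_asym_id"),
                     resno = as.integer(g2("auth_seq_id", "label_seq_id")),
                     ins = ifelse(is.na(g2("pdbx_PDB_ins_code")), "",
                                  g2("pdbx_PDB_ins_code")),
                     resid = toupper(g2("auth_comp_id", "label_comp_id")),
                     elety = ety, element = el,
                     x = as.numeric(g2("Cartn_x")),
                     y = as.numeric(g2("Cartn_y")),
                     z = as.numeric(g2("Cartn_z")),
                     occ = ifelse(is.na(occ), 1, occ),
                     alt = ifelse(is.na(g2("label_alt_id")), "",
                                  g2("label_alt_id")),
                     stringsAsFactors = FALSE)
    break
  }
  if (is.null(at)) stop("cannot parse mmCIF file: no _atom_site loop")
  at <- clean_atoms(at)
  if (nrow(at) == 0L) stop("empty structure after filtering")
  cell <- suppressWarnings(as.numeric(c(
    item("_cell.length_a"), item("_cell.length_b"), item("_cell.length_c"),
    item("_cell.angle_alpha"), item("_cell.angle_beta"),
    item("_cell.angle_gamma"))))
  if (length(cell) != 6L || !all(is.finite(cell))) cell <- NULL
  sg <- item("_symmetry.space_group_name_H-M") %||%
    item("_space_group.name_H-M_alt")
  new_structure(at, cell = cell, space_group = sg)
}

#' One-letter sequence of a chain
#'
#' @param s a structure.
#' @param chain chain identifier (default: first chain).
#' @return character scalar; unknown residues become `X`.
#' @export
chain_sequence <- function(s, chain = NULL) {
  at <- s$atoms
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  key <- residue_key(at$chain, at$resno, at$ins)
  res <- at$resid[!duplicated(key)]
  aa <- aa_three_to_one(res)
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# ---- crystal symmetry ------------------------------------------------

# orthogonalisation matrix (fractional -> cartesian), PDB convention
frac_to_orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

# parse an xyz triplet like "-y,x-y,z+1/3" into (R, t)
parse_triplet <- function(trip) {
  comps <- strsplit(trip, ",", fixed = TRUE)[[1]]
  if (length(comps) != 3L) stop("bad symmetry triplet: ", trip)
  if (any(grepl("[^xyzXYZ0-9+/ .*-]", comps)))
    stop("bad symmetry triplet: ", trip)
  evalc <- function(e, x, y, z)
    eval(parse(text = e), list(x = x, y = y, z = z))
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (k in 1:3) {
    e <- tolower(comps[k])
    t[k] <- evalc(e, 0, 0, 0)
    R[k, 1] <- evalc(e, 1, 0, 0) - t[k]
    R[k, 2] <- evalc(e, 0, 1, 0) - t[k]
    R[k, 3] <- evalc(e, 0, 0, 1) - t[k]
  }
  list(R = R, t = t)
}

#' Space-group symmetry operators
#'
#' Operators (including centring translations) for the 65 Sohncke space
#' groups in which chiral macromolecules crystallise, from a shipped
#' table of general-position triplets.
#'
#' @param symbol Hermann-Mauguin symbol (spacing-insensitive, e.g.
#'   `"P 21 21 21"` or `"P212121"`).
#' @return list of operators, each `list(R = 3x3, t = length-3)` acting
#'   on fractional coordinates.
#' @export
spacegroup_operators <- function(symbol) {
  tab <- read.table(extdata_path("spacegroups_sohncke.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  norm <- function(x) gsub("[ _]", "", toupper(x))
  hit <- which(norm(tab$hm) == norm(symbol))
  if (!length(hit)) {
    # PDB style "P 1 21 1" vs table "P 1 21 1" should match; also try
    # dropping explicit "1" axes: "P 1 21 1" -> "P 21"
    alt <- gsub("\\b1\\b", "", symbol)
    hit <- which(norm(tab$hm) == norm(alt))
  }
  if (!length(hit))
    stop("unknown space group symbol '", symbol,
         "'; supply pre-generated partner structures instead")
  trips <- strsplit(tab$operators[hit[1]], ";", fixed = TRUE)[[1]]
  lapply(trips, parse_triplet)
}

#' Reconstruct contacting crystal symmetry mates
#'
#' Applies every space-group operator combined with lattice translations
#' in the 3x3x3 neighbourhood and keeps the copies having at least one
#' atom within `contact_cutoff` of the query.  The identity copy is
#' excluded.
#'
#' @param s structure with `cell` and `space_group` set.
#' @param contact_cutoff Angstrom; default is the 5.5 A interface
#'   distance plus a 1 A margin.
#' @return list of transformed `xtal_structure` copies; each carries a
#'   `symmetry_op` attribute describing its operator and translation.
#' @export
symmetry_mates <- function(s, contact_cutoff = 6.5) {
  if (is.null(s$cell) || is.null(s$space_group))
    stop("structure has no cell/space group; ",
         "supply a pre-generated partner structure instead")
  ops <- spacegroup_operators(s$space_group)
  M <- frac_to_orth_matrix(s$cell)
  Minv <- solve(M)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  frac <- xyz %*% t(Minv)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  mates <- list()
  for (op in ops) {
    f1 <- frac %*% t(op$R)
    for (si in seq_len(nrow(shifts))) {
      tvec <- op$t + as.numeric(shifts[si, ])
      ident <- all(abs(op$R - diag(3)) < 1e-9) && all(abs(tvec) < 1e-9)
      if (ident) next
      f2 <- sweep(f1, 2, tvec, "+")
      cart <- f2 %*% t(M)
      # cheap bounding-box rejection before the pair scan
      if (any(apply(cart, 2, min) > apply(xyz, 2, max) + contact_cutoff) ||
          any(apply(cart, 2, max) < apply(xyz, 2, min) - contact_cutoff))
        next
      d2min <- min_sq_dist(xyz, cart)
      if (d2min < contact_cutoff^2) {
        m <- s
        m$atoms[, c("x", "y", "z")] <- cart
        attr(m, "symmetry_op") <- list(R = op$R, t = tvec)
        mates[[length(mates) + 1L]] <- m
      }
    }
  }
  mates
}

# minimum squared distance between two coordinate sets
min_sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

#' Write a structure as a minimal PDB file
#'
#' Emits ATOM records (and a CRYST1 record when cell information is
#' present) so synthetic fixtures exercise the real parser.
#'
#' @param s structure.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  lines <- character()
  if (!is.null(s$cell)) {
    sg <- s$space_group %||% "P 1"
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                     s$cell[1], s$cell[2], s$cell[3],
                     s$cell[4], s$cell[5], s$cell[6], sg)
  }
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  rec <- sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(at)), name4, at$resid,
                 substr(at$chain, 1, 1), at$resno,
                 ifelse(at$ins == "", " ", at$ins),
                 at$x, at$y, at$z, at$occ, 0, at$element)
  writeLines(c(lines, rec, "END"), path)
  invisible(path)
}
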