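# Shared constants and small helpers.

# 20 standard residues, alphabetical one-letter order; gap is state 21.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP <- "-"
STATES <- c(AA1, GAP)
N_STATES <- 21L

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Convert three-letter residue names to one-letter codes
#'
#' Unknown names map to `NA`.
#'
#' @param resid character vector of three-letter residue names.
#' @return character vector of one-letter codes.
#' @export
aa_three_to_one <- function(resid) {
  unname(AA3[toupper(resid)])
}

# residue key unique within a structure: chain|resno|ins
residue_key <- function(chain, resno, ins) {
  ins <- ifelse(is.na(ins) | ins == "", ".", ins)
  paste(chain, resno, ins, sep = "|")
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "xtalface")
  if (!nzchar(p)) stop("missing installed config file: ", file)
  p
}

#' Van der Waals radii table
#'
#' Element-based Bondi radii used for SASA and occlusion geometry,
#' shipped as a plain key-value config file.
#'
#' @param path optional path to a custom two-column (`element`,
#'   `radius`) TSV; defaults to the shipped Bondi set.
#' @return named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("vdw_bondi.tsv")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(tab$radius, toupper(tab$element))
}

#' Reference maximal SASA per residue type
#'
#' Theoretical maximum solvent accessibilities (Tien et al. 2013) used
#' to turn absolute SASA into relative SASA.  All 20 standard residues
#' are present; values are in square Angstrom.
#'
#' @param path optional path to a custom table (`resid`, `aa`,
#'   `max_sasa` TSV).
#' @return named numeric vector keyed by three-letter residue name.
#' @export
max_sasa_table <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("max_sasa_tien2013.tsv")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, all(tab$max_sasa > 0))
  setNames(tab$max_sasa, toupper(tab$resid))
}

#' Deterministic golden-spiral sphere points
#'
#' Fibonacci-lattice directions on the unit sphere.  Deterministic, so
#' SASA is reproducible bit-for-bit at fixed `n`.
#'
#' @param n number of points (>= 1).
#' @return an `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# guess the chemical element from a PDB atom name
guess_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  el <- substr(nm, 1, 1)
  el[startsWith(nm, "SE")] <- "SE"
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a
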