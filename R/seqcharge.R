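#' @title Residue sequences, charge sequences, and electroneutrality
#' @name seqcharge
#' @description
#' Sequences are handled as lightweight S3 objects. A `ResidueSequence` holds
#' one-letter residue codes plus optional phospho-tyrosine (pY) marks; a
#' `ChargeSequence` holds the per-residue integer charges `sigma` derived from
#' it at pH 7.4 (R,K = +1; D,E = -1; pY = -2; everything else, including
#' histidine and the chain termini of an internal IDR fragment, = 0).
NULL

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# average residue masses (Da; residue = amino acid - water)
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.MASS_WATER <- 18.0153
.MASS_PHOSPHO <- 79.9799  # HPO3 adduct on pY

#' Parse a residue sequence
#'
#' Accepts either a raw one-letter amino-acid string or FASTA-formatted text
#' (first record used unless `record` names one). Phospho-tyrosine sites can be
#' given as 1-based positions via `ptm`, or inline by writing the tyrosine as a
#' lowercase `"y"` (the package's FASTA dialect for PTMs); all other letters are
#' case-insensitive.
#'
#' @param text character: raw sequence or FASTA text (possibly multi-line).
#' @param ptm integer vector of 1-based phospho-tyrosine positions (optional).
#' @param name label for the sequence; defaults to the FASTA header or `"seq"`.
#' @param record for multi-record FASTA text, the name of the record to use.
#' @return A `ResidueSequence`: list with `name`, `residues` (uppercase
#'   one-letter codes) and `ptm` (logical, `TRUE` at pY sites).
#' @examples
#' parse_sequence("RKD")
#' parse_sequence("GYG", ptm = 2)
#' @export
parse_sequence <- function(text, ptm = integer(), name = NULL, record = NULL) {
  stopifnot(is.character(text), length(text) >= 1L)
  text <- paste(text, collapse = "\n")
  if (!nzchar(gsub("\\s", "", text))) stop("empty sequence text")
  if (grepl("^\\s*>", text)) {
    rec <- .parse_fasta_text(text)
    idx <- 1L
    if (!is.null(record)) {
      idx <- match(record, names(rec))
      if (is.na(idx)) stop("FASTA record not found: ", record)
    }
    if (is.null(name)) name <- names(rec)[idx]
    text <- rec[[idx]]
  }
  if (is.null(name)) name <- "seq"
  raw <- strsplit(gsub("\\s", "", text), "")[[1]]
  if (length(raw) < 1L) stop("empty sequence")
  inline_py <- which(raw == "y")
  residues <- toupper(raw)
  bad <- setdiff(unique(residues), .AA20)
  if (length(bad)) stop("invalid residue code(s): ", paste(bad, collapse = ","))
  ptm <- sort(unique(c(as.integer(ptm), inline_py)))
  if (length(ptm)) {
    if (any(ptm < 1L | ptm > length(residues)))
      stop("PTM position out of range")
    if (any(residues[ptm] != "Y"))
      stop("PTM position(s) not tyrosine: ",
           paste(ptm[residues[ptm] != "Y"], collapse = ","))
  }
  ptm_mask <- rep(FALSE, length(residues))
  ptm_mask[ptm] <- TRUE
  structure(list(name = name, residues = residues, ptm = ptm_mask),
            class = "ResidueSequence")
}

# minimal FASTA text splitter (records as named character vector)
.parse_fasta_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr <- grep("^\\s*>", lines)
  if (!length(hdr)) stop("no FASTA header found")
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
  }, character(1))
  names(seqs) <- sub("^\\s*>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs
}

#' Read a sequence from a FASTA file
#'
#' Multi-record files are supported; the first record is used unless `record`
#' names one. Lowercase `"y"` marks phospho-tyrosine inline; alternatively a
#' JSON side-channel file (a bare array of 1-based positions) can be given.
#'
#' @param path FASTA file path.
#' @param ptm_json optional path to a JSON array of 1-based pY positions.
#' @inheritParams parse_sequence
#' @return A `ResidueSequence`.
#' @export
read_fasta_sequence <- function(path, record = NULL, ptm_json = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  ptm <- integer()
  if (!is.null(ptm_json)) ptm <- as.integer(jsonlite::fromJSON(ptm_json))
  parse_sequence(txt, ptm = ptm, record = record)
}

#' @export
print.ResidueSequence <- function(x, ...) {
  cat("ResidueSequence", x$name, ":", length(x$residues), "residues,",
      sum(x$ptm), "pY\n")
  invisible(x)
}

#' @export
length.ResidueSequence <- function(x) length(x$residues)

#' Built-in sequence fixtures
#'
#' Returns one of the package's built-in IDR sequences by label:
#' `"caprin1_wt"`, `"py_caprin1"` (all 7 tyrosines phosphorylated),
#' `"15Rto15K"`, `"4Rto4K_N"`, `"4Rto4K_M"`, `"4Rto4K_C"`.
#'
#' The 103-residue Caprin1-like fixture is a SYNTHETIC stand-in: the literal
#' construct sequence is not redistributed here, so the fixture reproduces the
#' published composition of the Caprin1 C-terminal IDR (103 residues; 15 R, 1 K,
#' 3 D, 7 Y; net charge +13) and its coarse charge patterning (arginine-rich
#' N-terminal and pre-C-terminal regions), with a low-complexity G/S/Q/N/P/A
#' background. All charge-level results (Q, NCPR, FCR, electroneutrality) are
#' exact for the real construct; residue-identity-level results are
#' qualitative.
#'
#' @param label fixture name (see Details).
#' @return A `ResidueSequence`.
#' @examples
#' sequence_metrics(charge_sequence(builtin_sequence("caprin1_wt")))
#' @export
builtin_sequence <- function(label = c("caprin1_wt", "py_caprin1", "15Rto15K",
                                       "4Rto4K_N", "4Rto4K_M", "4Rto4K_C")) {
  label <- match.arg(label)
  wt <- paste0("GSRNPAGRQNPRGSQNRAGSRNPARSQNPYGSDNPAGYQNPRGSYNPRGDQNPARSQYPA",
               "RSQNPADSQYPAGSQRPAGRQNPRGYQRPAGRQNPAKSYNPAG")
  y_pos <- c(30, 38, 45, 58, 70, 86, 99)
  r_pos <- c(3, 8, 12, 17, 21, 25, 42, 48, 55, 61, 76, 80, 84, 88, 92)
  seq_wt <- parse_sequence(wt, name = "caprin1_wt")
  switch(label,
    caprin1_wt = seq_wt,
    py_caprin1 = {
      s <- parse_sequence(wt, ptm = y_pos, name = "py_caprin1")
      s
    },
    `15Rto15K` = make_variant(seq_wt, cbind(r_pos, "K"), name = "15Rto15K"),
    `4Rto4K_N` = make_variant(seq_wt, cbind(r_pos[1:4], "K"), name = "4Rto4K_N"),
    `4Rto4K_M` = make_variant(seq_wt, cbind(r_pos[7:10], "K"), name = "4Rto4K_M"),
    `4Rto4K_C` = make_variant(seq_wt, cbind(r_pos[12:15], "K"), name = "4Rto4K_C"))
}

#' Substitute residues in a sequence
#'
#' @param seq a `ResidueSequence`.
#' @param substitutions two-column matrix or data.frame: 1-based position and
#'   new one-letter residue code. For the package's RtoK fixtures the original
#'   residue at each position must be arginine; generally the position must
#'   hold a valid residue and the new code must be one of the 20 standard ones.
#' @param expect_original optional character vector: if given, the residue
#'   currently at each position must equal it (error otherwise). Defaults to
#'   no check when `NULL`; the RtoK constructors pass `"R"`.
#' @param name label for the variant.
#' @return A `ResidueSequence`.
#' @export
make_variant <- function(seq, substitutions, expect_original = NULL,
                         name = paste0(seq$name, "_variant")) {
  stopifnot(inherits(seq, "ResidueSequence"))
  if (is.null(dim(substitutions)))
    substitutions <- matrix(substitutions, ncol = 2)
  res <- seq$residues
  if (nrow(substitutions) > 0) {
    pos <- as.integer(substitutions[, 1])
    new <- toupper(as.character(substitutions[, 2]))
    if (any(pos < 1L | pos > length(res))) stop("substitution position out of range")
    if (!all(new %in% .AA20)) stop("invalid replacement residue code")
    if (!is.null(expect_original) && !all(res[pos] == toupper(expect_original)))
      stop("original-residue mismatch at substitution site(s): ",
           paste(pos[res[pos] != toupper(expect_original)], collapse = ","))
    if (any(seq$ptm[pos] & new != "Y")) stop("substitution would remove a pY site")
    res[pos] <- new
  }
  structure(list(name = name, residues = res, ptm = seq$ptm),
            class = "ResidueSequence")
}

#' Map a residue sequence to a charge sequence
#'
#' At pH 7.4: R,K carry +1; D,E carry -1; phospho-tyrosine carries `py_charge`
#' (default -2); all other residues -- including histidine at neutral pH and
#' the uncharged termini of an internal IDR fragment -- carry 0.
#'
#' @param seq a `ResidueSequence`.
#' @param ph solution pH; only 7.4-style assignments are implemented (no
#'   titration model), the argument is recorded for bookkeeping.
#' @param py_charge charge assigned to each phospho-tyrosine (default -2).
#' @return A `ChargeSequence`: list with `sigma` (integer vector), `Q`
#'   (total charge), `N` (length), and the originating sequence `name`.
#' @examples
#' charge_sequence(builtin_sequence("caprin1_wt"))$Q  # +13
#' @export
charge_sequence <- function(seq, ph = 7.4, py_charge = -2) {
  stopifnot(inherits(seq, "ResidueSequence"))
  sigma <- rep(0, length(seq$residues))
  sigma[seq$residues %in% c("R", "K")] <- 1
  sigma[seq$residues %in% c("D", "E")] <- -1
  sigma[seq$ptm] <- py_charge
  structure(list(sigma = sigma, Q = sum(sigma), N = length(sigma),
                 name = seq$name),
            class = "ChargeSequence")
}

#' @export
print.ChargeSequence <- function(x, ...) {
  cat("ChargeSequence", x$name, ": N =", x$N, ", Q =", x$Q, "\n")
  invisible(x)
}

#' Charge metrics of a sequence
#'
#' @param cs a `ChargeSequence`.
#' @return list with `Q` (net charge), `NCPR` (net charge per residue, Q/N)
#'   and `FCR` (fraction of charged residues).
#' @examples
#' sequence_metrics(charge_sequence(builtin_sequence("caprin1_wt")))
#' @export
sequence_metrics <- function(cs) {
  stopifnot(inherits(cs, "ChargeSequence"), cs$N >= 1)
  list(Q = cs$Q, NCPR = cs$Q / cs$N, FCR = sum(cs$sigma != 0) / cs$N)
}

#' Counterion concentration required for electroneutrality
#'
#' Overall electric neutrality of a solution of polymers with net charge `Q`,
#' salt ions of valency `zs` and counterions of valency `zc` requires
#' `|Q| rho_p + zs rho_s = zc rho_c`. The same relation holds in count form
#' for a simulation box (`n_c = (|Q| n_chains + zs n_s) / zc`).
#'
#' @param Q polymer net charge per chain (signed; only `|Q|` enters).
#' @param rho_p polymer concentration (or chain count).
#' @param zs,zc salt/counterion valencies (positive integers).
#' @param rho_s salt concentration (or ion count), default 0.
#' @param count logical: if `TRUE`, inputs are integer counts and a
#'   non-integer counterion count is an error (inconsistent discrete system).
#' @return counterion concentration (or count) `rho_c`.
#' @examples
#' neutralize(13, 100, zc = 1, count = TRUE)  # 1300
#' @export
neutralize <- function(Q, rho_p, zs = 1, zc = 1, rho_s = 0, count = FALSE) {
  stopifnot(zs >= 1, zc >= 1, all(rho_p >= 0), all(rho_s >= 0))
  rho_c <- (abs(Q) * rho_p + zs * rho_s) / zc
  if (count && any(abs(rho_c - round(rho_c)) > 1e-9))
    stop("non-integer counterion count: inconsistent discrete system")
  if (count) rho_c <- round(rho_c)
  rho_c
}

#' Sequence molar mass
#'
#' Average molar mass (Da) from residue composition, including one water for
#' the chain and one HPO3 per phospho-tyrosine.
#'
#' @param seq a `ResidueSequence`.
#' @return molar mass in g/mol.
#' @export
sequence_molar_mass <- function(seq) {
  stopifnot(inherits(seq, "ResidueSequence"))
  sum(.AA_MASS[seq$residues]) + .MASS_WATER + sum(seq$ptm) * .MASS_PHOSPHO
}

#' Ion species descriptor
#'
#' @param label species name.
#' @param bead_charges per-bead charge vector (length 1 for simple ions, 6 for
#'   the ATP-Mg chain model).
#' @param role `"counterion"` or `"salt"`; by convention counterions are the
#'   small ions whose charge is opposite in sign to the polymer net charge.
#' @return an `IonSpecies` list with `label`, `valency` (sum of bead charges),
#'   `bead_charges`, `role`.
#' @examples
#' ion_species("ATP-Mg", c(-1, -1, -1, -1, 1, 1), "counterion")  # valency -2
#' @export
ion_species <- function(label, bead_charges, role = c("counterion", "salt")) {
  role <- match.arg(role)
  structure(list(label = label, valency = sum(bead_charges),
                 bead_charges = as.numeric(bead_charges), role = role),
            class = "IonSpecies")
}

#' Unit conversions for concentrations
#'
#' Convert between molar (mol/L), number density in units of `b^-3`
#' (`b` = 3.8 Angstrom peptide virtual bond length), and mg/ml (mass density,
#' requires the species molar mass).
#'
#' @param x numeric concentrations.
#' @param from,to one of `"M"`, `"b-3"`, `"mg/ml"`, `"uM"`, `"mM"`.
#' @param molar_mass g/mol, needed to or from `"mg/ml"`.
#' @return converted numeric vector.
#' @export
convert_conc <- function(x, from, to, molar_mass = NULL) {
  b3_per_L <- 1e27 / .const$b_A^3   # number of b^3 volumes per litre
  to_M <- function(v, u) switch(u,
    "M" = v, "mM" = v / 1e3, "uM" = v / 1e6,
    "b-3" = v * b3_per_L / .const$N_A,
    "mg/ml" = {
      if (is.null(molar_mass)) stop("molar_mass required for mg/ml")
      v / molar_mass  # (g/L)/(g/mol) = mol/L
    },
    stop("unknown unit: ", u))
  from_M <- function(v, u) switch(u,
    "M" = v, "mM" = v * 1e3, "uM" = v * 1e6,
    "b-3" = v * .const$N_A / b3_per_L,
    "mg/ml" = {
      if (is.null(molar_mass)) stop("molar_mass required for mg/ml")
      v * molar_mass
    },
    stop("unknown unit: ", u))
  from_M(to_M(x, from), to)
}
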