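# Atom-level structure container and PDB-format input/output.
#
# A `zipper_structure` is a flat atom table (one row per atom) with the
# attributes `sheet_assignment` (named character vector, chain id -> "A"/"B")
# and `metadata` (free-form list).  The flat layout keeps all energy
# computations vectorizable.

.STRUCT_COLS <- c("chain", "resno", "resid3", "aa", "atom", "element",
                  "x", "y", "z", "occ", "het")

#' Construct a zipper structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid3`, `aa`,
#'   `atom`, `element`, `x`, `y`, `z`, `occ`, `het`.
#' @param sheet_assignment optional named character vector mapping chain ids
#'   to sheet labels `"A"`/`"B"`.
#' @param metadata free-form list.
#' @return object of class `zipper_structure`.
#' @keywords internal
new_structure <- function(atoms, sheet_assignment = NULL, metadata = list()) {
  stopifnot(is.data.frame(atoms), all(.STRUCT_COLS %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (!is.null(sheet_assignment)) {
    missing_chains <- setdiff(names(sheet_assignment), unique(atoms$chain))
    if (length(missing_chains) > 0) {
      stop("sheet_assignment refers to absent chains: ",
           paste(missing_chains, collapse = ", "))
    }
  }
  rownames(atoms) <- NULL
  structure(atoms[.STRUCT_COLS],
            sheet_assignment = sheet_assignment,
            metadata = metadata,
            class = c("zipper_structure", "data.frame"))
}

#' @export
print.zipper_structure <- function(x, ...) {
  ch <- unique(x$chain)
  nres <- nrow(unique(x[, c("chain", "resno")]))
  cat("zipper_structure: ", length(ch), " chain(s), ", nres, " residue(s), ",
      nrow(x), " atoms\n", sep = "")
  sheets <- attr(x, "sheet_assignment")
  if (!is.null(sheets)) {
    for (s in sort(unique(sheets))) {
      cat("  sheet ", s, ": ",
          paste(names(sheets)[sheets == s], collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

# residue table (one row per residue, file order preserved)
.residues <- function(s) {
  key <- paste(s$chain, s$resno, sep = "\r")
  idx <- !duplicated(key)
  data.frame(chain = s$chain[idx], resno = s$resno[idx],
             resid3 = s$resid3[idx], aa = s$aa[idx], het = s$het[idx],
             stringsAsFactors = FALSE)
}

.chain_sequences <- function(s) {
  r <- .residues(s)
  vapply(split(r$aa, factor(r$chain, levels = unique(r$chain))),
         paste, character(1), collapse = "")
}

#' Read a PDB file into a zipper structure
#'
#' Parses fixed-column PDB v3.3 `ATOM`/`HETATM` records (via bio3d), keeping
#' blank and `'A'` alternate-location indicators and flagging `HETATM` rows.
#' Atom order, residue order and chain order follow the file.
#'
#' @param path path to a PDB file.
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM or HETATM records in ", path)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("format error at line ", i, ": record too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) stop("format error at line ", i, ": bad coordinates")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = TRUE)
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", " ", "A")
  a <- a[keep, , drop = FALSE]
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  element <- ifelse(!is.na(elesy) & nzchar(trimws(elesy)),
                    trimws(elesy),
                    toupper(substr(gsub("[^A-Za-z].*", "", trimws(a$elety)), 1, 1)))
  aa <- unname(.AA_FROM3[a$resid])
  new_structure(data.frame(
    chain = chain, resno = a$resno, resid3 = a$resid, aa = aa,
    atom = trimws(a$elety), element = element,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), het = a$type == "HETATM",
    stringsAsFactors = FALSE
  ), metadata = list(source = path))
}

#' Write a zipper structure as a PDB file
#'
#' Emits fixed-column `ATOM`/`HETATM` records with `TER` separators between
#' chains and coordinates rounded to three decimals.
#'
#' @param s a `zipper_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "zipper_structure"))
  resid3 <- ifelse(!is.na(s$aa), unname(.AA3[s$aa]), s$resid3)
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = ifelse(s$het, "HETATM", "ATOM"),
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$resno, resid = resid3, chain = s$chain,
    elety = s$atom, eleno = seq_len(nrow(s)),
    o = s$occ, b = rep(0, nrow(s)), elesy = s$element,
    chainter = TRUE, end = TRUE, verbose = FALSE
  )
  invisible(path)
}

#' Remove all non-protein content from a structure
#'
#' Drops every `HETATM` residue (waters, ions, crystallization additives) and
#' every residue whose identity is not one of the 20 standard amino acids;
#' chains left empty are removed.  Idempotent.
#'
#' @param s a `zipper_structure`.
#' @return the sanitized structure.
#' @export
strip_nonprotein <- function(s) {
  stopifnot(inherits(s, "zipper_structure"))
  keep <- !s$het & !is.na(s$aa) & s$aa %in% .AA1
  if (!any(keep)) stop("empty structure: no standard protein residues remain")
  out <- as.data.frame(s)[keep, , drop = FALSE]
  sheets <- attr(s, "sheet_assignment")
  if (!is.null(sheets)) sheets <- sheets[names(sheets) %in% unique(out$chain)]
  new_structure(out, sheet_assignment = sheets, metadata = attr(s, "metadata"))
}

.CHAIN_ID_POOL <- c(LETTERS, letters, as.character(0:9))

#' Pad each beta sheet to a target strand count by translated chain copies
#'
#' Each sheet's terminal chain is copied and translated by successive integer
#' multiples of that sheet's translation vector until the sheet holds
#' `target_per_sheet` chains.  New chain ids continue alphabetically from the
#' last used id, deterministically.
#'
#' @param s a `zipper_structure` with a sheet assignment.
#' @param target_per_sheet desired chains per sheet (must be >= current count).
#' @param translation either a single 3-vector (Angstrom) applied to both
#'   sheets, or a list with elements `A` and `B`.
#' @return the padded structure.
#' @export
replicate_chains <- function(s, target_per_sheet, translation) {
  stopifnot(inherits(s, "zipper_structure"))
  sheets <- attr(s, "sheet_assignment")
  if (is.null(sheets)) stop("structure has no sheet_assignment")
  if (!is.list(translation)) translation <- list(A = translation, B = translation)
  atoms <- as.data.frame(s)
  used <- unique(atoms$chain)
  pool <- setdiff(.CHAIN_ID_POOL, used)
  for (sheet in sort(unique(sheets))) {
    chains <- names(sheets)[sheets == sheet]
    if (length(chains) < 1) stop("sheet ", sheet, " has no chains")
    if (target_per_sheet < length(chains)) {
      stop("target_per_sheet (", target_per_sheet,
           ") is below the current count (", length(chains), ")")
    }
    n_new <- target_per_sheet - length(chains)
    if (n_new == 0) next
    vec <- translation[[sheet]]
    if (is.null(vec) || length(vec) != 3) {
      stop("no 3-vector translation supplied for sheet ", sheet)
    }
    terminal <- atoms[atoms$chain == chains[length(chains)], , drop = FALSE]
    for (k in seq_len(n_new)) {
      copy <- terminal
      copy$chain <- pool[1]
      pool <- pool[-1]
      copy$x <- copy$x + k * vec[1]
      copy$y <- copy$y + k * vec[2]
      copy$z <- copy$z + k * vec[3]
      atoms <- rbind(atoms, copy)
      sheets[copy$chain[1]] <- sheet
    }
  }
  new_structure(atoms, sheet_assignment = sheets, metadata = attr(s, "metadata"))
}
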