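#' @title Atomic models
#' @description An atomic model is an ordered table of atoms (element, name,
#'   residue, chain, Cartesian position in angstrom, isotropic B in square
#'   angstrom, occupancy) together with a [unit_cell()] and a space-group
#'   symbol ("P 1" or "P 21 21 21"). Models are the input to structure-factor
#'   calculation and to all geometry metrics.
#' @name atomic_model
NULL

KNOWN_ELEMENTS <- c("H", "C", "N", "O", "S", "FE", "P")

#' Construct an atomic model
#'
#' @param atoms data.frame with columns `element`, `name`, `resname`, `resno`,
#'   `chain`, `x`, `y`, `z`, `b`, `occ` (Cartesian angstrom, B in A^2).
#' @param cell A [unit_cell()].
#' @param spacegroup Space-group symbol; `"P 1"` (default) or `"P 21 21 21"`.
#' @return Object of class `xtal_model`.
#' @export
atomic_model <- function(atoms, cell, spacegroup = "P 1") {
  required <- c("element", "name", "resname", "resno", "chain",
                "x", "y", "z", "b", "occ")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is_unit_cell(cell)) stop("cell must be a unit_cell")
  atoms <- as.data.frame(atoms)[required]
  atoms$element <- toupper(atoms$element)
  bad <- setdiff(unique(atoms$element), KNOWN_ELEMENTS)
  if (length(bad)) {
    stop("unknown element(s) without tabulated scattering factors: ",
         paste(bad, collapse = ", "))
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0)) stop("B factors must be >= 0")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, spacegroup = spacegroup),
            class = "xtal_model")
}

#' @export
print.xtal_model <- function(x, ...) {
  cat(sprintf("atomic model: %d atoms, space group %s\n",
              nrow(x$atoms), x$spacegroup))
  print(x$cell)
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

#' Cartesian coordinates of a model's atoms
#'
#' @param model An `xtal_model`.
#' @return Numeric matrix (n x 3) in angstrom.
#' @export
coords <- function(model) as.matrix(model$atoms[c("x", "y", "z")])

`coords<-` <- function(model, value) {
  model$atoms[c("x", "y", "z")] <- value
  model
}

# element from the PDB element columns (77-78) or, failing that, the atom name:
# leading digits stripped, two-letter symbols recognised before one-letter
infer_element <- function(element_field, name) {
  el <- toupper(trimws(element_field))
  if (nzchar(el) && el %in% KNOWN_ELEMENTS) return(el)
  if (nzchar(el) && !el %in% KNOWN_ELEMENTS) return(el)  # reported by caller
  nm <- gsub("[^A-Za-z]", "", toupper(name))
  if (!nzchar(nm)) return("")
  two <- substr(nm, 1, 2)
  if (two %in% KNOWN_ELEMENTS) return(two)
  substr(nm, 1, 1)
}

#' Read an atomic model from PDB text
#'
#' Parses the fixed-column ATOM/HETATM and CRYST1 records of a PDB file.
#' All other record types are ignored (their count is reported via a message).
#' Alternate locations: altloc blank or `"A"` kept, others dropped with a
#' warning, so a single conformer reaches the map pipeline.
#'
#' @param path Path to a PDB file, or `text =` a character vector of lines.
#' @param text Optional character vector of PDB lines (overrides `path`).
#' @param cell Optional [unit_cell()] used when no CRYST1 record is present.
#' @return An `xtal_model`.
#' @export
read_model <- function(path = NULL, text = NULL, cell = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_cryst <- startsWith(rec, "CRYST1")
  n_other <- sum(!is_atom & !is_cryst & !startsWith(rec, "END") & nzchar(trimws(lines)))
  if (n_other > 0) message(n_other, " non-coordinate PDB record(s) ignored")

  spacegroup <- "P 1"
  if (any(is_cryst)) {
    cl <- lines[which(is_cryst)[1]]
    nums <- suppressWarnings(as.numeric(c(
      substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
      substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54))))
    if (any(is.na(nums))) stop("malformed CRYST1 record: ", trimws(cl))
    cell <- unit_cell(nums[1], nums[2], nums[3], nums[4], nums[5], nums[6])
    sg <- trimws(substr(cl, 56, 66))
    if (nzchar(sg)) spacegroup <- sg
  }
  al <- lines[is_atom]
  if (!length(al)) stop("no ATOM/HETATM records found")
  if (is.null(cell)) stop("no CRYST1 record and no cell supplied")

  altloc <- substr(al, 17, 17)
  drop <- !(altloc %in% c(" ", "", "A"))
  if (any(drop)) {
    warning(sum(drop), " alternate-location atom(s) dropped (altloc not blank/'A')")
    al <- al[!drop]
  }

  num_field <- function(s, lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(s, lo, hi)))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed ", what, " in PDB line: ", trimws(al[bad[1]]))
    }
    v
  }
  x <- num_field(al, 31, 38, "x coordinate")
  y <- num_field(al, 39, 46, "y coordinate")
  z <- num_field(al, 47, 54, "z coordinate")
  occ_raw <- trimws(substr(al, 55, 60))
  b_raw <- trimws(substr(al, 61, 66))
  occ <- ifelse(nzchar(occ_raw), suppressWarnings(as.numeric(occ_raw)), 1)
  b <- ifelse(nzchar(b_raw), suppressWarnings(as.numeric(b_raw)), 0)
  if (any(is.na(occ)) || any(is.na(b))) {
    stop("malformed occupancy/B field in PDB line: ",
         trimws(al[which(is.na(occ) | is.na(b))[1]]))
  }

  name <- trimws(substr(al, 13, 16))
  element <- vapply(seq_along(al), function(i) {
    infer_element(substr(al[i], 77, 78), name[i])
  }, character(1))
  bad_el <- which(!element %in% KNOWN_ELEMENTS)
  if (length(bad_el)) {
    stop("unknown element for atom '", name[bad_el[1]], "' (line: ",
         trimws(al[bad_el[1]]), ")")
  }

  atoms <- data.frame(
    element = element,
    name = name,
    resname = trimws(substr(al, 18, 20)),
    resno = as.integer(num_field(al, 23, 26, "residue number")),
    chain = substr(al, 22, 22),
    x = x, y = y, z = z, b = b, occ = occ,
    stringsAsFactors = FALSE
  )
  atomic_model(atoms, cell, spacegroup)
}

#' Write an atomic model as PDB text
#'
#' Emits standard 80-column CRYST1 and ATOM records plus END. The writer and
#' [read_model()] round-trip models field-for-field within the supported
#' subset.
#'
#' @param model An `xtal_model`.
#' @param path Output path; if `NULL` the lines are returned invisibly only.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_model <- function(model, path = NULL) {
  cl <- model$cell
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                   model$spacegroup, 1L)
  a <- model$atoms
  # PDB atom-name alignment: names of 1-3 characters start in column 14
  pad_name <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                     sprintf(" %-3s", a$name))
  el <- ifelse(nchar(a$element) == 2, a$element, sprintf(" %s", a$element))
  atom_lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), pad_name, a$resname, a$chain, a$resno,
    a$x, a$y, a$z, a$occ, a$b, el)
  out <- c(cryst, atom_lines, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Select atoms by chain, residue range and atom names
#'
#' All supplied criteria must match; `NULL` means "any". Atom order is
#' preserved and an empty selection is valid.
#'
#' @param model An `xtal_model`.
#' @param chain Chain identifier, or `NULL`.
#' @param residues Length-2 integer vector `c(lo, hi)` (inclusive), or `NULL`.
#' @param atom_names Character vector of atom names, or `NULL`.
#' @return An `xtal_model` containing the matching atoms.
#' @export
select_atoms <- function(model, chain = NULL, residues = NULL, atom_names = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residues)) {
    if (length(residues) != 2 || residues[1] > residues[2]) {
      stop("residues must be c(lo, hi) with lo <= hi")
    }
    keep <- keep & a$resno >= residues[1] & a$resno <= residues[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  out <- model
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}
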