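## Fixed-column PDB substrate.
##
## The dialect implemented here is the one the docking pipeline consumes:
## ATOM records only, 4-character residue names in columns 18-21 (so that
## "SPIN" label residues round-trip), segment identifiers in columns 73-76
## which supersede the chain letter for all selection purposes, a terminal
## END line, and never any tab characters.

ATOM_COLS <- list(
  serial  = c(7L, 11L),
  name    = c(13L, 16L),
  altloc  = c(17L, 17L),
  resname = c(18L, 21L),
  chain   = c(22L, 22L),
  resid   = c(23L, 26L),
  icode   = c(27L, 27L),
  x       = c(31L, 38L),
  y       = c(39L, 46L),
  z       = c(47L, 54L),
  occ     = c(55L, 60L),
  b       = c(61L, 66L),
  segid   = c(73L, 76L),
  element = c(77L, 78L)
)

trimws2 <- function(x) gsub("^\\s+|\\s+$", "", x)

## element inferred from the atom name: first alphabetic character, so that
## "N001"->N, "CA"->C, "1HB"->H, "SG"->S
infer_element <- function(name) {
  el <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
  toupper(ifelse(grepl("[A-Za-z]", name), el, ""))
}

new_structure <- function(atoms, provenance = "memory") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, provenance = provenance),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("pdb_structure: %d atoms, segids: %s (%s)\n",
              nrow(a), paste(unique(a$segid), collapse = ","), x$provenance))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `pdb_structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a structure
#'
#' @param s a `pdb_structure`.
#' @return numeric n x 3 matrix of positions in Angstrom.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a structure
#' @param s a `pdb_structure`.
#' @param value numeric n x 3 matrix.
#' @export
`coords<-` <- function(s, value) {
  stopifnot(nrow(value) == nrow(s$atoms), ncol(value) == 3)
  s$atoms$x <- value[, 1]; s$atoms$y <- value[, 2]; s$atoms$z <- value[, 3]
  s
}

#' Read a fixed-column PDB file
#'
#' Parses ATOM records from a PDB file. Header lines and NUMMDL/MODEL/
#' ENDMDL/TER records are ignored; HETATM records are dropped unless
#' `keep_hetatm = TRUE` (mirroring removal of heteroatoms before docking).
#' The segment identifier (columns 73-76) supersedes the chain letter; when
#' blank it falls back to the chain. Residue names are taken from columns
#' 18-21 so 4-character names such as "SPIN" are preserved.
#'
#' @param path path to a PDB file.
#' @param keep_hetatm keep HETATM records as atoms? Default `FALSE`.
#' @return a `pdb_structure` with one row per atom: `serial`, `name`,
#'   `resname`, `chain`, `resid`, `x`, `y`, `z`, `occ`, `b`, `segid`,
#'   `element`.
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | substr(lines, 1, 5) == "ATOM "
  is_het <- substr(lines, 1, 6) == "HETATM"
  take <- which(is_atom | (keep_hetatm & is_het))
  if (length(take) == 0) stop("no ATOM records found in ", path)

  fld <- function(ln, key) {
    rng <- ATOM_COLS[[key]]
    substr(ln, rng[1], rng[2])
  }
  ln <- lines[take]
  bad <- which(nchar(ln) < 54)
  if (length(bad) > 0) {
    stop(sprintf("malformed fixed-width ATOM record at line %d of %s",
                 take[bad[1]], path))
  }
  altloc <- trimws2(fld(ln, "altloc"))
  if (any(altloc != "")) {
    stop(sprintf("alternate location indicators are not supported (line %d)",
                 take[which(altloc != "")[1]]))
  }
  icode <- trimws2(fld(ln, "icode"))
  if (any(icode != "")) {
    stop(sprintf("insertion codes are not supported (line %d)",
                 take[which(icode != "")[1]]))
  }
  num <- function(key, default = NA_real_) {
    v <- trimws2(fld(ln, key))
    out <- suppressWarnings(as.numeric(v))
    out[v == ""] <- default
    out
  }
  serial <- suppressWarnings(as.integer(trimws2(fld(ln, "serial"))))
  resid <- suppressWarnings(as.integer(trimws2(fld(ln, "resid"))))
  xyz <- cbind(num("x"), num("y"), num("z"))
  bad <- which(is.na(resid) | apply(is.na(xyz), 1, any))
  if (length(bad) > 0) {
    stop(sprintf("malformed fixed-width ATOM record at line %d of %s",
                 take[bad[1]], path))
  }
  name <- trimws2(fld(ln, "name"))
  chain <- trimws2(fld(ln, "chain"))
  segid <- trimws2(fld(ln, "segid"))
  segid[segid == ""] <- chain[segid == ""]
  element <- trimws2(fld(ln, "element"))
  element[element == ""] <- infer_element(name[element == ""])
  atoms <- data.frame(
    serial = ifelse(is.na(serial), seq_along(ln), serial),
    name = name,
    resname = trimws2(fld(ln, "resname")),
    chain = chain,
    resid = resid,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = num("occ", 1), b = num("b", 0),
    segid = segid,
    element = element,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, provenance = path)
}

format_atom_name <- function(name) {
  ## 4-char names fill columns 13-16; shorter names start in column 14
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a structure as a fixed-column PDB file
#'
#' Emits one ATOM record per atom in order, with serials renumbered to be
#' strictly increasing, residue names left-justified in columns 18-21,
#' segment ids in columns 73-76 and a final line containing only `END`.
#' The output never contains tab characters, and `read_pdb()` of the result
#' recovers all modelled fields (coordinates at 3 decimals).
#'
#' @param s a `pdb_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  if (any(nchar(a$name) > 4)) stop("atom name longer than 4 characters")
  if (any(nchar(a$segid) > 4)) stop("segment id longer than 4 characters")
  if (any(nchar(a$resname) > 4)) stop("residue name longer than 4 characters")
  if (any(a$resid > 9999 | a$resid < -999)) stop("residue number out of field range")
  key <- paste(a$segid, a$resid, a$name)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a (segid, resid): ", key[anyDuplicated(key)])
  }
  lines <- sprintf(
    "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
    seq_len(nrow(a)) %% 100000L,
    format_atom_name(a$name),
    a$resname,
    substr(paste0(a$chain, " "), 1, 1),
    a$resid, a$x, a$y, a$z, a$occ, a$b,
    a$segid,
    substr(paste0("  ", a$element), nchar(a$element) + 1, nchar(a$element) + 2)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Renumber residues of a selection
#'
#' Optional explicit renumbering (e.g. to make a generated segment start at a
#' given first residue); never applied implicitly.
#'
#' @param s a `pdb_structure`.
#' @param sel selection (string or parsed) choosing the atoms to renumber.
#' @param first new number for the lowest selected residue; subsequent
#'   residues keep their original offsets.
#' @return modified `pdb_structure`.
#' @export
renumber_residues <- function(s, sel, first = 1L) {
  idx <- select_atoms(s, sel)
  if (length(idx) == 0) return(s)
  r <- s$atoms$resid[idx]
  s$atoms$resid[idx] <- r - min(r) + as.integer(first)
  s
}

#' Rigidly transform a selection of atoms
#'
#' Applies `x' = R x + t` to every selected atom, leaving the rest of the
#' structure untouched. The rotation must be proper orthonormal; rigidity
#' (all intra-selection distances) is preserved to machine precision.
#'
#' @param s a `pdb_structure`.
#' @param sel selection string or object; `"all"` transforms every atom.
#' @param rotation 3x3 proper rotation matrix (det +1, orthonormal to 1e-8).
#' @param translation 3-vector in Angstrom.
#' @return transformed `pdb_structure`.
#' @export
apply_transform <- function(s, sel = "all", rotation = diag(3),
                            translation = c(0, 0, 0)) {
  if (!is_rotation_matrix(rotation)) {
    stop("rotation must be a proper orthonormal 3x3 matrix (det +1)")
  }
  idx <- select_atoms(s, sel)
  if (length(idx) == 0) return(s)
  X <- coords(s)
  X[idx, ] <- X[idx, , drop = FALSE] %*% t(rotation) +
    matrix(translation, length(idx), 3, byrow = TRUE)
  coords(s) <- X
  s
}

## rbind two structures
merge_structures <- function(a, b) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, provenance = a$provenance)
}
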