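#' @importFrom stats median sd mad optimize coef lm rnorm runif setNames
#'   quantile approx dist
#' @importFrom utils read.delim write.table head tail
NULL

# van der Waals radii (Angstrom), Bondi (1964) set; DEFAULT_VDW_RADIUS is the
# documented fallback for elements missing from the table.
VDW_RADII_BONDI <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, ZN = 1.39, CU = 1.40,
  NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, FE = 2.00, MN = 2.00
)
DEFAULT_VDW_RADIUS <- 1.8

#' Atomic structure model
#'
#' A `StructureModel` is the package's coordinate container: a data frame of
#' atom records (one row per atom) plus provenance. Atom columns are
#' `serial`, `name`, `alt_loc`, `res_name`, `chain_id`, `res_seq`, `ins_code`,
#' `x`, `y`, `z`, `occupancy`, `element`, `het` and `vdw_radius`
#' (`NA` until [assign_radii()] is called). Coordinates are in Angstrom and
#' `res_seq` is the author residue numbering, which is authoritative
#' throughout so residue ranges quoted for the mature pilin (e.g. the
#' alpha1-N helix, residues 3-18) can be addressed directly.
#'
#' @param atoms data frame with at least `name`, `res_name`, `chain_id`,
#'   `res_seq`, `x`, `y`, `z` and `element` columns.
#' @param label free-text label.
#' @param provenance list describing the source (file, format).
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, label = "", provenance = list(source = "memory")) {
  required <- c("name", "res_name", "chain_id", "res_seq", "x", "y", "z", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  defaults <- list(serial = seq_len(nrow(atoms)), alt_loc = "", ins_code = "",
                   occupancy = 1, het = FALSE, vdw_radius = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite coordinates in atom table")
    }
    if (any(!nzchar(atoms$element))) stop("empty element symbols in atom table")
    # author numbering must be non-decreasing within a chain; reorder stably
    ord <- order(match(atoms$chain_id, unique(atoms$chain_id)), atoms$res_seq)
    atoms <- atoms[ord, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  structure(list(atoms = atoms, label = label, provenance = provenance),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d atoms, %d chains (%s)\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$chain_id)),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `StructureModel`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract one chain as a StructureModel
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @return `StructureModel` restricted to that chain.
#' @export
get_chain <- function(model, chain_id) {
  sel <- model$atoms$chain_id == chain_id
  if (!any(sel)) stop("no such chain: ", chain_id)
  structure_model(model$atoms[sel, , drop = FALSE],
                  label = paste0(model$label, ":", chain_id),
                  provenance = model$provenance)
}

guess_element <- function(atom_name, res_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  if (nchar(nm) == 0) return("")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "CU")) return(two)
  toupper(substr(nm, 1, 1))
}

read_pdb_atoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) stop("no ATOM/HETATM records in ", path)
  ln <- lines[keep]
  num <- function(s, what, idx) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad) > 0) {
      stop(sprintf("malformed %s field in %s at line %d: '%s'",
                   what, path, keep[bad[1]], lines[keep[bad[1]]]))
    }
    v
  }
  f <- function(a, b) trimws(substr(ln, a, b))
  x <- num(substr(ln, 31, 38), "x", keep)
  y <- num(substr(ln, 39, 46), "y", keep)
  z <- num(substr(ln, 47, 54), "z", keep)
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    stop("missing coordinates in ", path)
  }
  element <- toupper(f(77, 78))
  name <- f(13, 16)
  res_name <- f(18, 20)
  no_el <- !nzchar(element)
  if (any(no_el)) {
    element[no_el] <- mapply(guess_element, name[no_el], res_name[no_el])
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  data.frame(
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = name,
    alt_loc = f(17, 17),
    res_name = res_name,
    chain_id = f(22, 22),
    res_seq = num(substr(ln, 23, 26), "residue number", keep),
    ins_code = f(27, 27),
    x = x, y = y, z = z,
    occupancy = occ,
    element = element,
    het = substr(ln, 1, 6) == "HETATM",
    vdw_radius = NA_real_,
    stringsAsFactors = FALSE
  )
}

read_mmcif_atoms <- function(lines, path) {
  # minimal loop_ parser for the _atom_site category
  i_fields <- grep("^_atom_site\\.", lines)
  if (length(i_fields) == 0) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[i_fields]))
  first_row <- max(i_fields) + 1
  rows <- character(0)
  for (i in first_row:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" ) next
    if (grepl("^(#|loop_|_)", l)) break
    rows <- c(rows, l)
  }
  if (length(rows) == 0) stop("empty _atom_site loop in ", path)
  parts <- strsplit(rows, "[[:space:]]+")
  nf <- length(fields)
  bad <- which(vapply(parts, length, 1L) != nf)
  if (length(bad) > 0) {
    stop(sprintf("malformed _atom_site row in %s at data row %d", path, bad[1]))
  }
  m <- do.call(rbind, parts)
  colnames(m) <- fields
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  unq <- function(v) gsub("^['\"]|['\"]$", "", v)
  numc <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out))) stop("malformed ", what, " in _atom_site of ", path)
    out
  }
  res_seq <- pick("auth_seq_id", "label_seq_id")
  res_seq[res_seq %in% c(".", "?")] <- "0"
  ins <- pick("pdbx_PDB_ins_code")
  ins[is.na(ins) | ins %in% c(".", "?")] <- ""
  alt <- pick("label_alt_id")
  alt[is.na(alt) | alt %in% c(".", "?")] <- ""
  occ <- suppressWarnings(as.numeric(pick("occupancy")))
  occ[is.na(occ)] <- 1
  data.frame(
    serial = suppressWarnings(as.integer(pick("id"))),
    name = unq(pick("auth_atom_id", "label_atom_id")),
    alt_loc = alt,
    res_name = pick("auth_comp_id", "label_comp_id"),
    chain_id = pick("auth_asym_id", "label_asym_id"),
    res_seq = numc(res_seq, "residue number"),
    ins_code = ins,
    x = numc(m[, "Cartn_x"], "x"), y = numc(m[, "Cartn_y"], "y"),
    z = numc(m[, "Cartn_z"], "z"),
    occupancy = occ,
    element = toupper(pick("type_symbol")),
    het = pick("group_PDB") == "HETATM",
    vdw_radius = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses ATOM/HETATM coordinate records. Waters (HOH/WAT/DOD) are excluded by
#' default because solvent is not part of the deposited heavy-atom filament
#' models this package analyses; pass `keep_waters = TRUE` to retain them.
#' Insertion codes and author residue numbering are preserved.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect by extension, then by
#'   content).
#' @param keep_waters keep water residues (default `FALSE`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_waters = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("^_atom_site\\.", lines))) "mmcif"
      else if (any(grepl("^(ATOM  |HETATM)", lines))) "pdb"
      else stop("cannot detect structure format of ", path)
  }
  atoms <- switch(format,
    pdb = read_pdb_atoms(lines, path),
    mmcif = read_mmcif_atoms(lines, path),
    stop("unknown format: ", format)
  )
  if (!keep_waters) atoms <- atoms[!(atoms$res_name %in% c("HOH", "WAT", "DOD")), ,
                                   drop = FALSE]
  structure_model(atoms,
                  label = basename(path),
                  provenance = list(source = path, format = format))
}

#' Write a model to PDB format
#'
#' Chains with multi-character identifiers are rotated through the
#' single-character PDB alphabet; the mapping is returned invisibly.
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @return Invisibly, the chain-id mapping used.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  chains <- unique(a$chain_id)
  alphabet <- c(LETTERS, letters, 0:9)
  if (length(chains) > length(alphabet)) {
    stop("chain-id exhaustion: ", length(chains),
         " chains exceed the PDB single-character alphabet; renumber or split")
  }
  short <- vapply(seq_along(chains), function(i) {
    if (nchar(chains[i]) == 1) chains[i] else alphabet[i]
  }, "")
  # resolve collisions between native single-char ids and rotated ids
  while (anyDuplicated(short)) {
    dup <- which(duplicated(short))[1]
    free <- setdiff(alphabet, short)
    if (length(free) == 0) stop("chain-id exhaustion while renaming; renumber chains")
    short[dup] <- free[1]
  }
  map <- setNames(short, chains)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"),
    ((seq_len(nrow(a)) - 1) %% 99999) + 1,
    ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
    substr(a$alt_loc, 1, 1),
    a$res_name, map[a$chain_id], as.integer(a$res_seq),
    substr(a$ins_code, 1, 1),
    a$x, a$y, a$z, a$occupancy, 0,
    substr(a$element, 1, 2)
  )
  writeLines(c(lines, "END"), path)
  invisible(map)
}

#' Export the atom table as TSV
#' @param model a `StructureModel`.
#' @param path output path.
#' @export
write_atoms_tsv <- function(model, path) {
  write.table(model$atoms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign van der Waals radii
#'
#' Attaches a radius to every atom from a published radius table (default:
#' Bondi 1964). Unknown elements receive the documented default of
#' `r DEFAULT_VDW_RADIUS` Angstrom with a warning. Idempotent.
#'
#' @param model a `StructureModel`.
#' @param radius_set named numeric vector element -> radius (Angstrom), or the
#'   name `"bondi"`.
#' @return The model with `vdw_radius` filled in.
#' @export
assign_radii <- function(model, radius_set = "bondi") {
  tab <- if (is.character(radius_set) && length(radius_set) == 1) {
    switch(radius_set, bondi = VDW_RADII_BONDI,
           stop("unknown radius set: ", radius_set))
  } else radius_set
  el <- toupper(model$atoms$element)
  el[el == "NA"] <- "NA."  # sodium; avoid clash with R's NA name handling
  r <- unname(tab[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no tabulated vdW radius for element(s) ",
            paste(unique(el[unknown]), collapse = ", "),
            "; using default ", DEFAULT_VDW_RADIUS, " A")
    r[unknown] <- DEFAULT_VDW_RADIUS
  }
  model$atoms$vdw_radius <- r
  model
}

#' Rigid-body transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1, checked to
#'   1e-9).
#' @param translation length-3 numeric vector (Angstrom).
#' @return An object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation is not a proper rotation (orthonormal, det +1)")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Compose two rigid transforms (a then b)
#' @param a,b `RigidTransform` objects.
#' @return The composition `b o a` as a `RigidTransform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param t a `RigidTransform`.
#' @return The inverse `RigidTransform`.
#' @export
invert_transform <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to a model
#' @param model a `StructureModel`.
#' @param t a `RigidTransform`.
#' @return The transformed model (topology unchanged).
#' @export
apply_transform <- function(model, t) {
  if (!inherits(t, "RigidTransform")) stop("t must be a RigidTransform")
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(t$rotation)
  model$atoms$x <- new[, 1] + t$translation[1]
  model$atoms$y <- new[, 2] + t$translation[2]
  model$atoms$z <- new[, 3] + t$translation[3]
  model
}
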