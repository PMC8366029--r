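#' Parse a PDB-format structure
#'
#' Reads `ATOM`/`HETATM` records from PDB-format text and returns a
#' structure model with polymer chains and heteroatom (ligand, ion,
#' cofactor) residues kept apart. Alternate locations are collapsed to a
#' single atom per atom name: the highest-occupancy altloc is kept, ties
#' broken toward altloc `"A"`. Hydrogens are retained and can be excluded
#' downstream via their element symbol.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines with PDB-format content, or the path of an existing file.
#' @param id Structure identifier; defaults to the `HEADER` idCode when
#'   present, else `"structure"`.
#' @return An object of class `pt_structure`: a list with elements
#'   `id`, `title`, and `atoms`, a data frame with one row per atom and
#'   columns `record`, `serial`, `name`, `altloc`, `resname`, `chain`,
#'   `resnum`, `icode`, `x`, `y`, `z`, `occupancy`, `element`,
#'   `is_hetero`.
#' @examples
#' pdb <- make_toy_structure(toy_structure_spec(n_residues = 5,
#'                                              pocket_members = c(2, 4)))
#' model <- parse_pdb(pdb)
#' model
#' @export
parse_pdb <- function(text, id = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(text))
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0L) stop("empty PDB input")

  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM or HETATM records found")

  title <- paste(trimws(substr(lines[startsWith(lines, "TITLE")], 11L, 80L)),
                 collapse = " ")
  if (is.null(id)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    id <- if (length(hdr)) trimws(substr(hdr[1L], 63L, 66L)) else ""
    if (!nzchar(id)) id <- "structure"
  }

  ln <- lines[is_atom]
  lineno <- which(is_atom)
  num_field <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad)) {
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, lineno[bad[1L]], ln[bad[1L]]))
    }
    v
  }
  x <- num_field(substr(ln, 31L, 38L), "x coordinate")
  y <- num_field(substr(ln, 39L, 46L), "y coordinate")
  z <- num_field(substr(ln, 47L, 54L), "z coordinate")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
    stop(sprintf("malformed coordinate field at line %d", lineno[bad]))
  }
  occ <- num_field(substr(ln, 55L, 60L), "occupancy")
  occ[is.na(occ)] <- 1

  name <- trimws(substr(ln, 13L, 16L))
  element <- trimws(substr(ln, 77L, 78L))
  # derive element from the atom name when the element column is blank
  noel <- !nzchar(element)
  if (any(noel)) {
    guess <- sub("^[0-9]*", "", name[noel])
    two <- toupper(substr(guess, 1L, 2L)) %in%
      c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA", "BR", "SE", "NI", "CO")
    element[noel] <- ifelse(two, substr(guess, 1L, 2L), substr(guess, 1L, 1L))
  }
  element <- toupper(element)

  atoms <- data.frame(
    record    = trimws(rec[is_atom]),
    serial    = suppressWarnings(as.integer(trimws(substr(ln, 7L, 11L)))),
    name      = name,
    altloc    = substr(ln, 17L, 17L),
    resname   = trimws(substr(ln, 18L, 20L)),
    chain     = substr(ln, 22L, 22L),
    resnum    = num_field(substr(ln, 23L, 26L), "residue number"),
    icode     = trimws(substr(ln, 27L, 27L)),
    x = x, y = y, z = z,
    occupancy = occ,
    element   = element,
    stringsAsFactors = FALSE
  )
  atoms$resnum <- as.integer(atoms$resnum)
  atoms$altloc[atoms$altloc == " "] <- ""
  atoms$is_hetero <- atoms$record == "HETATM"

  atoms <- resolve_altlocs(atoms)
  structure(list(id = id, title = title, atoms = atoms),
            class = "pt_structure")
}

# keep a single altloc per (chain, residue, atom name):
# highest occupancy wins, ties broken toward altloc 'A' (then first seen)
resolve_altlocs <- function(atoms) {
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name,
               atoms$is_hetero, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    sub <- atoms[idx, ]
    ord <- order(-sub$occupancy, sub$altloc != "A", seq_along(idx))
    keep[idx[-ord[1L]]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' @export
print.pt_structure <- function(x, ...) {
  het <- unique(x$atoms$resname[x$atoms$is_hetero])
  cat(sprintf("Structure '%s': %d atoms, chains [%s], het groups [%s]\n",
              x$id, nrow(x$atoms),
              paste(sort(unique(x$atoms$chain[!x$atoms$is_hetero])),
                    collapse = ","),
              paste(het, collapse = ",")))
  invisible(x)
}

water_codes <- c("HOH", "WAT", "DOD")
metal_codes <- c("ZN", "MG", "MN", "FE", "CU", "NA", "K", "CA", "NI", "CO", "CD")

#' Select the heavy atoms of a bound ligand
#'
#' Picks one het residue by code and returns its heavy (non-hydrogen)
#' atoms. If the structure carries several copies of the ligand and no
#' selector is given, the first copy by (chain, residue number) is used
#' and a warning is raised.
#'
#' @param model A `pt_structure` from [parse_pdb()].
#' @param het_code Three-letter het code, e.g. `"ABL"`. Water codes are
#'   rejected.
#' @param chain_id Optional chain restriction.
#' @param copy_index Optional 1-based index among the matching copies
#'   (ordered by chain, then residue number).
#' @return Data frame of atoms (subset of `model$atoms`).
#' @export
select_ligand <- function(model, het_code, chain_id = NULL, copy_index = NULL) {
  stopifnot(inherits(model, "pt_structure"))
  if (toupper(het_code) %in% water_codes) {
    stop(sprintf("'%s' is a water code, not a ligand", het_code))
  }
  het <- model$atoms[model$atoms$is_hetero, , drop = FALSE]
  hit <- het[het$resname == het_code, , drop = FALSE]
  if (!is.null(chain_id)) hit <- hit[hit$chain == chain_id, , drop = FALSE]
  if (nrow(hit) == 0L) {
    avail <- setdiff(unique(het$resname), water_codes)
    stop(sprintf("het code '%s' not found; available: %s", het_code,
                 if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
  }
  copies <- unique(hit[, c("chain", "resnum", "icode")])
  copies <- copies[order(copies$chain, copies$resnum, copies$icode), ,
                   drop = FALSE]
  if (is.null(copy_index)) {
    if (nrow(copies) > 1L) {
      warning(sprintf("%d copies of %s present; using first (chain %s, residue %d)",
                      nrow(copies), het_code, copies$chain[1L], copies$resnum[1L]))
    }
    copy_index <- 1L
  }
  if (copy_index > nrow(copies)) {
    stop(sprintf("copy_index %d out of range (%d copies)", copy_index,
                 nrow(copies)))
  }
  sel <- copies[copy_index, ]
  out <- hit[hit$chain == sel$chain & hit$resnum == sel$resnum &
               hit$icode == sel$icode & hit$element != "H", , drop = FALSE]
  if (nrow(out) == 0L) stop("selected ligand copy has no heavy atoms")
  out
}

#' Identify binding-pocket residues by a ligand distance criterion
#'
#' A polymer residue belongs to the pocket when at least one of its heavy
#' atoms lies within `cutoff_A` angstroms (Euclidean, atom centers) of at
#' least one ligand heavy atom. Waters and free metal ions never count as
#' pocket residues; het groups other than the ligand that fall inside the
#' cutoff are reported separately as context in the `context_het`
#' attribute.
#'
#' @param model A `pt_structure`.
#' @param ligand_atoms Data frame of ligand heavy atoms, as returned by
#'   [select_ligand()].
#' @param cutoff_A Distance cutoff in angstroms (default 5).
#' @param chain_id Optional: restrict pocket residues to one chain.
#' @return A [pocket_definition()] object with `provenance = "distance"`
#'   for every position.
#' @export
pocket_residues <- function(model, ligand_atoms, cutoff_A = 5, chain_id = NULL) {
  stopifnot(inherits(model, "pt_structure"))
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0L) {
    stop("empty ligand atom set")
  }
  if (!is.numeric(cutoff_A) || cutoff_A <= 0) stop("cutoff_A must be > 0")

  prot <- model$atoms[!model$atoms$is_hetero & model$atoms$element != "H", ,
                      drop = FALSE]
  if (!is.null(chain_id)) prot <- prot[prot$chain == chain_id, , drop = FALSE]
  # never count the ligand's own residue even if recorded as ATOM
  lig_key <- unique(paste(ligand_atoms$chain, ligand_atoms$resnum,
                          ligand_atoms$icode))
  prot <- prot[!(paste(prot$chain, prot$resnum, prot$icode) %in% lig_key), ,
               drop = FALSE]
  if (nrow(prot) == 0L) stop("no pocket found: no polymer atoms to test")

  lx <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  px <- as.matrix(prot[, c("x", "y", "z")])
  # squared distances protein x ligand, vectorized
  d2 <- outer(rowSums(px^2), rowSums(lx^2), "+") - 2 * (px %*% t(lx))
  near <- apply(d2, 1L, min) <= cutoff_A^2 + 1e-12

  hit <- unique(prot[near, c("chain", "resnum", "icode"), drop = FALSE])
  if (nrow(hit) == 0L) {
    stop(sprintf("no pocket found: no residue within %.1f angstrom of the ligand",
                 cutoff_A))
  }
  hit <- hit[order(hit$chain, hit$resnum, hit$icode), , drop = FALSE]

  # context: non-water het groups (e.g. catalytic metals) inside the cutoff
  het <- model$atoms[model$atoms$is_hetero & model$atoms$element != "H", ,
                     drop = FALSE]
  het <- het[!(paste(het$chain, het$resnum, het$icode) %in% lig_key) &
               !(het$resname %in% water_codes), , drop = FALSE]
  context <- character(0)
  if (nrow(het)) {
    hx <- as.matrix(het[, c("x", "y", "z")])
    hd2 <- outer(rowSums(hx^2), rowSums(lx^2), "+") - 2 * (hx %*% t(lx))
    hnear <- apply(hd2, 1L, min) <= cutoff_A^2 + 1e-12
    context <- unique(paste0(het$resname[hnear], " ", het$chain[hnear],
                             het$resnum[hnear]))
  }

  pd <- pocket_definition(
    structure_id = model$id,
    chain_id = if (is.null(chain_id)) paste(sort(unique(hit$chain)),
                                            collapse = ",") else chain_id,
    cutoff_A = cutoff_A,
    ligand_code = ligand_atoms$resname[1L],
    positions = hit$resnum,
    provenance = rep("distance", nrow(hit))
  )
  attr(pd, "context_het") <- context
  pd
}

#' Construct a pocket definition
#'
#' A pocket definition names the reference structure and chain, the
#' distance cutoff, the het code of the ligand, and the ordered residue
#' positions (author numbering) that make up the substrate binding
#' pocket, each with a provenance: `"distance"` when derived from the
#' ligand-distance criterion, `"literature"` when transcribed from
#' published reports.
#'
#' @param structure_id Reference structure identifier (e.g. `"1NAA"`).
#' @param chain_id Reference chain.
#' @param cutoff_A Distance cutoff in angstroms used (or assumed).
#' @param ligand_code Het code of the bound ligand.
#' @param positions Integer vector of residue numbers, strictly increasing.
#' @param provenance Character vector, one of `"distance"`/`"literature"`
#'   per position (recycled if scalar).
#' @return An object of class `pt_pocket`.
#' @seealso [packaged_pocket()] for the pocket definitions shipped with
#'   the package.
#' @export
pocket_definition <- function(structure_id, chain_id, cutoff_A = 5,
                              ligand_code = "", positions,
                              provenance = "literature") {
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("pocket definition must be non-empty")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("pocket positions must be strictly increasing")
  }
  if (!is.numeric(cutoff_A) || cutoff_A <= 0) stop("cutoff_A must be > 0")
  provenance <- rep_len(provenance, length(positions))
  if (!all(provenance %in% c("distance", "literature"))) {
    stop("provenance must be 'distance' or 'literature'")
  }
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 cutoff_A = cutoff_A, ligand_code = ligand_code,
                 positions = positions, provenance = provenance),
            class = "pt_pocket")
}

#' @export
print.pt_pocket <- function(x, ...) {
  cat(sprintf("Pocket definition: %s chain %s, ligand %s, cutoff %.1f A\n",
              x$structure_id, x$chain_id, x$ligand_code, x$cutoff_A))
  cat(sprintf("%d positions: %s\n", length(x$positions),
              paste(x$positions, collapse = ", ")))
  ctx <- attr(x, "context_het")
  if (length(ctx)) cat("context het groups within cutoff:",
                       paste(ctx, collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.pt_pocket <- function(x) length(x$positions)

#' Serialize / deserialize a pocket definition as JSON
#'
#' @param pocket A `pt_pocket`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return `write_pocket_json()`: the JSON text (invisibly when written to
#'   a file). `read_pocket_json()`: a `pt_pocket`.
#' @export
write_pocket_json <- function(pocket, path = NULL) {
  stopifnot(inherits(pocket, "pt_pocket"))
  obj <- list(structure_id = pocket$structure_id,
              chain_id = pocket$chain_id,
              cutoff_A = pocket$cutoff_A,
              ligand_code = pocket$ligand_code,
              positions = lapply(seq_along(pocket$positions), function(i) {
                list(number = pocket$positions[i],
                     provenance = pocket$provenance[i])
              }))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' @rdname write_pocket_json
#' @param json JSON text or a file path.
#' @export
read_pocket_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  pocket_definition(structure_id = obj$structure_id,
                    chain_id = obj$chain_id,
                    cutoff_A = obj$cutoff_A,
                    ligand_code = obj$ligand_code,
                    positions = obj$positions$number,
                    provenance = obj$positions$provenance)
}

#' Packaged pocket definitions
#'
#' Pocket definitions shipped with the package, transcribed from published
#' position lists: `"AOx"` — 19 positions of the long-chain alcohol
#' oxidase reference (cellobiose dehydrogenase flavoprotein 1NAA) within
#' 5 angstroms of its inhibitor ABL; `"AmDH"` — 20 substrate-binding
#' positions of the amine dehydrogenase reference 1C1D (chain A), derived
#' from structure inspection and literature reports.
#'
#' @param family `"AOx"` or `"AmDH"`.
#' @return A `pt_pocket`.
#' @examples
#' packaged_pocket("AOx")
#' length(packaged_pocket("AmDH"))
#' @export
packaged_pocket <- function(family = c("AOx", "AmDH")) {
  family <- match.arg(family)
  file <- switch(family,
    AOx  = "pocket_aox_1naa.json",
    AmDH = "pocket_amdh_1c1d.json")
  read_pocket_json(system.file("extdata", file, package = "pockettree",
                               mustWork = TRUE))
}

#' Map structure residue numbering to ungapped sequence positions
#'
#' Resolved residues of a chain are numbered densely 1..n in order of
#' appearance; the map translates author residue numbers (which may jump
#' or carry insertion codes) to those dense indices.
#'
#' @param model A `pt_structure`.
#' @param chain_id Chain label.
#' @return Named integer vector: names are author residue numbers (with
#'   insertion code appended when present, e.g. `"52A"`), values are dense
#'   1-based sequence indices.
#' @examples
#' pdb <- make_toy_structure(toy_structure_spec(n_residues = 4,
#'                                              pocket_members = 2))
#' structure_to_sequence_map(parse_pdb(pdb), "A")
#' @export
structure_to_sequence_map <- function(model, chain_id) {
  stopifnot(inherits(model, "pt_structure"))
  at <- model$atoms[!model$atoms$is_hetero & model$atoms$chain == chain_id, ,
                    drop = FALSE]
  if (nrow(at) == 0L) {
    stop(sprintf("unknown chain '%s' (available: %s)", chain_id,
                 paste(sort(unique(model$atoms$chain[!model$atoms$is_hetero])),
                       collapse = ", ")))
  }
  key <- paste0(at$resnum, at$icode)
  key <- key[!duplicated(key)]
  stats::setNames(seq_along(key), key)
}
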