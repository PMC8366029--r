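AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
GAP <- "-"

#' Construct an alignment object
#'
#' @param ids Unique sequence identifiers.
#' @param rows Gapped sequences (uppercase amino acids and `-`), all the
#'   same length.
#' @return An object of class `pt_alignment` with elements `ids`, `rows`
#'   and `width`.
#' @export
alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (length(ids) == 0L) stop("alignment needs at least one sequence")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    bad <- ids[w != w[1L]][1L]
    stop(sprintf("rows have unequal length (e.g. '%s')", bad))
  }
  # 20 standard residues plus extended/ambiguity codes and the gap
  ok <- grepl(sprintf("^[%sBZJUOX.*%s]*$", paste(AA_ALPHABET, collapse = ""),
                      GAP), rows)
  if (!all(ok)) {
    stop(sprintf("invalid characters in row '%s'", ids[!ok][1L]))
  }
  structure(list(ids = ids, rows = stats::setNames(rows, ids), width = w[1L]),
            class = "pt_alignment")
}

#' @export
print.pt_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n", length(x$ids), x$width))
  invisible(x)
}

#' Read / write an aligned FASTA file
#'
#' `read_alignment()` accepts a file path or FASTA text; all records must
#' have the same (gapped) length. `write_alignment()` emits canonical
#' single-line-per-sequence FASTA so that write/read round-trips are
#' byte-identical.
#'
#' @param input File path or FASTA text (character scalar with newlines).
#' @return `read_alignment()`: a `pt_alignment`. `write_alignment()`: the
#'   FASTA text, invisibly when written to a file.
#' @export
read_alignment <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    path <- input
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records found")
  ids <- sub("\\s.*$", "", names(set))
  alignment(ids, as.character(set))
}

#' @rdname read_alignment
#' @param a A `pt_alignment`.
#' @param path Optional output file path.
#' @export
write_alignment <- function(a, path = NULL) {
  stopifnot(inherits(a, "pt_alignment"))
  txt <- paste0(">", a$ids, "\n", unname(a$rows), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (is.null(path)) return(txt)
  cat(txt, file = path)
  invisible(txt)
}

row_chars <- function(a) {
  m <- matrix(unlist(strsplit(unname(a$rows), "", fixed = TRUE), use.names = FALSE),
              nrow = length(a$ids), ncol = a$width, byrow = TRUE)
  rownames(m) <- a$ids
  m
}

#' Filter sequences by ungapped length
#'
#' Optional admission filter mirroring database retrieval practice of
#' restricting candidate enzymes to a plausible length window (e.g.
#' 250-600 residues for a two-domain dehydrogenase architecture).
#'
#' @param a A `pt_alignment` (lengths are counted without gaps).
#' @param min_length,max_length Inclusive bounds.
#' @return The filtered `pt_alignment`.
#' @export
filter_by_length <- function(a, min_length = 250, max_length = 600) {
  stopifnot(inherits(a, "pt_alignment"))
  len <- nchar(gsub("-", "", a$rows, fixed = TRUE))
  keep <- len >= min_length & len <= max_length
  if (!any(keep)) stop("no sequences within the length bounds")
  alignment(a$ids[keep], a$rows[keep])
}

#' Declare a swap group
#'
#' A swap group records a set of alignment columns whose residues are
#' structurally equivalent but occur in a different sequential order in
#' different subfamilies (e.g. a loop whose hinge residues swap between
#' the human and fungal forms of an enzyme). For each subfamily tag, a
#' permutation of the columns states, for each profile slot, which source
#' column feeds it in that subfamily.
#'
#' @param columns Integer vector (>= 2) of 1-based alignment columns, in
#'   the slot order of the reduced profile.
#' @param permutations Named list: subfamily tag -> integer vector, a
#'   permutation of `columns`; `permutations[[tag]][i]` is the source
#'   column that fills slot `columns[i]` for members of `tag`.
#' @param members Named list: subfamily tag -> character vector of
#'   sequence ids. Each id may appear in at most one tag.
#' @return An object of class `pt_swap_group`.
#' @export
swap_group <- function(columns, permutations, members) {
  columns <- as.integer(columns)
  if (length(columns) < 2L) stop("a swap group needs at least 2 columns")
  if (!setequal(names(permutations), names(members))) {
    stop("permutations and members must cover the same subfamily tags")
  }
  for (tag in names(permutations)) {
    p <- as.integer(permutations[[tag]])
    if (!setequal(p, columns) || length(p) != length(columns)) {
      stop(sprintf("permutation for '%s' is not a bijection on the group columns",
                   tag))
    }
    permutations[[tag]] <- p
  }
  all_ids <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("a sequence id appears in more than one subfamily tag")
  }
  structure(list(columns = columns, permutations = permutations,
                 members = members),
            class = "pt_swap_group")
}

#' Construct a seed alignment
#'
#' A seed alignment is a frozen, curated alignment carrying (i) per
#' reference sequence, a map from ungapped positions to columns, (ii) the
#' designated pocket columns (set later via
#' [designate_pocket_columns()] or directly), and (iii) declared swap
#' groups.
#'
#' @param a A `pt_alignment`.
#' @param reference_ids Ids whose rows anchor structure numbering.
#' @param designated_columns Optional 1-based column indices of the
#'   pocket profile (strictly increasing).
#' @param swap_groups Optional list of [swap_group()] objects.
#' @return An object of class `pt_seed`.
#' @export
seed_alignment <- function(a, reference_ids = character(0),
                           designated_columns = integer(0),
                           swap_groups = list()) {
  stopifnot(inherits(a, "pt_alignment"))
  if (!all(reference_ids %in% a$ids)) {
    stop("reference ids not in alignment: ",
         paste(setdiff(reference_ids, a$ids), collapse = ", "))
  }
  maps <- lapply(stats::setNames(reference_ids, reference_ids), function(id) {
    which(strsplit(a$rows[[id]], "", fixed = TRUE)[[1L]] != GAP)
  })
  designated_columns <- as.integer(designated_columns)
  if (length(designated_columns)) {
    if (is.unsorted(designated_columns, strictly = TRUE)) {
      stop("designated columns must be strictly increasing")
    }
    if (max(designated_columns) > a$width) {
      stop("designated column beyond alignment width")
    }
  }
  for (g in swap_groups) {
    if (!inherits(g, "pt_swap_group")) stop("swap_groups must be pt_swap_group")
  }
  structure(list(alignment = a, reference_maps = maps,
                 designated_columns = designated_columns,
                 swap_groups = swap_groups),
            class = "pt_seed")
}

#' @export
print.pt_seed <- function(x, ...) {
  cat(sprintf("Seed alignment: %d sequences x %d columns; %d designated columns; %d swap groups\n",
              length(x$alignment$ids), x$alignment$width,
              length(x$designated_columns), length(x$swap_groups)))
  invisible(x)
}

#' Column of a reference residue
#'
#' Maps a 1-based ungapped position of a reference sequence to its
#' alignment column.
#'
#' @param seed A `pt_seed`.
#' @param ref_id Reference sequence id present in the seed's reference
#'   maps.
#' @param position 1-based ungapped residue index.
#' @return 1-based column index.
#' @export
column_of <- function(seed, ref_id, position) {
  stopifnot(inherits(seed, "pt_seed"))
  map <- seed$reference_maps[[ref_id]]
  if (is.null(map)) stop(sprintf("'%s' is not a reference sequence", ref_id))
  position <- as.integer(position)
  if (any(position < 1L | position > length(map))) {
    stop(sprintf("position out of range for '%s' (ungapped length %d)",
                 ref_id, length(map)))
  }
  map[position]
}

#' Designate pocket columns from a pocket definition
#'
#' Routes structure residue numbers through the structure-to-sequence map
#' and the reference row's gap pattern to alignment columns, and records
#' them as the seed's designated (pocket) columns. Idempotent: re-running
#' with the same pocket leaves the seed unchanged.
#'
#' @param seed A `pt_seed`.
#' @param pocket A `pt_pocket`.
#' @param struct_map Map from [structure_to_sequence_map()] for the
#'   pocket's reference chain.
#' @param ref_id Seed reference id corresponding to the structure's chain.
#' @return The seed with `designated_columns` set.
#' @export
designate_pocket_columns <- function(seed, pocket, struct_map, ref_id) {
  stopifnot(inherits(seed, "pt_seed"), inherits(pocket, "pt_pocket"))
  key <- as.character(pocket$positions)
  missing <- key[!key %in% names(struct_map)]
  if (length(missing)) {
    stop("pocket positions not resolvable in the structure map: ",
         paste(missing, collapse = ", "))
  }
  seqpos <- unname(struct_map[key])
  cols <- sort(unique(column_of(seed, ref_id, seqpos)))
  seed$designated_columns <- as.integer(cols)
  seed
}

#' Extract the pocket profile (reduced alignment)
#'
#' Concatenates, for every row, the characters at the seed's designated
#' columns. Rows belonging to a swap-group subfamily read the swapped
#' source columns instead, so that structurally equivalent residues land
#' in the same reduced column across subfamilies.
#'
#' @param seed A `pt_seed` with designated columns.
#' @param subject_ids Optional subset of sequence ids to extract.
#' @return An object of class `pt_reduced`: a `pt_alignment` restricted
#'   to the pocket columns, with extra fields `column_sources` (the
#'   designated columns) and `swap_applied` (logical per row).
#' @export
extract_pocket <- function(seed, subject_ids = NULL) {
  stopifnot(inherits(seed, "pt_seed"))
  dc <- seed$designated_columns
  if (length(dc) == 0L) stop("no designated columns; run designate_pocket_columns() first")
  a <- seed$alignment
  ids <- if (is.null(subject_ids)) a$ids else {
    if (!all(subject_ids %in% a$ids)) {
      stop("unknown subject ids: ",
           paste(setdiff(subject_ids, a$ids), collapse = ", "))
    }
    subject_ids
  }
  m <- row_chars(a)[ids, , drop = FALSE]

  # per-row source columns: start from the designated columns, then apply
  # any swap-group permutation the row's subfamily declares
  src <- matrix(rep(dc, each = length(ids)), nrow = length(ids))
  swapped <- rep(FALSE, length(ids))
  for (g in seed$swap_groups) {
    slot_idx <- match(g$columns, dc)
    if (anyNA(slot_idx)) {
      stop("swap group columns must all be designated pocket columns")
    }
    for (tag in names(g$members)) {
      rows <- which(ids %in% g$members[[tag]])
      if (!length(rows)) next
      perm <- g$permutations[[tag]]
      if (!identical(perm, g$columns)) swapped[rows] <- TRUE
      for (k in seq_along(slot_idx)) src[rows, slot_idx[k]] <- perm[k]
    }
  }
  rows <- vapply(seq_along(ids), function(i) {
    paste(m[i, src[i, ]], collapse = "")
  }, character(1))

  out <- alignment(ids, rows)
  out$column_sources <- dc
  out$swap_applied <- stats::setNames(swapped, ids)
  class(out) <- c("pt_reduced", class(out))
  out
}

#' @export
print.pt_reduced <- function(x, ...) {
  cat(sprintf("Pocket profile: %d sequences x %d pocket columns (source columns %s)\n",
              length(x$ids), x$width,
              paste(x$column_sources, collapse = ",")))
  invisible(x)
}

#' Read / write a seed configuration (JSON)
#'
#' The configuration records reference sequences, designated columns and
#' swap groups:
#' `{"references": [{"id": ..., "pdb_id": ..., "chain": ...}],
#'   "designated_columns": [...],
#'   "swap_groups": [{"columns": [...], "permutations": {tag: [...]},
#'                    "members": {tag: [ids]}}]}`.
#'
#' @param json JSON text or file path.
#' @param msa A `pt_alignment` the configuration applies to.
#' @return A `pt_seed`.
#' @export
read_seed_config <- function(json, msa) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  refs <- vapply(obj$references %||% list(), function(r) r$id, character(1))
  groups <- lapply(obj$swap_groups %||% list(), function(g) {
    swap_group(as.integer(g$columns),
               lapply(g$permutations, as.integer),
               lapply(g$members, as.character))
  })
  names(groups) <- NULL
  seed_alignment(msa, reference_ids = refs,
                 designated_columns = obj$designated_columns %||% integer(0),
                 swap_groups = groups)
}

#' @rdname read_seed_config
#' @param seed A `pt_seed`.
#' @param references Optional data frame (`id`, `pdb_id`, `chain`)
#'   describing the reference sequences; defaults to the seed's reference
#'   ids with empty structure fields.
#' @param path Optional output path.
#' @export
write_seed_config <- function(seed, references = NULL, path = NULL) {
  stopifnot(inherits(seed, "pt_seed"))
  if (is.null(references)) {
    ref_ids <- names(seed$reference_maps) %||% character(0)
    references <- data.frame(id = ref_ids,
                             pdb_id = rep("", length(ref_ids)),
                             chain = rep("", length(ref_ids)),
                             stringsAsFactors = FALSE)
  }
  obj <- list(
    references = references,
    designated_columns = seed$designated_columns,
    swap_groups = lapply(seed$swap_groups, function(g) {
      list(columns = g$columns, permutations = g$permutations,
           members = g$members)
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
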