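#' Specification for a toy ligand-bearing structure
#'
#' Describes a synthetic structure whose pocket membership is known by
#' construction: the listed residues get one heavy atom placed inside the
#' cutoff shell around a small het group, every other residue is kept
#' more than 2 angstroms beyond the cutoff.
#'
#' @param n_residues Number of polymer residues.
#' @param pocket_members Residue numbers intended inside the cutoff
#'   (subset of the residue numbers; may be empty).
#' @param cutoff_A Distance cutoff the construction targets (default 5).
#' @param ligand_code Het code of the ligand (default `"LIG"`).
#' @param chain_id Chain label (default `"A"`).
#' @param residue_numbers Optional explicit author numbering (defaults to
#'   `1:n_residues`); allows emulating structures with non-contiguous
#'   numbering.
#' @param seed RNG seed controlling the (small) geometric jitter.
#' @return A list of class `pt_toyspec`.
#' @export
toy_structure_spec <- function(n_residues, pocket_members = integer(0),
                               cutoff_A = 5, ligand_code = "LIG",
                               chain_id = "A", residue_numbers = NULL,
                               seed = 1) {
  if (is.null(residue_numbers)) residue_numbers <- seq_len(n_residues)
  residue_numbers <- as.integer(residue_numbers)
  if (length(residue_numbers) != n_residues) {
    stop("residue_numbers must have length n_residues")
  }
  if (anyDuplicated(residue_numbers)) stop("duplicate residue numbers")
  pocket_members <- as.integer(pocket_members)
  if (!all(pocket_members %in% residue_numbers)) {
    stop("pocket_members must be a subset of the residue numbers")
  }
  if (cutoff_A <= 0) stop("cutoff_A must be > 0")
  if (n_residues > 400L) {
    stop("geometric infeasibility: too many residues for the placement shell")
  }
  structure(list(n_residues = n_residues, pocket_members = pocket_members,
                 cutoff_A = cutoff_A, ligand_code = ligand_code,
                 chain_id = chain_id, residue_numbers = residue_numbers,
                 seed = as.integer(seed)),
            class = "pt_toyspec")
}

#' Generate PDB-format text for a toy structure
#'
#' Residues are 3-atom stubs (N, CA, CB) pointing away from a 4-atom het
#' group at the origin along evenly spread directions; only distances
#' matter to consumers. Pocket members place their CB inside the cutoff
#' (at `cutoff_A - 0.8` from the nearest ligand atom, minus a small
#' seeded jitter); all other residues sit entirely beyond
#' `cutoff_A + 2`. Output is deterministic per seed.
#'
#' @param spec A [toy_structure_spec()].
#' @return PDB-format text (character scalar), parseable with
#'   [parse_pdb()].
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "pt_toyspec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  lig <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.2, 0), c(0, 0, 1.2))
  n <- spec$n_residues
  # evenly spread unit directions (golden-angle spiral on the sphere)
  i <- seq_len(n)
  zc <- 1 - 2 * (i - 0.5) / max(n, 2L)
  rc <- sqrt(pmax(0, 1 - zc^2))
  th <- i * pi * (3 - sqrt(5))
  u <- cbind(rc * cos(th), rc * sin(th), zc)

  res_names <- sample(c("ALA", "LEU", "SER", "VAL", "PHE", "THR", "GLY",
                        "MET", "ILE", "TYR"), n, replace = TRUE)
  lines <- character(0)
  serial <- 0L
  emit <- function(record, name4, resname, chain, resnum, xyz, element) {
    serial <<- serial + 1L
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name4, resname, chain, resnum,
            xyz[1L], xyz[2L], xyz[3L], 1.00, 0.00, element)
  }
  for (k in seq_len(n)) {
    num <- spec$residue_numbers[k]
    dir <- u[k, ]
    if (num %in% spec$pocket_members) {
      anchor <- lig[(k %% 4L) + 1L, ]
      cb <- anchor + dir * (spec$cutoff_A - 0.8 - stats::runif(1, 0, 0.3))
    } else {
      cb <- dir * (spec$cutoff_A + 3.5 + stats::runif(1, 0, 1.5))
    }
    ca <- cb + dir * 1.5
    nn <- cb + dir * 3.0
    lines <- c(lines,
               emit("ATOM", "N", res_names[k], spec$chain_id, num, nn, "N"),
               emit("ATOM", "CA", res_names[k], spec$chain_id, num, ca, "C"),
               emit("ATOM", "CB", res_names[k], spec$chain_id, num, cb, "C"))
  }
  lines <- c(lines, "TER")
  lig_names <- c("C1", "C2", "C3", "O1")
  lig_elems <- c("C", "C", "C", "O")
  for (j in 1:4) {
    lines <- c(lines,
               emit("HETATM", lig_names[j], spec$ligand_code, spec$chain_id,
                    900L, lig[j, ], lig_elems[j]))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Synthetic stand-in for a packaged reference structure
#'
#' Builds a toy structure (see [make_toy_structure()]) whose author
#' residue numbering and pocket membership reproduce a packaged pocket
#' definition: the packaged positions are placed within the cutoff of a
#' het group carrying the reference's ligand code, and a deterministic
#' set of filler residues is placed well outside. This is a synthetic
#' object — its coordinates have nothing to do with the real crystal
#' structure; it exists so the distance-based pocket detection can be
#' exercised against the published position list without a structure
#' download.
#'
#' @param family `"AOx"` (reference 1NAA, ligand ABL) or `"AmDH"`
#'   (reference 1C1D).
#' @param n_filler Number of non-pocket residues to add (default 40).
#' @return PDB-format text.
#' @export
synthetic_reference_structure <- function(family = c("AOx", "AmDH"),
                                          n_filler = 40) {
  family <- match.arg(family)
  pocket <- packaged_pocket(family)
  lo <- min(pocket$positions) - 20L
  hi <- max(pocket$positions) + 20L
  candidates <- setdiff(seq(lo, hi), pocket$positions)
  old <- local_seed(20210802L)
  filler <- sort(sample(candidates, n_filler))
  restore_seed(old)
  numbers <- sort(c(pocket$positions, filler))
  spec <- toy_structure_spec(
    n_residues = length(numbers),
    pocket_members = pocket$positions,
    cutoff_A = pocket$cutoff_A,
    ligand_code = if (nzchar(pocket$ligand_code)) pocket$ligand_code else "LIG",
    chain_id = "A",
    residue_numbers = numbers,
    seed = 20210802L
  )
  make_toy_structure(spec)
}

#' Specification for a simulated enzyme superfamily
#'
#' States the world the family simulator generates: `n_families`
#' subfamilies sharing one background consensus, each subfamily carrying
#' its own residue signature at a few pocket columns. Within a family the
#' signature is conserved up to `within_rate`; every non-signature column
#' (pocket or background) mutates independently at `background_rate`.
#'
#' @param n_families Number of subfamilies (default 3).
#' @param seqs_per_family Sequences per subfamily (default 20).
#' @param profile_width Pocket columns (default 21, a typical
#'   substrate-binding-pocket profile size).
#' @param background_width Non-pocket columns (default 150).
#' @param n_signature Signature columns per family (default 6) when
#'   `signature_positions` is not given.
#' @param signature_positions Optional named list: per family, an
#'   integer-named character vector pocket-column -> residue.
#' @param within_rate Per-site mutation probability at signature columns
#'   (default 0.05).
#' @param background_rate Per-site mutation probability elsewhere
#'   (default 0.2).
#' @param seed RNG seed (default 42).
#' @return A list of class `pt_famspec`.
#' @export
family_sim_spec <- function(n_families = 3, seqs_per_family = 20,
                            profile_width = 21, background_width = 150,
                            n_signature = 6, signature_positions = NULL,
                            within_rate = 0.05, background_rate = 0.2,
                            seed = 42) {
  if (within_rate < 0 || within_rate > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("mutation rates must lie in [0, 1]")
  }
  if (n_families < 2L) {
    warning("fewer than 2 families: classification benchmarks are degenerate")
  }
  if (!is.null(signature_positions)) {
    cols <- unique(unlist(lapply(signature_positions,
                                 function(v) as.integer(names(v)))))
    if (any(cols < 1L | cols > profile_width)) {
      stop("signature columns must lie within the pocket profile")
    }
  } else if (n_signature > profile_width) {
    stop("n_signature exceeds profile_width")
  }
  structure(list(n_families = as.integer(n_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 profile_width = as.integer(profile_width),
                 background_width = as.integer(background_width),
                 n_signature = as.integer(n_signature),
                 signature_positions = signature_positions,
                 within_rate = within_rate,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "pt_famspec")
}

#' Simulate an enzyme superfamily with planted pocket signatures
#'
#' Generates the alignment (pocket plus background columns, pocket
#' columns recorded), an annotation table assigning family `k` the
#' pseudo-EC `9.9.9.k`, and the ground-truth family map. All draws come
#' from one seeded generator: the same spec yields the identical set.
#'
#' @param spec A [family_sim_spec()].
#' @return A list of class `pt_famset`: `alignment` (`pt_alignment`),
#'   `annotations` (`pt_annotations`), `truth` (named id -> family
#'   label), `designated_columns` (absolute pocket column indices),
#'   `signature_positions` (per family), `spec`.
#' @export
simulate_families <- function(spec) {
  stopifnot(inherits(spec, "pt_famspec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  total_w <- spec$profile_width + spec$background_width
  pocket_cols <- sort(sample.int(total_w, spec$profile_width))
  consensus <- sample(AA_ALPHABET, total_w, replace = TRUE)

  sig <- spec$signature_positions
  if (is.null(sig)) {
    sig_cols <- sort(sample.int(spec$profile_width, spec$n_signature))
    sig <- lapply(seq_len(spec$n_families), function(k) {
      stats::setNames(character(length(sig_cols)), sig_cols)
    })
    for (j in seq_along(sig_cols)) {
      res <- sample(AA_ALPHABET, spec$n_families)  # distinct per family
      for (k in seq_len(spec$n_families)) sig[[k]][j] <- res[k]
    }
    names(sig) <- paste0("family", seq_len(spec$n_families))
  }
  fam_names <- names(sig)

  mutate <- function(chars, rate) {
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1L)
      }, character(1))
    }
    chars
  }

  ids <- character(0)
  rows <- character(0)
  truth <- character(0)
  for (k in seq_len(spec$n_families)) {
    sig_abs <- pocket_cols[as.integer(names(sig[[k]]))]
    for (i in seq_len(spec$seqs_per_family)) {
      chars <- consensus
      chars[sig_abs] <- unname(sig[[k]])
      chars[sig_abs] <- mutate(chars[sig_abs], spec$within_rate)
      bg <- setdiff(seq_len(total_w), sig_abs)
      chars[bg] <- mutate(chars[bg], spec$background_rate)
      id <- sprintf("%s_seq%02d", fam_names[k], i)
      ids <- c(ids, id)
      rows <- c(rows, paste(chars, collapse = ""))
      truth <- c(truth, stats::setNames(fam_names[k], id))
    }
  }
  aln <- alignment(ids, rows)
  fam_idx <- match(truth, fam_names)
  ann <- annotations(id = ids,
                     ec = sprintf("9.9.9.%d", fam_idx),
                     substrate = sprintf("synthetic substrate %d", fam_idx),
                     evidence = TRUE,
                     organism = sprintf("synthetic organism %d", fam_idx))
  structure(list(alignment = aln, annotations = ann, truth = truth,
                 designated_columns = pocket_cols,
                 signature_positions = sig, spec = spec),
            class = "pt_famset")
}

#' @export
print.pt_famset <- function(x, ...) {
  cat(sprintf("Synthetic family set: %d families x %d sequences, %d pocket + %d background columns\n",
              x$spec$n_families, x$spec$seqs_per_family,
              x$spec$profile_width, x$spec$background_width))
  invisible(x)
}

#' Extract the pocket profile of a simulated family set
#'
#' @param sim A `pt_famset`.
#' @return A `pt_reduced` over the recorded pocket columns.
#' @export
family_pocket_profile <- function(sim) {
  stopifnot(inherits(sim, "pt_famset"))
  seed <- seed_alignment(sim$alignment,
                         designated_columns = sim$designated_columns)
  extract_pocket(seed)
}

# hold-one-out nearest-neighbour accuracy against the truth labels
holdout_accuracy <- function(a, truth, model = "p") {
  dm <- pairwise_distance(a, model = model)
  n <- length(dm$ids)
  correct <- vapply(seq_len(n), function(i) {
    others <- dm$ids[-i]
    d <- dm$d[i, -i]
    nb <- others[order(d, others)][1L]
    truth[[nb]] == truth[[dm$ids[i]]]
  }, logical(1))
  mean(correct)
}

#' Benchmark pocket-only against full-length classification
#'
#' Runs the whole pipeline — column extraction, distances, neighbor
#' joining, class clustering, and hold-one-out nearest-neighbour
#' prediction — twice on a simulated family set: once on the designated
#' pocket columns only and once on all columns. The comparison realizes
#' the premise that the few binding-site positions carry most of the
#' functional signal of the full-length alignment.
#'
#' @param sim A `pt_famset` from [simulate_families()].
#' @return Named numeric vector: `pocket_accuracy`, `full_accuracy`,
#'   `pocket_monophyly_fraction`, `full_monophyly_fraction`.
#' @export
benchmark_pocket_vs_full <- function(sim) {
  stopifnot(inherits(sim, "pt_famset"))
  pocket <- family_pocket_profile(sim)
  full <- sim$alignment
  labels <- classify_promiscuity(sim$annotations)

  monophyly <- function(a) {
    tr <- nj_tree(pairwise_distance(a, model = "poisson"))
    cs <- class_clustering(tr, labels)
    attr(cs, "single_block_fraction")
  }
  c(pocket_accuracy = holdout_accuracy(pocket, sim$truth),
    full_accuracy = holdout_accuracy(full, sim$truth),
    pocket_monophyly_fraction = monophyly(pocket),
    full_monophyly_fraction = monophyly(full))
}
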