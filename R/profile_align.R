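#' Position-specific profile of a seed alignment
#'
#' Per-column amino-acid frequencies with a Laplace pseudocount, turned
#' into log-odds scores against a uniform background of 1/20. Gaps do not
#' contribute counts; a column occupied mostly by gaps therefore scores
#' close to zero for every residue.
#'
#' @param seed A `pt_seed` or `pt_alignment`.
#' @param pseudocount Pseudocount added per residue type (default 0.1).
#' @return Matrix 20 x width of log-odds (base 2) scores, rownames the
#'   amino-acid alphabet.
#' @export
seed_profile <- function(seed, pseudocount = 0.1) {
  a <- if (inherits(seed, "pt_seed")) seed$alignment else seed
  stopifnot(inherits(a, "pt_alignment"))
  m <- row_chars(a)
  counts <- vapply(seq_len(a$width), function(j) {
    tab <- table(factor(m[, j], levels = AA_ALPHABET))
    as.integer(tab)
  }, integer(20))
  n <- colSums(counts)
  freq <- sweep(counts + pseudocount, 2L, n + 20 * pseudocount, "/")
  sc <- log2(freq * 20)
  rownames(sc) <- AA_ALPHABET
  sc
}

#' Align a new sequence to a frozen seed profile
#'
#' Global dynamic-programming alignment of an ungapped sequence against
#' the position-specific profile of the seed, with affine gap penalties.
#' The seed itself is never modified: residues of the new sequence that do
#' not fit any seed column are reported as insertions (position = seed
#' column they follow, 0 for an N-terminal insertion) and left out of the
#' returned gapped row, which always has the seed's width. Ties are broken
#' deterministically: match preferred over a column gap, which is
#' preferred over an insertion, then leftmost placement.
#'
#' @param seed A `pt_seed` (or plain `pt_alignment`).
#' @param new_seq Ungapped amino-acid sequence (character scalar).
#' @param gap_open Gap opening penalty in score units (default 11).
#' @param gap_extend Per-position gap extension penalty (default 1); a gap
#'   of length L costs `gap_open + gap_extend * L`.
#' @param pseudocount Profile pseudocount, see [seed_profile()].
#' @return List with elements `row` (gapped row of seed width), `score`
#'   (optimal alignment score), and `insertions` (data frame
#'   `after_column`, `inserted`).
#' @examples
#' a <- alignment(c("r1", "r2"), c("AKC-DE", "AKCFDE"))
#' s <- seed_alignment(a)
#' profile_align(s, "AKCDE")$row
#' @export
profile_align <- function(seed, new_seq, gap_open = 11, gap_extend = 1,
                          pseudocount = 0.1) {
  prof <- seed_profile(seed, pseudocount)
  new_seq <- toupper(new_seq)
  if (!nzchar(new_seq)) stop("new_seq must have length >= 1")
  s <- strsplit(new_seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(s, AA_ALPHABET)
  if (length(bad)) {
    stop("invalid characters in sequence: ", paste(unique(bad), collapse = ", "))
  }
  W <- ncol(prof)
  m <- length(s)
  si <- match(s, AA_ALPHABET)

  NEG <- -1e18
  oe <- gap_open + gap_extend
  # Gotoh state matrices, (m+1) x (W+1); row i = i sequence residues
  # consumed, col j = j profile columns consumed
  M <- matrix(NEG, m + 1L, W + 1L)  # s[i] placed in column j
  D <- matrix(NEG, m + 1L, W + 1L)  # column j gapped ('-' in output row)
  I <- matrix(NEG, m + 1L, W + 1L)  # s[i] inserted after column j
  # traceback pointers: predecessor state (1=M, 2=D, 3=I)
  tbM <- matrix(0L, m + 1L, W + 1L)
  tbD <- matrix(0L, m + 1L, W + 1L)
  tbI <- matrix(0L, m + 1L, W + 1L)

  M[1L, 1L] <- 0
  for (j in 2L:(W + 1L)) {
    D[1L, j] <- -(gap_open + gap_extend * (j - 1L))
    tbD[1L, j] <- if (j == 2L) 1L else 2L
  }
  for (i in seq_len(m) + 1L) {
    I[i, 1L] <- -(gap_open + gap_extend * (i - 1L))
    tbI[i, 1L] <- if (i == 2L) 1L else 3L
  }

  # deterministic tie-break: M over D over I
  pick <- function(vals) which(vals == max(vals))[1L]

  for (i in 2L:(m + 1L)) {
    for (j in 2L:(W + 1L)) {
      cand <- c(M[i - 1L, j - 1L], D[i - 1L, j - 1L], I[i - 1L, j - 1L])
      k <- pick(cand)
      M[i, j] <- prof[si[i - 1L], j - 1L] + cand[k]
      tbM[i, j] <- k

      cand <- c(M[i, j - 1L] - oe, D[i, j - 1L] - gap_extend,
                I[i, j - 1L] - oe)
      k <- pick(cand)
      D[i, j] <- cand[k]
      tbD[i, j] <- k

      cand <- c(M[i - 1L, j] - oe, D[i - 1L, j] - oe,
                I[i - 1L, j] - gap_extend)
      k <- pick(cand)
      I[i, j] <- cand[k]
      tbI[i, j] <- k
    }
  }

  finals <- c(M[m + 1L, W + 1L], D[m + 1L, W + 1L], I[m + 1L, W + 1L])
  state <- pick(finals)
  score <- finals[state]

  # traceback
  out <- character(W)
  ins_pos <- integer(0)
  ins_chr <- character(0)
  i <- m + 1L; j <- W + 1L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      out[j - 1L] <- s[i - 1L]
      state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      out[j - 1L] <- GAP
      state <- tbD[i, j]; j <- j - 1L
    } else {
      ins_pos <- c(ins_pos, j - 1L)
      ins_chr <- c(ins_chr, s[i - 1L])
      state <- tbI[i, j]; i <- i - 1L
    }
  }
  insertions <- if (length(ins_pos)) {
    agg <- tapply(rev(ins_chr), rev(ins_pos), paste, collapse = "")
    data.frame(after_column = as.integer(names(agg)),
               inserted = as.character(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(after_column = integer(0), inserted = character(0),
               stringsAsFactors = FALSE)
  }
  list(row = paste(out, collapse = ""), score = unname(score),
       insertions = insertions)
}

#' Append a profile-aligned sequence to an alignment
#'
#' Convenience wrapper around [profile_align()]: aligns `new_seq` and
#' returns the seed's alignment with the new gapped row appended. The seed
#' columns are preserved exactly; insertions are dropped (reported via
#' `attr(, "insertions")`).
#'
#' @inheritParams profile_align
#' @param new_id Identifier for the added sequence.
#' @return A `pt_alignment` with one extra row.
#' @export
add_sequence <- function(seed, new_id, new_seq, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(seed, "pt_seed"))
  res <- profile_align(seed, new_seq, gap_open, gap_extend)
  a <- seed$alignment
  out <- alignment(c(a$ids, new_id), c(unname(a$rows), res$row))
  attr(out, "insertions") <- res$insertions
  out
}
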