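# Independent oracles and fixture builders used across the suite.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_alignment <- function(n, width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alignment(sprintf("s%03d", seq_len(n)),
            replicate(n, paste(sample(AA20, width, replace = TRUE),
                               collapse = "")))
}

# naive all-pairs distance scan: residues whose minimal heavy-atom distance
# to any ligand heavy atom is within the cutoff
brute_force_pocket <- function(model, ligand_atoms, cutoff) {
  prot <- model$atoms[!model$atoms$is_hetero & model$atoms$element != "H", ]
  lig_key <- unique(paste(ligand_atoms$chain, ligand_atoms$resnum,
                          ligand_atoms$icode))
  prot <- prot[!(paste(prot$chain, prot$resnum, prot$icode) %in% lig_key), ]
  hits <- integer(0)
  for (rn in unique(prot$resnum)) {
    at <- prot[prot$resnum == rn, ]
    found <- FALSE
    for (i in seq_len(nrow(at))) {
      for (j in seq_len(nrow(ligand_atoms))) {
        dd <- sqrt((at$x[i] - ligand_atoms$x[j])^2 +
                     (at$y[i] - ligand_atoms$y[j])^2 +
                     (at$z[i] - ligand_atoms$z[j])^2)
        if (dd <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, rn)
  }
  sort(hits)
}

# exhaustive enumeration over all global alignments of a sequence against
# a profile, affine gaps (gap of length L costs open + extend * L)
brute_force_profile_score <- function(prof, seq_chars, gap_open, gap_extend) {
  si <- match(seq_chars, rownames(prof))
  m <- length(si)
  W <- ncol(prof)
  rec <- function(i, j, prev) {
    if (i > m && j > W) return(0)
    best <- -Inf
    if (i <= m && j <= W) {
      best <- max(best, prof[si[i], j] + rec(i + 1L, j + 1L, "M"))
    }
    if (j <= W) {
      cost <- if (identical(prev, "D")) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1L, "D"))
    }
    if (i <= m) {
      cost <- if (identical(prev, "I")) gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1L, j, "I"))
    }
    best
  }
  rec(1L, 1L, "start")
}

# unrooted monophyly by bipartition enumeration: some edge must split the
# leaf set into exactly (tips, rest)
brute_force_monophyletic <- function(tree, tips) {
  all_tips <- tree$tip.label
  # trivial splits (single tip on either side) are always attainable
  if (length(tips) <= 1L || length(tips) >= length(all_tips) - 1L) return(TRUE)
  target <- sort(tips)
  parts <- ape::prop.part(tree)
  for (p in parts) {
    side <- sort(all_tips[p])
    other <- sort(setdiff(all_tips, side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  # prop.part omits trivial (single-tip) splits; handled above
  FALSE
}

# naive relief weights: explicit double loop over sequences
brute_force_relief <- function(ra, groupA, groupB) {
  ids <- c(groupA, groupB)
  chars <- strsplit(unname(ra$rows[ids]), "", fixed = TRUE)
  names(chars) <- ids
  in_A <- ids %in% groupA
  W <- length(chars[[1L]])
  ham <- function(a, b) sum(chars[[a]] != chars[[b]])
  acc <- numeric(W)
  for (i in seq_along(ids)) {
    same <- ids[in_A == in_A[i] & ids != ids[i]]
    other <- ids[in_A != in_A[i]]
    dh <- vapply(same, ham, numeric(1), a = ids[i])
    hit <- same[order(dh, same)][1L]
    dm <- vapply(other, ham, numeric(1), a = ids[i])
    miss <- other[order(dm, other)][1L]
    acc <- acc + (chars[[i]] != chars[[miss]]) - (chars[[i]] != chars[[hit]])
  }
  acc / length(ids)
}

# two-sided Fisher exact p by direct hypergeometric summation
brute_force_fisher <- function(a, b, c, d) {
  # table rbind(c(a, b), c(c, d)); margins fixed
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a swap-group fixture mirroring the human/fungal ADH loop: subfamily "human"
# reads the three loop columns in natural order (L, W, F), subfamily
# "fungal" carries the structurally equivalent residues in reversed
# sequential order (F, W, L) and reads them through the reversing
# permutation, so both subfamilies land L/W/F in the same reduced slots.
swap_fixture <- function() {
  #            123456789
  rows <- c(hu1 = "AALWFDEKQ",
            hu2 = "AALWFDEKQ",
            fu1 = "AAFWLDEKQ",
            fu2 = "AAFWLDEKQ")
  a <- alignment(names(rows), unname(rows))
  sg <- swap_group(
    columns = c(3L, 4L, 5L),
    permutations = list(human = c(3L, 4L, 5L), fungal = c(5L, 4L, 3L)),
    members = list(human = c("hu1", "hu2"), fungal = c("fu1", "fu2"))
  )
  seed_alignment(a, designated_columns = c(3L, 4L, 5L, 7L),
                 swap_groups = list(sg))
}
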