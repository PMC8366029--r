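#' Pairwise distances on an alignment
#'
#' Computes the proportion of mismatching residues over jointly non-gap
#' ("comparable") columns per pair, optionally corrected for multiple
#' substitutions with the Poisson model `d = -ln(1 - p)`. With
#' `complete_deletion`, columns containing any gap are removed once for
#' the whole alignment; with `pairwise_deletion` (the default, which is
#' far less destructive on 19-21 column pocket profiles) comparable
#' columns are counted per pair.
#'
#' @param a A `pt_alignment` or `pt_reduced`.
#' @param model `"poisson"` (default) or `"p"` (uncorrected p-distance).
#' @param gap_rule `"pairwise_deletion"` (default) or
#'   `"complete_deletion"`.
#' @param max_distance Cap applied where `p >= 1` makes the Poisson
#'   correction undefined (default 5.0 substitutions per site). Saturated
#'   pairs (`p >= 1 - 1/width`) trigger a warning listing them.
#' @return An object of class `pt_dist`: list with `ids`, symmetric
#'   matrix `d` (zero diagonal), `model`, and matrix `comparable_sites`.
#' @export
pairwise_distance <- function(a, model = c("poisson", "p"),
                              gap_rule = c("pairwise_deletion",
                                           "complete_deletion"),
                              max_distance = 5) {
  stopifnot(inherits(a, "pt_alignment"))
  model <- match.arg(model)
  gap_rule <- match.arg(gap_rule)
  n <- length(a$ids)
  if (n < 2L) stop("need at least 2 sequences")
  m <- row_chars(a)
  if (gap_rule == "complete_deletion") {
    keep <- colSums(m == GAP) == 0L
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  ng <- m != GAP
  # comparable sites per pair and mismatches, via matrix products
  ngi <- ng * 1L
  comparable <- ngi %*% t(ngi)
  # matches: same residue and both non-gap
  match_count <- matrix(0, n, n)
  for (aa in setdiff(unique(as.vector(m)), GAP)) {
    hit <- (m == aa) * 1L
    match_count <- match_count + hit %*% t(hit)
  }
  if (any(comparable[upper.tri(comparable)] == 0)) {
    idx <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1L, ]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 a$ids[idx[1L]], a$ids[idx[2L]]))
  }
  p <- (comparable - match_count) / comparable
  diag(p) <- 0
  width <- ncol(m)
  if (model == "p") {
    d <- p
  } else {
    saturated <- p >= 1 - 1 / width & row(p) < col(p)
    if (any(saturated)) {
      idx <- which(saturated, arr.ind = TRUE)
      warning("saturated pairs (p near 1): ",
              paste(sprintf("%s/%s", a$ids[idx[, 1L]], a$ids[idx[, 2L]]),
                    collapse = ", "))
    }
    d <- ifelse(p >= 1, max_distance, -log(1 - p))
    d <- pmin(d, max_distance)
  }
  d <- (d + t(d)) / 2  # enforce exact symmetry against float noise
  dimnames(d) <- list(a$ids, a$ids)
  dimnames(comparable) <- list(a$ids, a$ids)
  structure(list(ids = a$ids, d = d, model = model,
                 comparable_sites = comparable),
            class = "pt_dist")
}

#' @export
print.pt_dist <- function(x, ...) {
  cat(sprintf("Distance matrix (%s model): %d sequences\n",
              x$model, length(x$ids)))
  invisible(x)
}

#' Coerce a plain matrix to a pt_dist
#'
#' @param d Symmetric numeric matrix with labelled rows/columns.
#' @param model Model tag to record.
#' @return A `pt_dist`.
#' @export
as_pt_dist <- function(d, model = "p") {
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  }
  structure(list(ids = rownames(d), d = d, model = model,
                 comparable_sites = matrix(NA_integer_, nrow(d), ncol(d))),
            class = "pt_dist")
}

#' Write a distance matrix as TSV
#'
#' Square matrix with a header row and a leading id column.
#'
#' @param dm A `pt_dist`.
#' @param path Output path, or `NULL` to return the text.
#' @export
write_distance_tsv <- function(dm, path = NULL) {
  stopifnot(inherits(dm, "pt_dist"))
  df <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  txt <- paste(utils::capture.output(
    utils::write.table(df, sep = "\t", quote = FALSE, row.names = FALSE)),
    collapse = "\n")
  if (is.null(path)) return(paste0(txt, "\n"))
  writeLines(txt, path)
  invisible(path)
}

#' Neighbor-joining binding-site tree
#'
#' Classic neighbor joining (Q-criterion agglomeration) on a distance
#' matrix. Negative intermediate branch lengths are clamped to zero with
#' the deficit transferred to the sibling edge (so the joined pair's path
#' length is preserved); ties in the Q matrix are broken toward the
#' lowest index pair, making the output deterministic. `method =
#' "bionj"` delegates to the BioNJ variance-weighted variant (negative
#' lengths likewise clamped).
#'
#' @param dm A `pt_dist` (or symmetric labelled matrix).
#' @param method `"nj"` (default) or `"bionj"`.
#' @return An [ape::ape-package] `phylo` tree, unrooted, with branch
#'   lengths in substitutions per site.
#' @export
nj_tree <- function(dm, method = c("nj", "bionj")) {
  method <- match.arg(method)
  if (is.matrix(dm)) dm <- as_pt_dist(dm)
  stopifnot(inherits(dm, "pt_dist"))
  d <- dm$d
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  n <- length(dm$ids)
  if (n < 2L) stop("need at least 2 sequences")

  if (method == "bionj") {
    tr <- ape::bionj(stats::as.dist(d))
    tr$edge.length[tr$edge.length < 0] <- 0
    return(tr)
  }

  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        dm$ids[1L], d[1L, 2L] / 2,
                                        dm$ids[2L], d[1L, 2L] / 2))
    return(tr)
  }

  # active nodes: 1..n are leaves; internal nodes numbered n+1 ...
  labels <- dm$ids
  node_id <- seq_len(n)           # phylo node numbers of active nodes
  next_internal <- 2L * n - 2L    # phylo internal ids count down from root
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  D <- d
  active <- seq_len(n)

  # we build child lists, then convert to phylo at the end
  children <- list()
  internal_counter <- 0L

  repeat {
    k <- length(active)
    if (k == 2L) break
    Dk <- D[active, active, drop = FALSE]
    R <- rowSums(Dk)
    Q <- (k - 2) * Dk - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest index pair on ties (row-major over upper triangle)
    Qu <- Q
    Qu[lower.tri(Qu, diag = TRUE)] <- Inf
    idx <- which(Qu == min(Qu), arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
    i <- idx[1L]; j <- idx[2L]
    dij <- Dk[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (k - 2))
    bj <- dij - bi
    # clamp negatives, moving the deficit to the sibling edge
    if (bi < 0) { bj <- dij; bi <- 0 }
    if (bj < 0) { bi <- dij; bj <- 0 }

    internal_counter <- internal_counter + 1L
    new_node <- n + internal_counter
    children[[internal_counter]] <-
      list(kids = c(node_id[active[i]], node_id[active[j]]),
           lens = c(bi, bj))
    # distances from the new node to the remaining ones
    rest <- active[-c(i, j)]
    dnew <- (D[active[i], rest] + D[active[j], rest] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    nn <- nrow(D)
    D[nn, rest] <- dnew
    D[rest, nn] <- dnew
    node_id <- c(node_id, new_node)
    active <- c(rest, nn)
  }
  # join the last two active nodes with a single edge
  i <- active[1L]; j <- active[2L]
  internal_counter <- internal_counter + 1L
  root <- n + internal_counter
  children[[internal_counter]] <-
    list(kids = c(node_id[i], node_id[j]), lens = c(D[i, j], 0))
  # the final join is an edge, not a node with two branches: put the whole
  # remaining distance on one child and zero on the other, then collapse
  # by reading it as the root of an unrooted tree

  # convert: phylo wants internal nodes numbered n+1..2n-1 with root first
  n_internal <- internal_counter
  # our internal ids are n+1 .. n+n_internal in creation order; root is last.
  # phylo convention: root = n+1. Renumber internal node x -> n + (n_internal + 1 - (x - n)).
  renum <- function(x) {
    ifelse(x <= n, x, n + (n_internal + 1L - (x - n)))
  }
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  for (ic in seq_len(n_internal)) {
    parent <- renum(n + ic)
    for (t in 1:2) {
      edge <- rbind(edge, c(parent, renum(children[[ic]]$kids[t])))
      edge_len <- c(edge_len, children[[ic]]$lens[t])
    }
  }
  tr <- list(edge = edge, edge.length = edge_len,
             tip.label = labels, Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  # the zero-length root edge from the final join is an artifact of the
  # rooted representation of an unrooted tree; leave as is (path lengths
  # between leaves are what matter and are preserved)
  tr
}

#' Leaf-to-leaf path length matrix of a tree
#'
#' Sums branch lengths along the path between every pair of leaves; the
#' independent check that neighbor joining reproduced an additive matrix.
#'
#' @param tree A `phylo`.
#' @return Symmetric matrix labelled by tip.
#' @export
tree_path_lengths <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}

needs_quote <- function(label) grepl("[^A-Za-z0-9_.|/-]", label)

#' Serialize a tree to Newick
#'
#' Branch lengths are written to 6 decimals; labels containing spaces or
#' other special characters are single-quoted (embedded quotes doubled).
#'
#' @param tree A `phylo`.
#' @param path Optional output path.
#' @return Newick text (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_label <- function(lab) {
    if (needs_quote(lab)) paste0("'", gsub("'", "''", lab), "'") else lab
  }
  rec <- function(node, blen) {
    core <- if (node <= n) {
      fmt_label(tree$tip.label[node])
    } else {
      e <- kids[[as.character(node)]]
      paste0("(", paste(vapply(e, function(k) {
        rec(tree$edge[k, 2L], tree$edge.length[k])
      }, character(1)), collapse = ","), ")")
    }
    if (is.na(blen)) core else sprintf("%s:%.6f", core, blen)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  txt <- paste0(rec(root, NA_real_), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse a Newick tree
#'
#' Recursive-descent parser supporting branch lengths, internal labels
#' and single-quoted labels. Structural errors (unbalanced parentheses,
#' trailing garbage) are reported with the character position.
#'
#' @param text Newick string or path to a file containing one.
#' @return A `phylo`.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  s <- strsplit(text, "", fixed = TRUE)[[1L]]
  pos <- 1L
  np <- length(s)
  peek <- function() if (pos <= np) s[pos] else ""
  fail <- function(msg) stop(sprintf("newick parse error at position %d: %s",
                                     pos, msg))
  tips <- character(0)
  edges <- list()
  n_internal <- 0L
  # temporary node ids: negative = internal (creation order), positive = tip
  read_label <- function() {
    if (peek() == "'") {
      pos <<- pos + 1L
      out <- character(0)
      repeat {
        if (pos > np) fail("unterminated quoted label")
        ch <- s[pos]
        if (ch == "'") {
          if (pos + 1L <= np && s[pos + 1L] == "'") {
            out <- c(out, "'"); pos <<- pos + 2L
          } else { pos <<- pos + 1L; break }
        } else { out <- c(out, ch); pos <<- pos + 1L }
      }
      paste(out, collapse = "")
    } else {
      out <- character(0)
      while (pos <= np && !s[pos] %in% c(",", ")", "(", ":", ";")) {
        out <- c(out, s[pos]); pos <<- pos + 1L
      }
      paste(out, collapse = "")
    }
  }
  read_length <- function() {
    if (peek() != ":") return(NA_real_)
    pos <<- pos + 1L
    out <- character(0)
    while (pos <= np && grepl("[0-9eE+.-]", s[pos])) {
      out <- c(out, s[pos]); pos <<- pos + 1L
    }
    v <- suppressWarnings(as.numeric(paste(out, collapse = "")))
    if (is.na(v)) fail("malformed branch length")
    v
  }
  parse_clade <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      n_internal <<- n_internal + 1L
      me <- -n_internal
      repeat {
        child <- parse_clade()
        edges[[length(edges) + 1L]] <<- c(me, child$id, child$len)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      read_label()  # internal label, ignored
      len <- read_length()
      list(id = me, len = len)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("empty leaf label")
      tips <<- c(tips, lab)
      len <- read_length()
      list(id = length(tips), len = len)
    }
  }
  root <- parse_clade()
  if (peek() != ";") fail("expected ';'")
  pos <- pos + 1L
  if (pos <= np && any(nzchar(trimws(s[pos:np])))) fail("trailing characters")
  if (anyDuplicated(tips)) stop("duplicate leaf labels in newick input")

  n <- length(tips)
  if (length(edges) == 0L) stop("newick tree must have at least one edge")
  em <- do.call(rbind, edges)
  renum <- function(x) ifelse(x > 0, x, n - x)  # internal -k -> n + k
  tr <- list(edge = cbind(renum(em[, 1L]), renum(em[, 2L])),
             edge.length = ifelse(is.na(em[, 3L]), 0, em[, 3L]),
             tip.label = tips, Nnode = n_internal)
  storage.mode(tr$edge) <- "integer"
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Rank all sequences by distance to a query
#'
#' @param dm A `pt_dist`.
#' @param query Sequence id.
#' @return Data frame `id`, `distance`, ascending by distance with ties
#'   broken lexicographically; the query itself is excluded.
#' @export
leaf_distance_rank <- function(dm, query) {
  stopifnot(inherits(dm, "pt_dist"))
  if (!query %in% dm$ids) stop(sprintf("query '%s' not in matrix", query))
  others <- setdiff(dm$ids, query)
  dist <- dm$d[query, others]
  ord <- order(dist, others)
  data.frame(id = others[ord], distance = unname(dist[ord]),
             stringsAsFactors = FALSE)
}
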