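EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-|\\*)$"

#' Load a sequence annotation table
#'
#' Reads a TSV with columns `id`, `ec`, `substrate`, `evidence`,
#' `organism`, `tags`. `ec` and `tags` may hold several values separated
#' by `;`. `evidence` is `yes`/`no` (or `TRUE`/`FALSE`). EC strings must
#' match `d.d.d.(d|-|*)`.
#'
#' @param input File path or TSV text.
#' @return An object of class `pt_annotations`: a data frame with
#'   list-columns `ec` and `tags`.
#' @export
load_annotations <- function(input) {
  if (length(input) == 1L && !grepl("[\n\t]", input) && file.exists(input)) {
    df <- utils::read.delim(input, stringsAsFactors = FALSE,
                            colClasses = "character")
  } else {
    df <- utils::read.delim(text = input, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  required <- c("id", "ec", "substrate", "evidence", "organism", "tags")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation table lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in annotation table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  split_multi <- function(x) {
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  ecs <- split_multi(df$ec)
  bad <- vapply(ecs, function(v) any(!grepl(EC_PATTERN, v)), logical(1))
  if (any(bad)) {
    stop(sprintf("malformed EC number for id '%s': %s",
                 df$id[bad][1L], df$ec[bad][1L]))
  }
  out <- data.frame(id = df$id, substrate = df$substrate,
                    evidence = tolower(df$evidence) %in% c("yes", "true", "1"),
                    organism = df$organism, stringsAsFactors = FALSE)
  out$ec <- ecs
  out$tags <- split_multi(df$tags)
  class(out) <- c("pt_annotations", class(out))
  out
}

#' Build an annotation table in code
#'
#' @param id,substrate,evidence,organism Vectors, one entry per sequence.
#' @param ec,tags Lists of character vectors (or character vectors with
#'   `;`-separated multi-values).
#' @return A `pt_annotations`.
#' @export
annotations <- function(id, ec, substrate = "", evidence = TRUE,
                        organism = "", tags = list()) {
  norm <- function(x, n) {
    if (is.character(x)) x <- strsplit(x, ";", fixed = TRUE)
    if (length(x) == 0L) x <- rep(list(character(0)), n)
    lapply(rep_len(x, n), function(v) trimws(v[nzchar(trimws(v))]))
  }
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate ids")
  ecs <- norm(ec, n)
  bad <- vapply(ecs, function(v) any(!grepl(EC_PATTERN, v)), logical(1))
  if (any(bad)) stop("malformed EC number for id '", id[bad][1L], "'")
  out <- data.frame(id = id, substrate = rep_len(substrate, n),
                    evidence = rep_len(evidence, n),
                    organism = rep_len(organism, n),
                    stringsAsFactors = FALSE)
  out$ec <- ecs
  out$tags <- norm(tags, n)
  class(out) <- c("pt_annotations", class(out))
  out
}

#' Classify sequences as substrate-specific or promiscuous
#'
#' A sequence is assigned its EC class when it carries exactly one EC
#' number outside the promiscuous set; anything annotated with a
#' promiscuous code (by default the broad-specificity alcohol
#' dehydrogenase codes `1.1.1.1` and `1.1.1.-`) or with more than one EC
#' number is labelled `"promiscuous"`. Sequences without any EC number
#' are labelled `NA` (unannotated).
#'
#' @param ann A `pt_annotations`.
#' @param promiscuous_ecs EC codes treated as unspecific.
#' @return Named character vector id -> EC class, `"promiscuous"`, or
#'   `NA` for unannotated sequences.
#' @export
classify_promiscuity <- function(ann, promiscuous_ecs = c("1.1.1.1", "1.1.1.-")) {
  stopifnot(inherits(ann, "pt_annotations"))
  lab <- vapply(ann$ec, function(v) {
    if (length(v) == 0L) return(NA_character_)
    if (length(v) > 1L || v %in% promiscuous_ecs) return("promiscuous")
    v
  }, character(1))
  stats::setNames(lab, ann$id)
}

node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  edges <- tree$edge[order(-tree$edge[, 1L]), , drop = FALSE]
  # postorder-ish: children have higher numbers than... not guaranteed; loop
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; c <- tr$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' How well annotation classes cluster on a tree
#'
#' For every specific class, counts the minimal number of maximal
#' subtrees whose (non-promiscuous) leaves all belong to that class
#' ("blocks": 1 = monophyletic) and the best-clade purity (the maximum
#' over clades of class leaves in the clade divided by clade size).
#' Promiscuous leaves are ignored when judging clade purity if
#' `ignore_promiscuous` (they neither break nor support a block), which
#' mirrors reading a coloured tree while skipping black dots.
#'
#' @param tree A `phylo` whose tips are sequence ids.
#' @param labels Named character vector from [classify_promiscuity()]
#'   (every leaf must be present; `NA` treated like promiscuous).
#' @param ignore_promiscuous Logical, default `TRUE`.
#' @return An object of class `pt_class_summary`: data frame per class
#'   (`class`, `n_leaves`, `n_blocks`, `best_purity`) with attribute
#'   `single_block_fraction`.
#' @export
class_clustering <- function(tree, labels, ignore_promiscuous = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    stop("leaves missing from labels: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  }
  lab <- unname(labels[tips])
  lab[is.na(lab)] <- "promiscuous"
  classes <- sort(setdiff(unique(lab), "promiscuous"))
  if (length(classes) == 0L) stop("no specific classes among the leaves")
  sets <- node_tip_sets(tree)
  n <- length(tips)

  res <- lapply(classes, function(cl) {
    members <- which(lab == cl)
    others <- if (ignore_promiscuous) {
      which(!lab %in% c(cl, "promiscuous"))
    } else {
      which(lab != cl)
    }
    # blocks on the unrooted tree: root at a non-class leaf when one
    # exists so that monophyly is judged on bipartitions, not on an
    # arbitrary root inside the class
    tr <- tree
    if (length(others)) {
      tr <- ape::root(tree, outgroup = tips[others[1L]], resolve.root = TRUE)
      sets_r <- node_tip_sets(tr)
      lab_r <- lab[match(tr$tip.label, tips)]
      members_r <- which(lab_r == cl)
      others_r <- if (ignore_promiscuous) {
        which(!lab_r %in% c(cl, "promiscuous"))
      } else {
        which(lab_r != cl)
      }
    } else {
      sets_r <- sets
      lab_r <- lab
      members_r <- members
      others_r <- integer(0)
    }
    nn <- length(tr$tip.label)
    pure <- vapply(seq_along(sets_r), function(v) {
      tt <- sets_r[[v]]
      any(tt %in% members_r) && !any(tt %in% others_r)
    }, logical(1))
    # maximal pure nodes: pure, with an impure (or absent) parent
    parent <- rep(NA_integer_, length(sets_r))
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    maximal <- pure & (is.na(parent) | !pure[ifelse(is.na(parent), 1L, parent)])
    n_blocks <- sum(maximal)
    purity <- max(vapply(seq_along(sets_r), function(v) {
      tt <- sets_r[[v]]
      sum(tt %in% members_r) / length(tt)
    }, numeric(1)))
    data.frame(class = cl, n_leaves = length(members), n_blocks = n_blocks,
               best_purity = purity, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "single_block_fraction") <- mean(out$n_blocks == 1L)
  class(out) <- c("pt_class_summary", class(out))
  out
}

#' Predict substrate class of unannotated sequences by pocket similarity
#'
#' k-nearest-neighbour vote on pocket-profile distances. Promiscuous
#' neighbours never vote but the nearest one is reported. Ties between
#' classes are broken toward the class with the smaller mean distance
#' among its voting neighbours, then toward the class of the
#' lexicographically smallest neighbour id.
#'
#' @param ra A `pt_reduced` (or `pt_alignment`) containing both labelled
#'   sequences and the queries.
#' @param labels Named vector from [classify_promiscuity()]; ids absent
#'   or `NA` are treated as unlabelled.
#' @param queries Ids to predict (must be rows of `ra`).
#' @param k Number of voting neighbours (default 1).
#' @param model Distance model passed to [pairwise_distance()]
#'   (default `"p"`).
#' @return Data frame per query: `id`, `predicted`, `tie` (logical),
#'   plus a list-column `neighbors` of data frames
#'   (`id`, `class`, `distance`).
#' @export
predict_labels <- function(ra, labels, queries, k = 1, model = "p") {
  stopifnot(inherits(ra, "pt_alignment"))
  if (!all(queries %in% ra$ids)) {
    stop("queries not in alignment: ",
         paste(setdiff(queries, ra$ids), collapse = ", "))
  }
  lab <- labels[ra$ids]
  names(lab) <- ra$ids
  eligible <- names(lab)[!is.na(lab) & lab != "promiscuous" &
                           !names(lab) %in% queries]
  promisc <- names(lab)[!is.na(lab) & lab == "promiscuous"]
  if (length(eligible) == 0L) stop("no eligible labelled neighbours")
  dm <- pairwise_distance(ra, model = model)

  res <- lapply(queries, function(q) {
    dist <- dm$d[q, eligible]
    ord <- order(dist, eligible)
    kk <- min(k, length(eligible))
    nb <- eligible[ord][seq_len(kk)]
    nbd <- unname(dist[ord][seq_len(kk)])
    votes <- table(unname(lab[nb]))
    top <- names(votes)[votes == max(votes)]
    # a boundary tie: excluded neighbours sit at exactly the k-th distance
    # with a class not already selected at that distance
    boundary <- eligible[dist == nbd[kk]]
    tie <- length(top) > 1L ||
      length(unique(unname(lab[boundary]))) > 1L
    if (length(top) > 1L) {
      meand <- vapply(top, function(cl) mean(nbd[lab[nb] == cl]), numeric(1))
      top <- top[meand == min(meand)]
      if (length(top) > 1L) {
        # class of the lexicographically smallest neighbour id among ties
        cand <- nb[lab[nb] %in% top]
        top <- unname(lab[cand[order(cand)][1L]])
      }
    }
    nearest_prom <- if (length(promisc)) {
      pd <- dm$d[q, setdiff(promisc, q)]
      if (length(pd)) {
        po <- order(pd, setdiff(promisc, q))[1L]
        data.frame(id = setdiff(promisc, q)[po],
                   distance = unname(pd[po]), stringsAsFactors = FALSE)
      } else NULL
    } else NULL
    list(predicted = top[1L], tie = tie,
         neighbors = data.frame(id = nb, class = unname(lab[nb]),
                                distance = nbd, stringsAsFactors = FALSE),
         nearest_promiscuous = nearest_prom)
  })
  out <- data.frame(id = queries,
                    predicted = vapply(res, `[[`, character(1), "predicted"),
                    tie = vapply(res, `[[`, logical(1), "tie"),
                    stringsAsFactors = FALSE)
  out$neighbors <- lapply(res, `[[`, "neighbors")
  out$nearest_promiscuous <- lapply(res, `[[`, "nearest_promiscuous")
  out
}

#' Nearest tagged sequences to a query
#'
#' Ranks the sequences carrying a given organism tag (e.g.
#' `"thermophile"`) by pocket distance to the query — the screen used to
#' shortlist heat-tolerant homologues of a reference enzyme.
#'
#' @param x A `pt_reduced`/`pt_alignment` or a precomputed `pt_dist`.
#' @param query Sequence id.
#' @param tag Tag to filter on.
#' @param ann A `pt_annotations` carrying the tags.
#' @param n Number of hits to return (default all tagged sequences).
#' @param model Distance model when `x` is an alignment.
#' @return Data frame `id`, `organism`, `distance`, ascending.
#' @export
nearest_tagged <- function(x, query, tag, ann, n = Inf, model = "poisson") {
  stopifnot(inherits(ann, "pt_annotations"))
  dm <- if (inherits(x, "pt_dist")) x else pairwise_distance(x, model = model)
  if (!query %in% dm$ids) stop(sprintf("query '%s' not in distance set", query))
  tagged <- ann$id[vapply(ann$tags, function(t) tag %in% t, logical(1))]
  if (length(tagged) == 0L) {
    stop(sprintf("tag '%s' not present in the annotation table", tag))
  }
  tagged <- setdiff(intersect(tagged, dm$ids), query)
  if (length(tagged) == 0L) stop("no tagged sequences besides the query")
  rank <- leaf_distance_rank(dm, query)
  rank <- rank[rank$id %in% tagged, , drop = FALSE]
  rank$organism <- ann$organism[match(rank$id, ann$id)]
  utils::head(rank[, c("id", "organism", "distance")], n)
}

#' Annotation coverage of a reaction universe
#'
#' Percentage of a family's known unique reactions (EC numbers) that are
#' backed by experimental evidence in the annotation table, reported to
#' one decimal: `100 * distinct evidence-backed ECs / universe`.
#'
#' @param ann A `pt_annotations`.
#' @param universe_reaction_count Total number of unique reactions
#'   recorded for the family.
#' @return Percentage, rounded to 1 decimal.
#' @examples
#' # 40 evidence-backed reactions of 55 total
#' ann <- annotations(id = paste0("s", 1:40),
#'                    ec = sprintf("1.1.1.%d", 1:40), evidence = TRUE)
#' annotation_coverage(ann, 55)  # 72.7
#' @export
annotation_coverage <- function(ann, universe_reaction_count) {
  stopifnot(inherits(ann, "pt_annotations"))
  backed <- unique(unlist(ann$ec[ann$evidence], use.names = FALSE))
  n <- length(backed)
  if (universe_reaction_count < n) {
    stop("universe_reaction_count smaller than the evidence-backed count")
  }
  round(100 * n / universe_reaction_count, 1L)
}
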