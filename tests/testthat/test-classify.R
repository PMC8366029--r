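ann_tsv <- paste(
  "id\tec\tsubstrate\tevidence\torganism\ttags",
  "s1\t1.1.1.9\txylitol\tyes\tHomo sapiens\t",
  "s2\t1.1.1.9;1.1.1.14\txylitol; L-iditol\tyes\tSaccharomyces\tthermophile",
  "s3\t1.1.1.1\tethanol\tno\tEscherichia coli\t",
  sep = "\n")

test_that("annotation tables parse, split multi-values and validate", {
  ann <- load_annotations(ann_tsv)
  expect_s3_class(ann, "pt_annotations")
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$ec[[2]], c("1.1.1.9", "1.1.1.14"))
  expect_true(ann$evidence[1])
  expect_false(ann$evidence[3])
  expect_equal(ann$tags[[2]], "thermophile")

  bad_ec <- sub("1.1.1.9\t", "1.1.x\t", ann_tsv, fixed = TRUE)
  expect_error(load_annotations(bad_ec), "malformed EC")
  dup <- paste(ann_tsv, "s1\t1.1.1.2\t\tyes\tx\t", sep = "\n")
  expect_error(load_annotations(dup), "duplicate")
  expect_error(load_annotations("id\tec\nz\t1.1.1.1"), "required columns")
})

test_that("promiscuity rule: single specific EC wins, everything else is promiscuous", {
  ann <- annotations(id = c("a", "b", "c", "d", "e"),
                     ec = list("1.1.1.9", "1.1.1.1", "1.1.1.-",
                               c("1.1.1.9", "1.1.1.14"), character(0)))
  lab <- classify_promiscuity(ann)
  expect_equal(unname(lab[c("a", "b", "c", "d")]),
               c("1.1.1.9", "promiscuous", "promiscuous", "promiscuous"))
  expect_true(is.na(lab["e"]))
  # the promiscuous set is configurable
  lab2 <- classify_promiscuity(ann, promiscuous_ecs = character(0))
  expect_equal(unname(lab2["b"]), "1.1.1.1")
})

test_that("class_clustering counts monophyletic blocks and purity", {
  tr <- read_newick("((a1:1,a2:1):1,((b1:1,b2:1):1,(a3:1,b3:1):1):1);")
  labels <- c(a1 = "X", a2 = "X", a3 = "X", b1 = "Y", b2 = "Y", b3 = "Y")
  cs <- class_clustering(tr, labels)
  x <- cs[cs$class == "X", ]
  expect_equal(x$n_blocks, 2L)  # the a-cherry plus the stranded a3
  expect_equal(x$n_leaves, 3L)
  y <- cs[cs$class == "Y", ]
  expect_equal(y$n_blocks, 2L)  # the b-cherry plus the stranded b3
  expect_equal(y$best_purity, 1)

  # one class on one cherry
  tr2 <- read_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  cs2 <- class_clustering(tr2, c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y"))
  expect_true(all(cs2$n_blocks == 1L))
  expect_true(all(cs2$best_purity == 1))
  expect_equal(attr(cs2, "single_block_fraction"), 1)

  # all leaves one class
  cs3 <- class_clustering(tr2, c(a1 = "X", a2 = "X", b1 = "X", b2 = "X"))
  expect_equal(cs3$n_blocks, 1L)

  expect_error(class_clustering(tr2, c(a1 = "X")), "missing from labels")
})

test_that("promiscuous leaves neither break nor join blocks", {
  tr <- read_newick("((a1:1,p1:1):1,((a2:1,p2:1):1,(b1:1,b2:1):1):1);")
  labels <- c(a1 = "X", a2 = "X", p1 = "promiscuous", p2 = "promiscuous",
              b1 = "Y", b2 = "Y")
  cs <- class_clustering(tr, labels)
  # ignoring promiscuous leaves, the two X leaves form one block
  expect_equal(cs[cs$class == "X", "n_blocks"], 1L)
  cs2 <- class_clustering(tr, labels, ignore_promiscuous = FALSE)
  expect_equal(cs2[cs2$class == "X", "n_blocks"], 2L)
})

test_that("block count is 1 exactly for unrooted-monophyletic classes", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    labels <- stats::setNames(sample(c("X", "Y"), n, replace = TRUE),
                              tr$tip.label)
    if (length(unique(labels)) < 2) next
    cs <- class_clustering(tr, labels)
    for (cl in cs$class) {
      expect_equal(cs[cs$class == cl, "n_blocks"] == 1L,
                   brute_force_monophyletic(tr, names(labels)[labels == cl]),
                   info = sprintf("trial %d class %s", i, cl))
    }
  }
})

test_that("predict_labels transfers the class of identical neighbours at distance 0", {
  a <- alignment(c("q", "n1", "n2"), c("ACDEF", "ACDEF", "WWWWW"))
  labels <- c(n1 = "1.1.1.9", n2 = "1.1.1.14")
  pl <- predict_labels(a, labels, "q", k = 1)
  expect_equal(pl$predicted, "1.1.1.9")
  expect_equal(pl$neighbors[[1]]$distance[1], 0)
  expect_false(pl$tie)
})

test_that("prediction ties resolve toward the lexicographically smaller id", {
  a <- alignment(c("q", "nb", "na"), c("ACDE", "ACDF", "ACDW"))
  labels <- c(nb = "classB", na = "classA")
  pl <- predict_labels(a, labels, "q", k = 1)
  expect_true(pl$tie)
  expect_equal(pl$predicted, "classA")
})

test_that("promiscuous sequences are excluded from voting but reported", {
  a <- alignment(c("q", "p", "n"), c("ACDE", "ACDE", "ACDF"))
  labels <- c(p = "promiscuous", n = "1.1.1.9")
  pl <- predict_labels(a, labels, "q", k = 1)
  expect_equal(pl$predicted, "1.1.1.9")
  expect_equal(pl$nearest_promiscuous[[1]]$id, "p")
  expect_equal(pl$nearest_promiscuous[[1]]$distance, 0)
  expect_error(predict_labels(a, c(p = "promiscuous"), "q"), "no eligible")
})

test_that("prediction is invariant to row order", {
  sim <- simulate_families(family_sim_spec(n_families = 2,
                                           seqs_per_family = 6,
                                           background_width = 30, seed = 9))
  ra <- family_pocket_profile(sim)
  labels <- classify_promiscuity(sim$annotations)
  q <- ra$ids[1]
  p1 <- predict_labels(ra, labels, q)
  set.seed(4)
  perm <- sample(length(ra$ids))
  ra2 <- alignment(ra$ids[perm], unname(ra$rows[perm]))
  p2 <- predict_labels(ra2, labels, q)
  expect_equal(p1$predicted, p2$predicted)
  expect_equal(p1$neighbors[[1]], p2$neighbors[[1]])
})

test_that("held-out classification on the default simulated world is accurate", {
  sim <- simulate_families(family_sim_spec())
  ra <- family_pocket_profile(sim)
  labels <- classify_promiscuity(sim$annotations)
  correct <- vapply(ra$ids, function(q) {
    predict_labels(ra, labels, q, k = 1)$predicted ==
      unname(labels[q])
  }, logical(1))
  expect_gte(mean(correct), 0.9)
})

test_that("nearest_tagged ranks tagged sequences like a brute-force sort", {
  sim <- simulate_families(family_sim_spec(n_families = 2,
                                           seqs_per_family = 8,
                                           background_width = 20, seed = 31))
  ra <- family_pocket_profile(sim)
  ann <- sim$annotations
  set.seed(2)
  tagged_ids <- sample(ann$id, 5)
  ann$tags <- lapply(ann$id, function(i) {
    if (i %in% tagged_ids) "thermophile" else character(0)
  })
  q <- setdiff(ann$id, tagged_ids)[1]
  dm <- pairwise_distance(ra, model = "p")
  got <- nearest_tagged(dm, q, "thermophile", ann, n = 5)
  d <- dm$d[q, tagged_ids]
  want <- tagged_ids[order(d, tagged_ids)]
  expect_equal(got$id, want)
  expect_equal(got$organism,
               ann$organism[match(got$id, ann$id)])
  expect_error(nearest_tagged(dm, q, "halophile", ann), "not present")
})

test_that("a single tagged sequence is returned regardless of distance", {
  a <- alignment(c("q", "far"), c("ACDE", "WWWW"))
  ann <- annotations(id = c("q", "far"), ec = c("1.1.1.9", "1.1.1.9"),
                     organism = c("x", "Thermus thermophilus"),
                     tags = list(character(0), "thermophile"))
  got <- suppressWarnings(nearest_tagged(a, "q", "thermophile", ann))
  expect_equal(got$id, "far")
})

test_that("annotation coverage reproduces the evidence fraction", {
  ann <- annotations(id = paste0("s", 1:40),
                     ec = sprintf("1.1.1.%d", 1:40), evidence = TRUE)
  expect_equal(annotation_coverage(ann, 55), 72.7)
  none <- annotations(id = "s1", ec = "1.1.1.2", evidence = FALSE)
  expect_equal(annotation_coverage(none, 10), 0)
  all_ev <- annotations(id = paste0("s", 1:5), ec = sprintf("1.1.1.%d", 1:5))
  expect_equal(annotation_coverage(all_ev, 5), 100)
  expect_error(annotation_coverage(all_ev, 3), "smaller")
})
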