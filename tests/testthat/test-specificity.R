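test_that("group frequencies are exact relative counts with the gap symbol", {
  a <- alignment(c("a1", "a2", "b1", "b2"),
                 c("MK-", "ML-", "LKA", "LKC"))
  prof <- group_frequencies(a, list(A = c("a1", "a2"), B = c("b1", "b2")))
  expect_equal(unname(prof$A$freq["M", 1]), 1)
  expect_equal(unname(prof$A$freq["K", 2]), 0.5)
  expect_equal(unname(prof$A$freq["L", 2]), 0.5)
  expect_equal(unname(prof$A$freq["-", 3]), 1)
  expect_equal(unname(prof$B$freq["L", 1]), 1)
  expect_equal(unname(prof$B$freq["A", 3]), 0.5)
  expect_true(all(abs(colSums(prof$A$freq) - 1) < 1e-9))

  # identical rows give point masses
  p2 <- group_frequencies(a, list(A = c("a1", "a1x" = "a1")[1],
                                  B = c("b1", "b2")))
  expect_true(all(p2$A$freq %in% c(0, 1)))

  expect_error(group_frequencies(a, list(A = "a1", B = "a1")), "overlap")
  expect_error(group_frequencies(a, list(A = character(0), B = "b1")),
               "at least two|empty")
})

test_that("harmony score hits its boundary values and the JSD oracle", {
  expect_equal(harmony_score(c(M = 0.5, L = 0.5), c(M = 0.5, L = 0.5)), 1)
  expect_equal(harmony_score(c(M = 1, L = 0), c(M = 0, L = 1)), 0)
  # direct Jensen-Shannon summation over {M, L}:
  # m = (0.25, 0.75); JSD = 0.5*KL(pA||m) + 0.5*KL(pB||m) = 0.311278...
  expect_equal(harmony_score(c(M = 0.5, L = 0.5), c(M = 0, L = 1)),
               0.6887219, tolerance = 1e-6)
  expect_error(harmony_score(c(0.5, 0.4), c(1, 0)), "not a normalized")
})

test_that("harmony score is symmetric on random distributions", {
  set.seed(23)
  for (i in 1:50) {
    pA <- stats::runif(21); pA <- pA / sum(pA)
    pB <- stats::runif(21); pB <- pB / sum(pB)
    expect_equal(harmony_score(pA, pB), harmony_score(pB, pA),
                 tolerance = 1e-12)
    expect_gte(harmony_score(pA, pB), 0)
    expect_lte(harmony_score(pA, pB), 1)
  }
})

test_that("position_zscores flags a planted separating position as the minimum", {
  set.seed(31)
  n <- 30
  width <- 12
  planted <- 5L
  rows <- replicate(2 * n, paste(sample(AA20, width, replace = TRUE),
                                 collapse = ""))
  chars <- strsplit(rows, "", fixed = TRUE)
  for (i in seq_len(n)) chars[[i]][planted] <- "M"
  for (i in (n + 1):(2 * n)) chars[[i]][planted] <- "L"
  a <- alignment(sprintf("s%02d", seq_len(2 * n)),
                 vapply(chars, paste, character(1), collapse = ""))
  rep <- position_zscores(a, a$ids[1:n], a$ids[(n + 1):(2 * n)],
                          n_perm = 1000, seed = 77)
  expect_true(rep$flagged[planted])
  expect_lt(rep$z[planted], -3)
  expect_equal(which.min(rep$z), planted)
  # reproducible per seed
  rep2 <- position_zscores(a, a$ids[1:n], a$ids[(n + 1):(2 * n)],
                           n_perm = 1000, seed = 77)
  expect_identical(rep$z, rep2$z)
})

test_that("constant columns yield z = 0 and are never flagged", {
  a <- alignment(sprintf("s%d", 1:8),
                 rep("AAAA", 8))
  rep <- position_zscores(a, a$ids[1:4], a$ids[5:8], n_perm = 100, seed = 1)
  expect_true(all(rep$z == 0))
  expect_false(any(rep$flagged))
})

test_that("the flag rule applies the -3 threshold to a given z vector", {
  z <- c(-4.02, -1.0, 0.0)
  expect_equal(flag_positions(z), c(TRUE, FALSE, FALSE))
  # flag sets grow as the threshold relaxes
  expect_true(all(flag_positions(z, -3) <= flag_positions(z, -2)))
})

test_that("flag sets are monotone in the threshold on real reports", {
  sim <- simulate_families(family_sim_spec(n_families = 2,
                                           seqs_per_family = 10,
                                           background_width = 20, seed = 13))
  ra <- family_pocket_profile(sim)
  ids <- ra$ids
  rep <- position_zscores(ra, ids[1:10], ids[11:20], n_perm = 200, seed = 5)
  f3 <- flag_positions(rep$z, -3)
  f2 <- flag_positions(rep$z, -2)
  expect_true(all(which(f3) %in% which(f2)))
})

test_that("relief weights isolate a single differing position", {
  a <- alignment(c("a1", "a2", "b1", "b2"),
                 c("MKCD", "MKCD", "LKCD", "LKCD"))
  w <- relief_weights(a, c("a1", "a2"), c("b1", "b2"))
  expect_equal(w, c(1, 0, 0, 0))
  # identical groups: all zero
  w0 <- relief_weights(alignment(c("a1", "a2", "b1", "b2"), rep("MKCD", 4)),
                       c("a1", "a2"), c("b1", "b2"))
  expect_equal(w0, rep(0, 4))
})

test_that("relief weights equal the brute-force nearest-neighbour oracle", {
  set.seed(41)
  for (i in 1:5) {
    a <- random_alignment(6, 8)
    gA <- a$ids[1:3]
    gB <- a$ids[4:6]
    expect_equal(relief_weights(a, gA, gB), brute_force_relief(a, gA, gB),
                 tolerance = 1e-12)
  }
})

test_that("relief weights are invariant to residue relabelling", {
  set.seed(43)
  a <- random_alignment(8, 10)
  gA <- a$ids[1:4]
  gB <- a$ids[5:8]
  w1 <- relief_weights(a, gA, gB)
  # permute the amino-acid alphabet
  perm <- stats::setNames(sample(AA20), AA20)
  rows2 <- vapply(strsplit(unname(a$rows), ""), function(ch) {
    paste(perm[ch], collapse = "")
  }, character(1))
  a2 <- alignment(a$ids, rows2)
  expect_equal(relief_weights(a2, gA, gB), w1)
})

test_that("two-sample logo flags strong enrichment and spares tiny samples", {
  # 18/20 M in group A versus 2/20 M in group B at one position
  rowsA <- c(rep("M", 18), rep("L", 2))
  rowsB <- c(rep("M", 2), rep("L", 18))
  a <- alignment(c(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20)),
                 c(rowsA, rowsB))
  prof <- group_frequencies(a, list(A = sprintf("a%02d", 1:20),
                                    B = sprintf("b%02d", 1:20)))
  enr <- two_sample_logo(prof$A, prof$B, alpha = 0.05)
  m_row <- enr[enr$residue == "M", ]
  expect_equal(m_row$group, "A")
  expect_equal(m_row$delta_f, 0.8)
  # independent p-value by direct hypergeometric summation
  expect_equal(m_row$p, brute_force_fisher(18, 2, 2, 18), tolerance = 1e-9)

  # identical profiles: nothing reported
  same <- group_frequencies(a, list(A = sprintf("a%02d", 1:10),
                                    B = sprintf("a%02d", 11:20)))
  expect_equal(nrow(two_sample_logo(same$A, same$B)), 0L)

  # n = 2 per group with a single mismatch cannot reach significance
  b <- alignment(c("a1", "a2", "b1", "b2"), c("M", "M", "M", "L"))
  p2 <- group_frequencies(b, list(A = c("a1", "a2"), B = c("b1", "b2")))
  enr2 <- two_sample_logo(p2$A, p2$B, alpha = 0.05)
  expect_equal(nrow(enr2), 0L)
  expect_equal(brute_force_fisher(2, 0, 1, 1), 1)
})

test_that("residue volumes match the quoted table", {
  expect_equal(residue_volume("M"), 166.7)
  expect_equal(residue_volume("L"), 162.9)
  expect_equal(length(pockettree:::RESIDUE_VOLUMES), 20L)
  expect_true(all(pockettree:::RESIDUE_VOLUMES > 0))
  expect_error(residue_volume("X"), "unknown residue")
})

test_that("specificity reports serialize to TSV", {
  sim <- simulate_families(family_sim_spec(n_families = 2,
                                           seqs_per_family = 5,
                                           background_width = 10, seed = 2))
  ra <- family_pocket_profile(sim)
  rep <- position_zscores(ra, ra$ids[1:5], ra$ids[6:10],
                          n_perm = 100, seed = 3)
  txt <- write_specificity_tsv(rep)
  parsed <- utils::read.delim(text = txt)
  expect_equal(nrow(parsed), nrow(rep))
  expect_named(parsed, c("position", "harmony", "z", "relief", "flagged"))
})
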