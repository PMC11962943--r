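test_that("cell abundance is the phenotype histogram", {
  cells <- make_cells(c(0, 1, 2), c(0, 0, 0), c("a", "a", "a"))
  vocab <- phenotype_vocabulary(c("a", "b"))
  prof <- cell_abundance_profiles(cells, vocab)
  expect_equal(unname(unlist(prof[1, -1])), c(3, 0))
  # conservation and permutation invariance on a cohort
  sim <- small_sim(seed = 41, n_patients = 4)
  p1 <- cell_abundance_profiles(sim$cells, sim$vocabulary)
  set.seed(2)
  p2 <- cell_abundance_profiles(sim$cells[sample(nrow(sim$cells)), ],
                                sim$vocabulary)
  expect_equal(as.data.frame(p2), as.data.frame(p1))
  counts <- dplyr::count(sim$cells, patient_id)
  expect_equal(rowSums(p1[-1]), counts$n, ignore_attr = TRUE)
})

test_that("pairwise proximity averages the Gaussian kernel over cross pairs", {
  vocab <- phenotype_vocabulary(c("a", "b", "c"))
  # one a and one b, coincident
  cells <- make_cells(c(5, 5), c(5, 5), c("a", "b"))
  prof <- suppressMessages(pairwise_proximity_profiles(cells, vocab))
  expect_equal(prof[["a|b"]], 1)
  expect_equal(prof[["a|c"]], 0)

  # one a, two b both at distance 10: mean of two equal terms
  cells2 <- make_cells(c(0, 10, -10), c(0, 0, 0), c("a", "b", "b"))
  prof2 <- suppressMessages(pairwise_proximity_profiles(cells2, vocab))
  expect_equal(prof2[["a|b"]], exp(-1), tolerance = 1e-12)

  # symmetric in the pair and bounded in [0,1]
  sim <- small_sim(seed = 43, n_patients = 3)
  pr <- suppressMessages(
    pairwise_proximity_profiles(sim$cells, sim$vocabulary))
  vals <- as.matrix(pr[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(ncol(vals), 6 * 5 / 2)

  # pairs in different images contribute nothing
  cells3 <- dplyr::bind_rows(
    make_cells(0, 0, "a", image_id = "i1"),
    make_cells(0, 0, "b", image_id = "i2"))
  prof3 <- suppressMessages(pairwise_proximity_profiles(cells3, vocab))
  expect_equal(prof3[["a|b"]], 0)
})

test_that("category abundance coarsens the pattern histogram", {
  cats <- tibble::tibble(pattern = c("P1", "P2", "P3"),
                         category = c("tumor", "tumor", "interface"))
  a <- tibble::tibble(patient_id = c("p1", "p1", "p1", "p2"),
                      pattern = c(1L, 2L, 3L, 3L))
  prof <- category_abundance_profiles(a, cats)
  expect_equal(unname(unlist(prof[prof$patient_id == "p1", -1])),
               c(2, 0, 0, 1))
  expect_equal(rowSums(prof[-1]), c(3, 1), ignore_attr = TRUE)
})

test_that("WL refinement distinguishes exactly non-isomorphic subtrees", {
  # path a - b - a: after one iteration both a-endpoints share a color
  # distinct from b
  A <- matrix(FALSE, 3, 3); A[1, 2] <- A[2, 3] <- TRUE
  g <- binary_graph_from_matrix(A, c("a", "b", "a"))
  wl <- wl_color_refinement(g, h = 1)
  cm <- wl$colors[[1]]
  expect_equal(cm[1, 2], cm[3, 2])
  expect_true(cm[2, 2] != cm[1, 2])
  # accumulated features: counts (a:2, b:1, c_{a|b}:2, c_{b|aa}:1)
  f <- wl_features(wl, mode = "accumulated")
  expect_equal(sort(unname(unlist(f[-1]))), c(1, 1, 2, 2))
  f_last <- wl_features(wl, mode = "last")
  expect_equal(sort(unname(unlist(f_last[-1]))), c(1, 2))

  # two isomorphic graphs get identical color multisets at every iteration
  B <- matrix(FALSE, 3, 3); B[2, 1] <- B[1, 3] <- TRUE
  g2 <- binary_graph_from_matrix(B, c("b", "a", "a"))
  wl2 <- wl_color_refinement(list(g, g2), h = 2)
  for (it in 1:3) {
    expect_equal(sort(wl2$colors[[1]][, it]), sort(wl2$colors[[2]][, it]))
  }

  # edgeless graph never changes after iteration 0
  g3 <- binary_graph_from_matrix(matrix(FALSE, 4, 4), c("a", "b", "a", "b"))
  wl3 <- wl_color_refinement(g3, h = 2)
  grp0 <- wl3$colors[[1]][, 1]
  for (it in 2:3) {
    expect_equal(length(unique(paste(grp0, wl3$colors[[1]][, it]))),
                 length(unique(grp0)))
  }
})

test_that("WL colors agree with brute-force rooted-subtree isomorphism on
           random small graphs", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    A <- matrix(runif(n * n) < 0.4, n, n)
    ph <- sample(c("a", "b"), n, TRUE)
    g <- binary_graph_from_matrix(A, ph)
    wl <- wl_color_refinement(g, h = 2)
    Au <- as.matrix(g$A)
    for (h in 0:2) {
      canon <- vapply(seq_len(n), function(v)
        oracle_subtree_canon(Au, ph, v, h), character(1))
      col <- wl$colors[[1]][, h + 1]
      # same color <=> same canonical depth-h subtree
      expect_equal(outer(col, col, "=="), outer(canon, canon, "=="),
                   ignore_attr = TRUE)
    }
  }
})

test_that("wl_last kernels are near-diagonal on heterogeneous cohorts", {
  # dense niches only (no scattered background): deep subtrees are almost
  # surely unique to their graph, so exact-match features rarely overlap
  sim <- simulate_cohort(sim_config(
    n_patients = 6, n_subgroups = 3, niches_per_patient = 3,
    cells_per_niche = 25, niche_radius = 40, image_size = 600,
    min_separation = 150, background_rate = 0, seed = 44))
  cmp_last <- comparator_fit(sim$cells, scheme = "wl_last",
                             config = small_config())
  cmp_acc <- comparator_fit(sim$cells, scheme = "wl_accumulated",
                            config = small_config())
  off_last <- cmp_last$kernel[upper.tri(cmp_last$kernel)]
  off_acc <- cmp_acc$kernel[upper.tri(cmp_acc$kernel)]
  # deep exact-subtree matches are rare across patients
  expect_gt(sum(off_last < 0.01), 0)
  expect_lt(mean(off_last), mean(off_acc))
})
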