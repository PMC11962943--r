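test_that("subtree embeddings match hand-computed values", {
  vocab <- phenotype_vocabulary(c("a", "b"))
  # isolated cell: embedding stays its one-hot at every depth
  iso <- build_cellular_graph(make_cells(0, 0, "a"))
  for (h in 1:3) {
    expect_equal(compute_embeddings(iso, h = h, vocabulary = vocab),
                 matrix(c(1, 0), 1, dimnames = list(NULL, c("a", "b"))))
  }
  # two cells 10 um apart, w = exp(-1)
  w <- exp(-1)
  pair <- build_cellular_graph(two_cell_patient(10))
  E1 <- compute_embeddings(pair, h = 1, vocabulary = vocab)
  expect_equal(E1[1, ], c(a = 1, b = w), tolerance = 1e-12)
  E2 <- compute_embeddings(pair, h = 2, vocabulary = vocab)
  expect_equal(E2[1, ], c(a = 1 + w^2, b = 2 * w), tolerance = 1e-12)
  expect_equal(unname(E2[1, ]), c(1.1353, 0.7358), tolerance = 1e-4)
})

test_that("iterative and matrix-power embeddings agree on random graphs", {
  vocab <- phenotype_vocabulary(c("a", "b", "c"))
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:50, 1)
    cells <- random_patient(n, m = 3, extent = 60, seed = seed)
    g <- build_cellular_graph(cells)
    for (h in 1:3) {
      expect_lt(max(abs(
        compute_embeddings(g, h = h, vocabulary = vocab) -
          oracle_embeddings_iterative(g$cells, vocab, 0.01, h))), 1e-9)
    }
  }
})

test_that("one-hot initial features conserve mass: row sums equal A^h row sums", {
  for (seed in 1:5) {
    cells <- random_patient(30, extent = 80, seed = seed)
    g <- build_cellular_graph(cells)
    A <- as.matrix(g$A)
    for (h in 1:3) {
      E <- compute_embeddings(g, h = h)
      Ah <- A
      for (i in seq_len(h - 1)) Ah <- Ah %*% A
      expect_equal(rowSums(E), rowSums(Ah), tolerance = 1e-9)
    }
  }
})

test_that("neighborhood membership matches a brute-force scan of A^h", {
  # isolated cell: itself only, radius 0
  iso <- build_cellular_graph(make_cells(0, 0, "a"))
  nb <- neighborhood_membership(iso)
  expect_equal(nb$size, 1)
  expect_equal(nb$radius, 0)
  expect_identical(nb$members[[1]], 1L)

  # membership is strict: influence exactly at tau is excluded
  pair <- build_cellular_graph(two_cell_patient(10))
  A2 <- as.matrix(pair$A) %*% as.matrix(pair$A)
  nb2 <- neighborhood_membership(pair, h = 2, tau = A2[1, 2])
  expect_equal(nb2$size, c(1, 1))

  # 100-cell uniform disc vs dense-matrix oracle
  set.seed(42)
  th <- runif(100, 0, 2 * pi); r <- 60 * sqrt(runif(100))
  cells <- make_cells(r * cos(th), r * sin(th),
                      sample(c("a", "b"), 100, TRUE))
  g <- build_cellular_graph(cells)
  nb3 <- neighborhood_membership(g, h = 2, tau = 0.01)
  A <- oracle_adjacency(g$cells, 0.01)
  Ah <- A %*% A
  for (i in c(1, 17, 50, 100)) {
    expect_identical(nb3$members[[i]], which(Ah[i, ] > 0.01))
  }
  expect_equal(nb3$size, rowSums(Ah > 0.01))
})

test_that("subtree clustering recovers planted blobs and is reproducible", {
  # all embeddings identical -> one pattern
  same <- tibble::tibble(patient_id = "p1",
                         emb_a = rep(1, 30), emb_b = rep(2, 30))
  m1 <- cluster_subtrees(same, k_pheno = 5, seed = 1)
  expect_equal(nrow(m1$signatures), 1)

  # two tight planted blobs far apart. With k_pheno spanning most of a
  # blob the k-NN graph is near-complete within each blob and Louvain
  # recovers the blobs exactly; with k_pheno far below the blob size,
  # modularity legitimately refines each blob into density strata, so the
  # guarantee at that scale is purity, not a pattern count.
  set.seed(7)
  blob <- rbind(matrix(rnorm(400, 0, 0.01), 200, 2),
                matrix(rnorm(400, 100, 0.01), 200, 2))
  emb <- tibble::tibble(patient_id = "p1",
                        emb_a = blob[, 1], emb_b = blob[, 2])
  planted <- rep(1:2, each = 200)
  m2 <- cluster_subtrees(emb, k_pheno = 150, seed = 1)
  expect_equal(nrow(m2$signatures), 2)
  expect_equal(ari(m2$labels, planted), 1)

  m2s <- cluster_subtrees(emb, k_pheno = 20, seed = 1)
  purity <- tapply(planted, m2s$labels, function(v) max(table(v)) / length(v))
  expect_true(all(purity == 1))  # no pattern ever mixes the two blobs

  # determinism under a fixed seed
  m2b <- cluster_subtrees(emb, k_pheno = 150, seed = 1)
  expect_identical(m2$labels, m2b$labels)

  # too few rows
  expect_error(cluster_subtrees(same[1:4, ], k_pheno = 5, seed = 1),
               class = "ng_validation_error")
})

test_that("signatures are member means, equivariant under relabeling", {
  E <- rbind(c(1, 0), c(0, 1), c(4, 2))
  colnames(E) <- c("a", "b")
  S <- compute_signatures(E, c(1L, 1L, 2L))
  expect_equal(unname(S["P1", ]), c(0.5, 0.5))
  expect_equal(unname(S["P2", ]), c(4, 2))
  # singleton cluster equals its member
  S1 <- compute_signatures(E, c(1L, 2L, 3L))
  expect_equal(unname(S1), unname(E))
  # permuting labels permutes rows, same multiset
  Sp <- compute_signatures(E, c(2L, 2L, 1L))
  expect_equal(unname(Sp[c(2, 1), ]), unname(S))
  expect_error(compute_signatures(E, c(1L, 1L, 3L)),
               class = "ng_validation_error")
})

test_that("pattern histograms count every cell exactly once", {
  a <- tibble::tibble(patient_id = rep("p1", 5), pattern = rep(2L, 5))
  h <- pattern_histograms(a, C = 3)
  expect_equal(unname(unlist(h[1, -1])), c(0, 5, 0))

  b <- tibble::tibble(patient_id = c("q", "q", "q", "q"),
                      pattern = c(1L, 1L, 2L, 3L))
  expect_equal(unname(unlist(pattern_histograms(b, C = 3)[1, -1])),
               c(2, 1, 1))

  # conservation across a cohort
  sim <- small_sim(seed = 9, n_patients = 6)
  emb <- compute_subtree_embeddings(sim$cells, vocabulary = sim$vocabulary)
  model <- cluster_subtrees(emb, k_pheno = 20, seed = 1)
  hist <- pattern_histograms(pattern_assignments(model, emb),
                             C = nrow(model$signatures))
  counts <- dplyr::count(sim$cells, patient_id)
  expect_equal(rowSums(hist[-1]),
               counts$n[match(hist$patient_id, counts$patient_id)],
               ignore_attr = TRUE)
  expect_equal(colSums(hist[-1]),
               tabulate(model$labels, nbins = nrow(model$signatures)),
               ignore_attr = TRUE)
})

test_that("the kernel is cosine similarity with its boundary cases", {
  expect_equal(softwl_similarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(softwl_similarity(c(2, 0), c(0, 3)), 0)
  expect_equal(softwl_similarity(c(2, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(softwl_similarity(c(0, 0), c(1, 1)),
               class = "ng_validation_error")

  prof <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                         P1 = c(2, 0, 1), P2 = c(0, 3, 1))
  K <- kernel_matrix(prof)
  expect_equal(K, t(K))
  expect_equal(diag(K), setNames(rep(1, 3), prof$patient_id))
  expect_equal(K["p1", "p3"], 1 / sqrt(2), tolerance = 1e-12)
  expect_true(all(K >= 0 & K <= 1))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("histograms, signatures, and kernel are invariant to cell order", {
  sim <- small_sim(seed = 13, n_patients = 5)
  cells <- sim$cells
  set.seed(1)
  shuffled <- cells[sample(nrow(cells)), ]

  emb1 <- compute_subtree_embeddings(cells, vocabulary = sim$vocabulary)
  emb2 <- compute_subtree_embeddings(shuffled, vocabulary = sim$vocabulary)

  # embeddings are permutation-equivariant: identical per cell after joining
  # on patient and coordinates
  key1 <- paste(emb1$patient_id, emb1$x, emb1$y)
  key2 <- paste(emb2$patient_id, emb2$x, emb2$y)
  perm <- match(key1, key2)
  expect_false(anyNA(perm))
  ecols <- grep("^emb_", names(emb1), value = TRUE)
  expect_equal(as.matrix(emb2[perm, ecols]), as.matrix(emb1[, ecols]),
               ignore_attr = TRUE, tolerance = 1e-12)

  # with a fixed pattern model, histograms and kernel do not see cell order
  m1 <- cluster_subtrees(emb1, k_pheno = 20, seed = 1)
  h1 <- map_subtrees_to_patterns(emb1, m1)$histograms
  h2 <- map_subtrees_to_patterns(emb2, m1)$histograms
  expect_equal(as.data.frame(h2[match(h1$patient_id, h2$patient_id), ]),
               as.data.frame(h1), ignore_attr = TRUE)
  K1 <- kernel_matrix(h1); K2 <- kernel_matrix(h2)
  expect_equal(K2[rownames(K1), colnames(K1)], K1, tolerance = 1e-12)
})

test_that("optional L1 normalization clusters on composition only", {
  # distinct compositions at wildly varying total masses: the L1 path must
  # cluster by composition only, i.e. be invariant to per-row mass
  set.seed(3)
  u <- runif(120, 0.2, 0.8)
  mass <- runif(120, 1, 50)
  emb <- tibble::tibble(patient_id = "p1",
                        emb_a = mass * u, emb_b = mass * (1 - u))
  comp <- tibble::tibble(patient_id = "p1", emb_a = u, emb_b = 1 - u)
  l1 <- cluster_subtrees(emb, k_pheno = 20, seed = 1, l1_normalize = TRUE)
  ref <- cluster_subtrees(comp, k_pheno = 20, seed = 1)
  expect_identical(l1$labels, ref$labels)
  # the raw path sees the masses and partitions differently
  raw <- cluster_subtrees(emb, k_pheno = 20, seed = 1)
  expect_false(identical(raw$labels, l1$labels))
  # signatures still average the raw (unnormalised) embeddings
  E <- as.matrix(emb[c("emb_a", "emb_b")])
  for (c in seq_len(nrow(l1$signatures))) {
    expect_equal(unname(l1$signatures[c, ]),
                 unname(colMeans(E[l1$labels == c, , drop = FALSE])))
  }
})
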