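# independent brute-force oracles; deliberately written with plain loops so
# they share no code path with the implementation they check

# Gaussian adjacency by explicit double loop (unit self-loops, zero across
# images)
oracle_adjacency <- function(cells, alpha) {
  n <- nrow(cells)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (cells$image_id[i] == cells$image_id[j]) {
        d2 <- (cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2
        A[i, j] <- exp(-alpha * d2)
      }
    }
  }
  diag(A) <- 1
  A
}

# iterative update form: x_i <- x_i + sum_{j != i} x_j A_ij, per sweep
oracle_embeddings_iterative <- function(cells, vocab, alpha, h) {
  A <- oracle_adjacency(cells, alpha)
  n <- nrow(cells)
  m <- nrow(vocab)
  X <- matrix(0, n, m)
  for (i in seq_len(n)) X[i, match(cells$phenotype[i], vocab$phenotype)] <- 1
  for (it in seq_len(h)) {
    Xnew <- X
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j != i) Xnew[i, ] <- Xnew[i, ] + X[j, ] * A[i, j]
      }
    }
    X <- Xnew
  }
  colnames(X) <- vocab$phenotype
  X
}

# Hodges-Lehmann by full enumeration and explicit order statistics
oracle_hl <- function(x, y) {
  diffs <- numeric(0)
  for (xi in x) for (yj in y) diffs <- c(diffs, xi - yj)
  diffs <- sort(diffs)
  n <- length(diffs)
  if (n %% 2 == 1) diffs[(n + 1) / 2]
  else (diffs[n / 2] + diffs[n / 2 + 1]) / 2
}

# IoU of k-NN sets by explicit set arithmetic (same tie rule: similarity
# descending, then index; self excluded)
oracle_knn_sets <- function(K, k) {
  n <- nrow(K)
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-K[i, others], others)]
    ord[seq_len(k)]
  })
}

oracle_iou_matrix <- function(K, k) {
  sets <- oracle_knn_sets(K, k)
  n <- nrow(K)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        M[i, j] <- length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
      }
    }
  }
  M
}

# canonical string of the depth-h unfolded rooted subtree: recursive
# brute-force equivalent of WL refinement
oracle_subtree_canon <- function(A, phenotype, root, h) {
  if (h == 0) return(phenotype[root])
  nb <- which(A[root, ])
  subs <- sort(vapply(nb, function(u)
    oracle_subtree_canon(A, phenotype, u, h - 1), character(1)))
  paste0(phenotype[root], "(", paste(subs, collapse = ","), ")")
}

# Kaplan-Meier product-limit by hand
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  list(time = ut, surv = out)
}
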