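# Independent oracles: deliberately naive re-derivations used only to check
# the package's faster/structured implementations.

# tip-to-tip distances by explicit path construction: walk each tip to the
# root, then sum edge lengths in the symmetric difference of the two paths
oracle_patristic_matrix <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- lapply(seq_len(n), function(tip) {
    e <- integer(0)
    node <- tip
    while (node != root) {
      e <- c(e, node)
      node <- parent[node]
    }
    e
  })
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        both <- c(setdiff(paths[[i]], paths[[j]]),
                  setdiff(paths[[j]], paths[[i]]))
        D[i, j] <- D[j, i] <- sum(elen[both])
      }
    }
  }
  D
}

# dense, solve()-based evaluation of the marginal log posterior of tau
oracle_log_posterior <- function(tau, d, X, V, blocks, rho, tau_max) {
  n <- length(d)
  Delta <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) Delta[i, j] <- tau^2
      else if (blocks[i] == blocks[j]) Delta[i, j] <- rho * tau^2
    }
  }
  Sigma <- V + Delta
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% d)
  r <- d - X %*% beta
  ld1 <- determinant(Sigma, logarithm = TRUE)$modulus
  ld2 <- determinant(XtSiX, logarithm = TRUE)$modulus
  as.numeric(-log(tau_max) - 0.5 * (ld1 + ld2 + t(r) %*% Si %*% r))
}

# exhaustive weighted set packing over all 2^S study subsets
oracle_pack <- function(sets, wts, ids) {
  S <- length(sets)
  best_w <- -1L
  best_ids <- character(0)
  for (mask in 0:(2^S - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(S) - 1)))
    sp <- unlist(sets[sel], use.names = FALSE)
    if (anyDuplicated(sp)) next
    w <- sum(wts[sel])
    cand <- sort(ids[sel])
    if (w > best_w ||
        (w == best_w && paste(cand, collapse = "\r") <
           paste(sort(best_ids), collapse = "\r"))) {
      best_w <- w
      best_ids <- cand
    }
  }
  list(weight = best_w, ids = best_ids)
}

# literal transcription of the rank-based L0 trim iteration: estimate the
# number of suppressed studies assuming the k0 *largest* observed values are
# the unmatched ones (i.e. studies missing on the left)
oracle_L0_left <- function(d, v, maxiter = 50) {
  n <- length(d)
  k0 <- 0L
  repeat {
    trimmed <- sort(d)[seq_len(n - k0)]
    v_trim <- v[order(d)][seq_len(n - k0)]
    # DerSimonian-Laird pooled mean of the trimmed set
    w <- 1 / v_trim
    mu_fe <- sum(w * trimmed) / sum(w)
    Q <- sum(w * (trimmed - mu_fe)^2)
    t2 <- max(0, (Q - (length(trimmed) - 1)) /
                (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (v_trim + t2)
    mu <- sum(wr * trimmed) / sum(wr)
    cent <- round(d - mu, 10)
    rk <- rank(abs(cent), ties.method = "average")
    Tn <- sum(rk[cent > 0])
    k0_new <- min(as.integer(max(0, round((4 * Tn - n * (n + 1)) /
                                            (2 * n - 1)))), n - 2L)
    if (k0_new == k0) return(k0)
    k0 <- k0_new
    maxiter <- maxiter - 1
    if (maxiter <= 0) return(k0)
  }
}
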