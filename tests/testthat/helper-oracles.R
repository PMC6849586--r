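# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (Cholesky solves, ape::vcv, ape::pic) so each
# check compares two distinct routes to the same quantity.

# multivariate-normal log-density via eigendecomposition
mvn_loglik_oracle <- function(V, y, sigma2, mu) {
  n <- length(y)
  e <- eigen(sigma2 * V, symmetric = TRUE)
  d <- y - mu
  w <- crossprod(e$vectors, d)
  -0.5 * (n * log(2 * pi) + sum(log(e$values)) + sum(w^2 / e$values))
}

# shared-time matrix by explicit enumeration of root-to-tip edge paths
brute_vcv <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  parent <- integer(n + phy$Nnode)
  blen <- numeric(n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  path_edges <- lapply(seq_len(n), function(tip) {
    v <- tip; out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent[v] }
    out
  })
  V <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- sum(blen[intersect(path_edges[[i]], path_edges[[j]])])
  }
  V
}

# Felsenstein pruning written as a direct recursion
hand_pic <- function(phy, y) {
  n <- ape::Ntip(phy)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  blen <- numeric(n + phy$Nnode)
  blen[phy$edge[, 2]] <- phy$edge.length
  contrasts <- numeric(0)
  rec <- function(node) {
    if (node <= n) return(c(x = unname(y[phy$tip.label[node]]), b = blen[node]))
    ch <- vapply(kids[[as.character(node)]], rec, c(x = 0, b = 0))
    b1 <- ch["b", 1]; b2 <- ch["b", 2]
    contrasts[as.character(node)] <<- (ch["x", 1] - ch["x", 2]) / sqrt(b1 + b2)
    x <- (b2 * ch["x", 1] + b1 * ch["x", 2]) / (b1 + b2)
    c(x = unname(x), b = blen[node] + b1 * b2 / (b1 + b2))
  }
  rec(n + 1L)
  contrasts
}

# fixed example trees
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
balanced8 <- function() {
  read_newick(paste0("(((A:1,B:1):1,(C:1,D:1):1):1,",
                     "((E:1,F:1):1,(G:1,H:1):1):1);"))
}

maxrate_r <- function() log(1e-5)
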