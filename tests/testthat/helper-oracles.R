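# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Mass-action oracle for the binding isotherm: solve K*x = (Pt - x)(St - x)
# by root bracketing, with Pt the diluted protein concentration, total
# sites St = n * r * Pt and macroscopic constant K = n * kd; the CSP is
# cspmax times the bound fraction x / Pt.
oracle_csp <- function(r, kd, n, c_pro, c_lig, cspmax) {
  pt <- 1 / (1 / c_pro + r / c_lig)
  st <- n * r * pt
  if (st == 0) return(0)
  K <- n * kd
  f <- function(x) K * x - (pt - x) * (st - x)
  upper <- min(pt, st)
  if (K == 0) return(cspmax * upper / pt)
  x <- uniroot(f, c(0, upper), tol = .Machine$double.eps / 4)$root
  cspmax * x / pt
}

# Uniform random proper rotation via QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Random unrooted tree with positive branch lengths; its cophenetic
# matrix is additive by construction.
rand_additive_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  tr
}

# Least-squares branch lengths of a fixed 4-taxon unrooted topology
# fitted to a distance matrix; returns the residual sum of squares.
# Topology is given as a split: taxa `pair` vs the rest.
ls_quartet_rss <- function(dm, pair) {
  taxa <- rownames(dm)
  other <- setdiff(taxa, pair)
  # unknowns: 4 terminal lengths + 1 internal, design over the 6 pairs
  labs <- c(pair, other)
  comb <- utils::combn(4, 2)
  a_mat <- matrix(0, ncol(comb), 5)
  y <- numeric(ncol(comb))
  for (k in seq_len(ncol(comb))) {
    i <- comb[1, k]; j <- comb[2, k]
    a_mat[k, i] <- 1; a_mat[k, j] <- 1
    crosses <- (i <= 2) != (j <= 2)
    if (crosses) a_mat[k, 5] <- 1
    y[k] <- dm[labs[i], labs[j]]
  }
  fit <- lm.fit(a_mat, y)
  sum(fit$residuals^2)
}
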