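# Independent oracles used to check the package's implementations. These
# stay deliberately naive (literal sums, double loops, plain gradient
# descent) and never share code with the implementation paths they verify.

# Literal term-by-term Jensen-Shannon divergence with the gap factor.
oracle_jsd <- function(p, q, gap_fraction = 0) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / b[i])
    s
  }
  unname((1 - gap_fraction) * (0.5 * kl(p, m) + 0.5 * kl(q, m)))
}

# Random frequency profile over the 20 residues (optionally sparse).
random_profile <- function(sparse = FALSE) {
  x <- stats::rexp(20)
  if (sparse) x[sample.int(20, sample(0:15, 1))] <- 0
  if (sum(x) == 0) x[1] <- 1
  stats::setNames(x / sum(x), varmod::AA_ALPHABET)
}

# Exhaustive all-pairs minimum distance between two coordinate sets.
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Monte Carlo SASA oracle: uniform random directions per atom.
oracle_sasa_mc <- function(xyz, radii, probe = 1.4, n_points = 100000L) {
  n <- nrow(xyz)
  rad <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= rad[j]^2
    }
    areas[i] <- mean(exposed) * 4 * pi * rad[i]^2
  }
  areas
}

# Plain gradient-descent fit of the Platt objective (smoothed targets),
# independent of the package's quasi-Newton fit.
oracle_platt <- function(f, y, lr = NULL, iters = 200000L) {
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  t <- ifelse(y == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  if (is.null(lr)) lr <- 0.5 / length(f)
  for (it in seq_len(iters)) {
    z <- A * f + B
    s <- 1 / (1 + exp(-z))
    gA <- sum((s - (1 - t)) * f)
    gB <- sum(s - (1 - t))
    A <- A - lr * gA
    B <- B - lr * gB
    if (max(abs(gA), abs(gB)) < 1e-10) break
  }
  list(A = A, B = B)
}

# O(n^2) pairwise-concordance AUC with ties counted as 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + (p > q) + 0.5 * (p == q)
    }
  }
  s / (length(pos) * length(neg))
}

# Tiny structure from an atom coordinate matrix (one residue per row group).
structure_from_xyz <- function(xyz, seq_pos, element = "C",
                               res_name = "ALA") {
  n <- nrow(xyz)
  if (length(element) == 1L) element <- rep(element, n)
  new_structure(data.frame(
    seq_pos = seq_pos, res_name = res_name,
    atom_name = paste0(element, seq_len(n)), element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE,
    stringsAsFactors = FALSE))
}

# Alignment whose column c is given by the character vector cols[[c]].
alignment_from_columns <- function(cols) {
  depth <- length(cols[[1]])
  rows <- vapply(seq_len(depth), function(r) {
    paste(vapply(cols, `[[`, "", r), collapse = "")
  }, "")
  new_alignment(ids = c("query", paste0("row", seq_len(depth - 1L))),
                rows = rows)
}
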