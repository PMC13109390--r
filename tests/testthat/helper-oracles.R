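# Independent oracles used across the suite. Each deliberately takes a
# different algebraic route than the implementation it checks.

# Adjusted genotype means for a connected genotype x block design via the
# Moore-Penrose pseudoinverse of the full over-parameterised dummy matrix:
# an estimable function L theta evaluated with the minimum-norm solution.
blue_oracle <- function(cells) {
  g <- factor(cells$genotype)
  b <- factor(cells$block)
  ind <- function(f) diag(nlevels(f))[as.integer(f), , drop = FALSE]
  X <- cbind(1, ind(g), ind(b))
  theta <- MASS::ginv(X) %*% cells$value
  nG <- nlevels(g)
  nB <- nlevels(b)
  L <- cbind(1, diag(nG), matrix(1 / nB, nG, nB))
  setNames(drop(L %*% theta), levels(g))
}

# genotype-block connectivity by breadth-first search (independent of the
# union-find in the package)
is_connected <- function(cells) {
  gs <- unique(cells$genotype)
  bs <- unique(cells$block)
  nodes <- c(paste0("g", gs), paste0("b", bs))
  edges <- rbind(paste0("g", cells$genotype), paste0("b", cells$block))
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier)) {
    nxt <- unique(c(edges[2, edges[1, ] %in% frontier],
                    edges[1, edges[2, ] %in% frontier]))
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  length(seen) == length(nodes)
}

# percentile by explicit sort-and-interpolate (order-statistic definition,
# linear interpolation at h = (n-1) p + 1)
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# anatomical gmax evaluated straight from its definition: ellipse area
# pi * a * b with a = pl/2, b = pl/4, pore length pl = SL/2, pore depth SW
gmax_oracle <- function(SD, SL, SW, dw = 0.0000249, v = 0.0224) {
  pl <- SL / 2
  amax <- pi * (pl / 2) * (pl / 4)
  (dw / v * SD * amax) / (SW + (pi / 2) * sqrt(amax / pi))
}

# simple-regression slope/p by calling lm()/summary() directly
slope_oracle <- function(y, x) {
  f <- summary(stats::lm(y ~ x))
  c(coef = f$coefficients[2, 1], p = f$coefficients[2, 4])
}
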