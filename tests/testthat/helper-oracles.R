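# Independent oracles, deliberately implemented differently from the
# package internals they check.

# scalar recursive evaluator with the same protection semantics as the
# engine (per-node clamp to +/- 1e15, NaN -> 0), written as a switch over
# operator names instead of the vectorised operator table
oracle_eval_scalar <- function(tree, row) {
  clamp <- function(v) {
    if (is.nan(v)) return(0)
    min(max(v, -1e15), 1e15)
  }
  if (!is.null(tree$const)) return(tree$const)
  if (!is.null(tree$feat)) return(unname(row[[tree$feat]]))
  a <- vapply(tree$args, oracle_eval_scalar, numeric(1), row = row)
  clamp(switch(tree$op,
    add  = a[1] + a[2],
    sub  = a[1] - a[2],
    mul  = a[1] * a[2],
    div  = if (a[2] == 0) 1 else a[1] / a[2],
    neg  = -a[1],
    log  = log(max(abs(a[1]), 1e-12)),
    exp  = exp(min(max(a[1], -50), 50)),
    sqrt = sqrt(abs(a[1])),
    min  = min(a[1], a[2]),
    max  = max(a[1], a[2]),
    ifg  = if (a[1] > a[2]) a[3] else a[4],
    stop("oracle: unknown operator ", tree$op)))
}

# O(n^2) pairwise-dominance front assignment (minimisation)
oracle_fronts <- function(objs) {
  n <- nrow(objs)
  dominates <- function(i, j) {
    all(objs[i, ] <= objs[j, ]) && any(objs[i, ] < objs[j, ])
  }
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) i != j && dominates(j, i),
                  logical(1))), logical(1))]
    rank[nd] <- r
    remaining <- setdiff(remaining, nd)
    r <- r + 1L
  }
  lapply(0:(r - 1L), function(k) which(rank == k))
}

# brute-force AUC: all positive x negative pairs, ties count one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exact Shapley by averaging marginal contributions over all k!
# permutations (independent of the coalition-weight formula in the package)
oracle_shapley_perms <- function(f, row, background, features) {
  k <- length(features)
  vcache <- new.env()
  v <- function(members) {
    key <- paste0("k_", paste(sort(members), collapse = "|"))
    if (!is.null(vcache[[key]])) return(vcache[[key]])
    M <- background
    for (nm in members) M[, nm] <- row[[nm]]
    vcache[[key]] <- mean(f(M))
    vcache[[key]]
  }
  perms <- gtools_permutations(k)
  phi <- stats::setNames(numeric(k), features)
  for (p in seq_len(nrow(perms))) {
    ord <- features[perms[p, ]]
    prev <- v(character(0))
    for (j in seq_len(k)) {
      val <- v(ord[seq_len(j)])
      phi[ord[j]] <- phi[ord[j]] + (val - prev)
      prev <- val
    }
  }
  phi / nrow(perms)
}

# all permutations of 1..k as a matrix (tiny k only)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# random expression tree builder for property tests (uses package exports)
random_test_tree <- function(features, depth = 4) {
  random_tree(features, max_depth = depth, method = "grow")
}
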