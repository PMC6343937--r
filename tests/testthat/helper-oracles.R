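## Independent brute-force oracles used to cross-check the implementation.
## These deliberately share no code with the package internals.

## Exact two-sided WMW p-value by full enumeration of rank assignments.
oracle_wmw_p <- function(a, b) {
  n <- length(a) + length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  u_all <- apply(combos, 2, function(idx) {
    sum(sort(r)[idx]) - length(a) * (length(a) + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

## Step-up BH adjustment written directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(n), function(i) {
    min(1, min((p * n / r)[r >= r[i]]))
  }, numeric(1))
}

## Pairwise-comparison AUC (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(wins)
}

## Precision/recall/F straight from the counts.
oracle_prf <- function(ntp, nfp, nfn) {
  p <- if (ntp + nfp) ntp / (ntp + nfp) else 0
  r <- if (ntp + nfn) ntp / (ntp + nfn) else 0
  f <- if (p + r) 2 * p * r / (p + r) else 0
  c(p, r, f)
}

## Hypergeometric over-representation tail by explicit combinatorial sum.
oracle_hyper_tail <- function(overlap, n_deg, universe, set_size) {
  j <- overlap:min(n_deg, set_size)
  sum(choose(n_deg, j) * choose(universe - n_deg, set_size - j)) /
    choose(universe, set_size)
}

## Small dataset builders -----------------------------------------------

make_dataset <- function(values, labels, species = "human", name = "toy") {
  expression_dataset(values, labels, species = species, name = name)
}

## Two-class Gaussian dataset with `n_info` planted genes shifted by `shift`.
planted_dataset <- function(n_genes = 200, n_info = 20, shift = 2,
                            n_per_class = c(20, 20), seed = 1,
                            species = "human") {
  set.seed(seed)
  n <- sum(n_per_class)
  v <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  labels <- rep(c("control", "disease"), n_per_class)
  info <- seq_len(n_info)
  v[info, labels == "disease"] <- v[info, labels == "disease"] + shift
  list(ds = zscore_by_gene(make_dataset(v, labels, species = species)),
       informative = rownames(v)[info])
}
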