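# Shared fixtures: small survey configurations generated in code.

# two-scale layout for fast unit tests
small_scales <- function() list(
  list(scale_id = "SA", prefix = "A", n_items = 12L, n_clusters = 3L,
       within_pcc = 0.7, between_pcc = 0.1, likert = c(1L, 5L),
       reverse_fraction = 0.25),
  list(scale_id = "SB", prefix = "B", n_items = 8L, n_clusters = 2L,
       within_pcc = 0.7, between_pcc = 0.1, likert = c(1L, 4L),
       reverse_fraction = 0.25))

small_config <- function(seed = 1L, n = 300L, subgroups = list()) {
  synthetic_config(
    n_respondents = n, scales = small_scales(),
    dose_model = list(intercept = 2, coefficients = c("A-c1" = -0.8),
                      noise_sd = 0.8),
    demographics = list(colour = c(red = 0.5, blue = 0.3, green = 0.2)),
    planted_subgroups = subgroups, seed = seed)
}

small_dataset <- function(seed = 1L, n = 300L) {
  reverse_score(generate_dataset(small_config(seed, n))$dataset)
}

# adjusted Rand index between two labelings (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# recovered factor id whose scores best track a planted latent column
match_factor <- function(scores, latent) {
  cors <- abs(stats::cor(scores, latent))
  rownames(cors)[which.max(cors)]
}

# independent Lance-Williams recursion for Ward linkage on squared
# dissimilarities (the ward.D2 convention); returns the merge sets in order
lw_ward_merges <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  merges <- list()
  repeat {
    m <- length(active)
    if (m == 1L) break
    best <- c(NA, NA); bestval <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (d2[i, j] < bestval) { bestval <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(active[[i]], active[[j]]))
    merges[[length(merges) + 1L]] <- merged
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      newrow[k] <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                    nk * d2[i, j]) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    active <- c(active[keep], list(merged))
    sizes <- c(sizes[keep], ni + nj)
  }
  merges
}

# merge sets of an hclust tree, in merge order
hclust_merges <- function(tree) {
  n <- length(tree$order)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    grab <- function(x) if (x < 0) -x else sets[[x]]
    sets[[i]] <- sort(c(grab(tree$merge[i, 1]), grab(tree$merge[i, 2])))
  }
  sets
}

# brute-force plug-in mutual information: explicit double sum over the
# joint count table, natural log
mi_bruteforce <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij == 0) next
    total <- total + (nij / n) *
      log((nij / n) / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
  }
  total
}
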