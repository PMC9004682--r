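# Shared synthetic fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# two widely separated, strongly coupled clusters + oriented co-embedding
paired_two_cluster <- function() {
  fixture("paired_two_cluster", {
    sim <- generate_multimodal(synthetic_config(
      n_cells = 600, n_clusters = 2, coupled_fraction = 0.5, seed = 11
    ))
    truth <- sim$truth
    mchn <- raw_rates(sim$mc_counts) / truth$per_cell_global
    expr <- normalize_expression(sim$rna_counts)
    ce <- cca_coembed(mchn, expr, n_components = 20, reverse_x = TRUE)
    list(sim = sim, labels = as.character(truth$cluster_labels),
         mchn = mchn, expr = expr, ce = ce)
  })
}

# five-cluster dataset for the consensus pipeline
five_cluster <- function() {
  fixture("five_cluster", {
    sim <- generate_multimodal(synthetic_config(
      n_cells = 500, n_clusters = 5, seed = 2
    ))
    nr <- normalize_rates(sim$mc_counts)
    pcs <- embed_methylome(nr, n_pcs = 15)
    list(sim = sim, nr = nr, pcs = pcs,
         labels = as.character(sim$truth$cluster_labels))
  })
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  mean(vapply(seq_len(n), function(i) {
    per_cluster <- tapply(d[i, ], labels, mean)
    own <- mean(d[i, labels == labels[i] & seq_len(n) != i])
    other <- min(per_cluster[names(per_cluster) != labels[i]])
    (other - own) / max(own, other)
  }, numeric(1)))
}

# reference implementation of restricted k-partners: full distance matrix,
# explicit eligibility scan each step
rkp_reference <- function(src, tgt, k, z, seed,
                          metric = c("euclidean", "one_minus_spearman")) {
  metric <- match.arg(metric)
  d <- if (metric == "euclidean") {
    as.matrix(dist(rbind(src, tgt)))[seq_len(nrow(src)),
                                     nrow(src) + seq_len(nrow(tgt))]
  } else {
    1 - cor(t(src), t(tgt), method = "spearman")
  }
  kp <- ceiling(z * k * nrow(src) / nrow(tgt))
  cnt <- integer(nrow(tgt))
  used <- matrix(FALSE, nrow(src), nrow(tgt))
  out <- matrix(NA_integer_, nrow(src), k)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(k)) {
      for (i in sample.int(nrow(src))) {
        eligible <- which(cnt < kp & !used[i, ])
        j <- eligible[order(d[i, eligible], eligible)][1]
        out[i, r] <- j
        used[i, j] <- TRUE
        cnt[j] <- cnt[j] + 1L
      }
    }
  })
  out
}
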