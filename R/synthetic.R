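#' Configuration for the synthetic multi-modal generator
#'
#' Collects the knobs of the ground-truth simulator: clustered cells profiled
#' simultaneously for gene-body non-CG methylation (beta-binomial counts
#' around a per-cell global mCH level times a cluster-specific gene factor)
#' and RNA expression (negative-binomial counts with cluster-specific
#' log-normal means). A configurable fraction of genes is "coupled": their
#' per-cluster methylation factor is a decreasing logistic transform of the
#' standardized per-cluster log expression, emulating the anti-correlation of
#' gene-body mCH and transcription in neurons.
#'
#' @param n_cells,n_genes,n_clusters Positive counts.
#' @param coupled_fraction Fraction in \[0,1\] of genes with anti-correlated
#'   mCH/RNA.
#' @param rna_dispersion Negative-binomial dispersion (variance
#'   `mu + rna_dispersion * mu^2`).
#' @param meth_concentration Beta-binomial concentration (alpha + beta);
#'   larger means less extra-binomial noise.
#' @param coverage_mean Mean cytosine coverage per gene per cell (Poisson).
#' @param global_mch_range Length-2 interval in (0,1): per-cell global mCH
#'   levels are drawn uniformly from it.
#' @param seed Integer seed; identical configs generate identical data.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 500, n_genes = 1000, n_clusters = 3,
                             coupled_fraction = 0.2, rna_dispersion = 0.5,
                             meth_concentration = 100, coverage_mean = 100,
                             global_mch_range = c(0.02, 0.06), seed = 1L) {
  assert_count(n_cells, "n_cells")
  assert_count(n_genes, "n_genes")
  assert_count(n_clusters, "n_clusters")
  assert_scalar_number(coupled_fraction, "coupled_fraction", 0, 1)
  assert_scalar_number(rna_dispersion, "rna_dispersion", lower = 1e-12)
  assert_scalar_number(meth_concentration, "meth_concentration", lower = 1e-12)
  assert_scalar_number(coverage_mean, "coverage_mean", lower = 1e-12)
  if (length(global_mch_range) != 2L || any(global_mch_range <= 0) ||
      any(global_mch_range >= 1) || diff(global_mch_range) < 0) {
    mf_abort("`global_mch_range` must be an increasing interval in (0,1).",
             "bad_argument")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters),
         coupled_fraction = coupled_fraction,
         rna_dispersion = rna_dispersion,
         meth_concentration = meth_concentration,
         coverage_mean = coverage_mean,
         global_mch_range = as.numeric(global_mch_range),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# cluster-specific methylation factors: decreasing logistic in standardized
# per-cluster log-expression effects, bounded in [f_min, f_max]; the range is
# centered at 1 so the marginal methylation rate stays at the global level
coupling_transform <- function(effects, f_min = 0.1, f_max = 1.9, steep = 2) {
  s <- sd(effects)
  z <- if (s > 0) (effects - mean(effects)) / s else rep(0, length(effects))
  f_min + (f_max - f_min) * (1 - stats::plogis(steep * z))
}

#' Generate a coupled methylome + transcriptome dataset with known truth
#'
#' @param config A [synthetic_config].
#'
#' @return A list with elements
#'   * `mc_counts`: a [paired_counts] (context `"HCH"`) of gene-body
#'     methylated/total cytosine calls,
#'   * `rna_counts`: cell-by-gene integer matrix of RNA counts,
#'   * `truth`: list with `cluster_labels` (factor), `coupled_genes`
#'     (integer indices), `rna_means` (gene-by-cluster), `meth_levels`
#'     (gene-by-cluster fractions), `per_cell_global` (numeric).
#' @export
#'
#' @examples
#' sim <- generate_multimodal(synthetic_config(n_cells = 60, n_genes = 50))
#' table(sim$truth$cluster_labels)
generate_multimodal <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cells; g <- cfg$n_genes; k <- cfg$n_clusters
    labels <- factor(sample(rep_len(seq_len(k), n)),
                     levels = seq_len(k),
                     labels = paste0("C", seq_len(k)))
    cl <- as.integer(labels)

    n_coupled <- round(cfg$coupled_fraction * g)
    coupled <- if (n_coupled > 0) sort(sample.int(g, n_coupled)) else integer(0)

    # RNA: per-gene base mean, per-cluster log effects for coupled genes and
    # for a further 30% of uncoupled genes (RNA-only markers)
    mu0 <- exp(rnorm(g, log(5), 1))
    eff <- matrix(0, g, k)
    structured <- union(coupled,
                        sample(setdiff(seq_len(g), coupled),
                               round(0.3 * (g - n_coupled))))
    eff[structured, ] <- rnorm(length(structured) * k, 0, 1.2)
    rna_means <- mu0 * exp(eff)

    # methylation factors: coupled genes follow the decreasing transform of
    # the RNA effects; uncoupled genes get independent cluster structure
    fmat <- matrix(1, g, k)
    for (gg in coupled) fmat[gg, ] <- coupling_transform(eff[gg, ])
    uncoupled_struct <- setdiff(structured, coupled)
    for (gg in uncoupled_struct) {
      fmat[gg, ] <- coupling_transform(rnorm(k, 0, 1.2))
    }

    global <- runif(n, cfg$global_mch_range[1], cfg$global_mch_range[2])

    rate <- pmin(pmax(global * t(fmat[, cl, drop = FALSE]), 1e-4), 0.999)
    cov <- matrix(rpois(n * g, cfg$coverage_mean), n, g)
    p <- matrix(rbeta(n * g, rate * cfg$meth_concentration,
                      (1 - rate) * cfg$meth_concentration), n, g)
    mc <- matrix(rbinom(n * g, as.vector(cov), as.vector(p)), n, g)

    rna <- matrix(
      rnbinom(n * g, mu = as.vector(t(rna_means[, cl, drop = FALSE])),
              size = 1 / cfg$rna_dispersion),
      n, g, byrow = FALSE
    )

    cells <- sprintf("cell_%04d", seq_len(n))
    genes <- sprintf("gene_%04d", seq_len(g))
    dimnames(cov) <- dimnames(mc) <- dimnames(rna) <- list(cells, genes)

    meth_levels <- pmin(pmax(mean(global) * fmat, 0), 1)
    dimnames(rna_means) <- dimnames(meth_levels) <-
      list(genes, levels(labels))

    list(
      mc_counts = paired_counts(mc, cov, context = "HCH"),
      rna_counts = rna,
      truth = list(
        cluster_labels = setNames(labels, cells),
        coupled_genes = coupled,
        rna_means = rna_means,
        meth_levels = meth_levels,
        per_cell_global = setNames(global, cells)
      )
    )
  })
}

#' Simulate read-level methylation records from an RNA/DNA mixture
#'
#' Emulates bisulfite reads from an assay in which cDNA is fully methylated
#' during reverse transcription: RNA-origin reads carry a per-read mCH ratio
#' near 1, DNA-origin reads sit near the genomic non-CG background. Cytosine
#' counts per read are Poisson.
#'
#' @param n_reads Number of reads (0 allowed).
#' @param rna_fraction Fraction of reads of RNA origin, in \[0,1\].
#' @param seed Integer seed.
#' @param cytosines_mean Mean CH cytosines per read.
#' @param hard If `TRUE`, draw the two mCH-ratio mixture components closer to
#'   the classification thresholds (RNA Beta(19,2), DNA Beta(5,5)) to stress
#'   the classifier; default components are RNA Beta(50,1), DNA Beta(2,48).
#'
#' @return A tibble with columns `read_id`, `mch`, `ch`, `mcg`, `cg`,
#'   `true_origin` (`"RNA"`/`"DNA"`).
#' @export
generate_reads <- function(n_reads, rna_fraction, seed = 1L,
                           cytosines_mean = 15, hard = FALSE) {
  assert_count(n_reads, "n_reads", min = 0L)
  assert_scalar_number(rna_fraction, "rna_fraction", 0, 1)
  if (n_reads == 0L) {
    return(tibble::tibble(read_id = character(), mch = integer(),
                          ch = integer(), mcg = integer(), cg = integer(),
                          true_origin = character()))
  }
  with_seed(seed, {
    origin <- ifelse(runif(n_reads) < rna_fraction, "RNA", "DNA")
    ch <- rpois(n_reads, cytosines_mean)
    shapes <- if (hard) list(rna = c(19, 2), dna = c(5, 5))
              else list(rna = c(50, 1), dna = c(2, 48))
    ratio <- ifelse(origin == "RNA",
                    rbeta(n_reads, shapes$rna[1], shapes$rna[2]),
                    rbeta(n_reads, shapes$dna[1], shapes$dna[2]))
    mch <- rbinom(n_reads, ch, ratio)
    cg <- rpois(n_reads, 2)
    mcg <- rbinom(n_reads, cg, ifelse(origin == "RNA", 0.98, 0.75))
    tibble::tibble(
      read_id = sprintf("read_%06d", seq_len(n_reads)),
      mch = mch, ch = ch, mcg = mcg, cg = cg, true_origin = origin
    )
  })
}

#' Simulate NOMe-seq GpC accessibility counts with cluster-specific open bins
#'
#' Each cluster receives its own set of open bins in which the GmCY rate is
#' elevated above the cell's global GpC methylation level; all other bins sit
#' at the global rate.
#'
#' @param config A [synthetic_config] (cells/clusters/seed are used).
#' @param open_bins_per_cluster Open bins unique to each cluster.
#' @param n_bins Total genomic bins.
#' @param open_rate_factor Fold elevation of the GmCY rate in open bins;
#'   `1` is the degenerate no-signal case.
#' @param coverage_mean Mean GCY basecalls per bin per cell (Poisson).
#' @param global_range Per-cell global GmCY level range.
#'
#' @return A list with `gmcy`, `gcy_cov` (cell-by-bin integer matrices),
#'   `global_rates`, `open_bins` (list of bin indices per cluster),
#'   `cluster_labels`.
#' @export
generate_nome_counts <- function(config, open_bins_per_cluster = 20,
                                 n_bins = 200, open_rate_factor = 5,
                                 coverage_mean = 30,
                                 global_range = c(0.02, 0.05)) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_count(open_bins_per_cluster, "open_bins_per_cluster", min = 0L)
  assert_count(n_bins, "n_bins")
  if (open_bins_per_cluster * config$n_clusters > n_bins) {
    mf_abort("Too many open bins for the number of bins.", "bad_argument")
  }
  with_seed(config$seed + 1L, {
    n <- config$n_cells; k <- config$n_clusters
    labels <- factor(sample(rep_len(seq_len(k), n)),
                     levels = seq_len(k), labels = paste0("C", seq_len(k)))
    cl <- as.integer(labels)
    pool <- sample.int(n_bins, open_bins_per_cluster * k)
    open_bins <- split(pool, rep(seq_len(k), each = open_bins_per_cluster))
    names(open_bins) <- levels(labels)

    global <- runif(n, global_range[1], global_range[2])
    rate <- matrix(global, n, n_bins)
    for (j in seq_len(k)) {
      idx <- cl == j
      rate[idx, open_bins[[j]]] <-
        pmin(rate[idx, open_bins[[j]]] * open_rate_factor, 0.95)
    }
    cov <- matrix(rpois(n * n_bins, coverage_mean), n, n_bins)
    gmcy <- matrix(rbinom(n * n_bins, as.vector(cov), as.vector(rate)),
                   n, n_bins)
    cells <- sprintf("cell_%04d", seq_len(n))
    bins <- sprintf("bin_%04d", seq_len(n_bins))
    dimnames(gmcy) <- dimnames(cov) <- list(cells, bins)
    list(gmcy = gmcy, gcy_cov = cov,
         global_rates = setNames(global, cells),
         open_bins = open_bins,
         cluster_labels = setNames(labels, cells))
  })
}

#' Perturb a clustering for over-/under-splitting fixtures
#'
#' @param labels Per-cell cluster labels (factor or character).
#' @param mode `"split"` randomly halves one cluster, `"merge"` unions two
#'   distinct clusters, `"identity"` returns the input.
#' @param seed Integer seed.
#' @param clusters Optional cluster name(s) to act on: one for `"split"`,
#'   two for `"merge"`; random if omitted.
#'
#' @return Character labels, same length as the input.
#' @export
perturb_labels <- function(labels, mode = c("identity", "split", "merge"),
                           seed = 1L, clusters = NULL) {
  mode <- match.arg(mode)
  if (length(labels) == 0L) mf_abort("`labels` is empty.", "bad_argument")
  lab <- as.character(labels)
  if (mode == "identity") return(lab)
  uniq <- unique(lab)
  with_seed(seed, {
    if (mode == "split") {
      target <- if (is.null(clusters)) sample(uniq, 1) else clusters[1]
      idx <- which(lab == target)
      half <- sample(idx, floor(length(idx) / 2))
      lab[idx] <- paste0(target, ".a")
      lab[half] <- paste0(target, ".b")
    } else {
      if (length(uniq) < 2L) {
        mf_abort("Merge needs at least two clusters.", "bad_argument")
      }
      pair <- if (is.null(clusters)) sample(uniq, 2) else clusters[1:2]
      lab[lab %in% pair] <- paste(sort(pair), collapse = "+")
    }
    lab
  })
}
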