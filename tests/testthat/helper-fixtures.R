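# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small noiseless cohort: exact linear mixtures, identical cells per type
noiseless_cohort <- function() {
  fixture("noiseless", function() simulate_cohort(cohort_config(
    n_genes = 600, n_patients_per_source = c(blood = 2, tumorA = 3,
                                             tumorB = 2),
    cells_per_sample = 80, noise_sd = 0, dropout_rate = 0,
    marker_fraction = 0.08, seed = 101)))
}

# small noisy cohort with source shifts (defaults scaled down)
noisy_cohort <- function() {
  fixture("noisy", function() simulate_cohort(cohort_config(
    n_genes = 800, n_patients_per_source = c(blood = 3, tumorA = 5,
                                             tumorB = 3),
    cells_per_sample = 120, marker_fraction = 0.06, seed = 202)))
}

# tiny deterministic expression matrix
tiny_matrix <- function(vals, genes = NULL, cells = NULL, scale = "TPM") {
  m <- as.matrix(vals)
  if (is.null(genes))
    genes <- if (is.null(rownames(m))) sprintf("g%d", seq_len(nrow(m)))
             else rownames(m)
  if (is.null(cells))
    cells <- if (is.null(colnames(m))) sprintf("c%d", seq_len(ncol(m)))
             else colnames(m)
  rownames(m) <- genes
  colnames(m) <- cells
  expr_scale(m) <- scale
  m
}

# well-conditioned random mixture system on a linear scale
random_mixture <- function(n_genes = 60, types = c("A", "B", "C"),
                           w = c(A = 0.3, B = 0.5, C = 0.2), seed = 1) {
  set.seed(seed)
  B <- matrix(rexp(n_genes * length(types), rate = 1 / 100), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), types))
  list(B = B, w = w, m = drop(B %*% w))
}

# profiles with disjoint gene support per type (orthogonal in linear space)
orthogonal_profiles <- function(n_types = 4, block = 40, level = 6,
                                seed = 1) {
  set.seed(seed)
  n_genes <- n_types * block
  P <- matrix(0, n_genes, n_types,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("T%d", seq_len(n_types))))
  for (k in seq_len(n_types))
    P[(k - 1) * block + seq_len(block), k] <- rnorm(block, level, 0.5)
  P
}

# minimal config whose noise/dropout settings drive simulate_sample
plain_config <- function(noise_sd = 0, dropout_rate = 0) {
  cfg <- cohort_config(n_genes = 600, marker_fraction = 0.08,
                       noise_sd = noise_sd, dropout_rate = dropout_rate,
                       seed = 1)
  cfg
}
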