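# Shared fixture builders: everything is generated in code at test time.

# Random descriptor dataset with ids d001..; descriptors dft_nci, x1..x{p-1}.
random_dataset <- function(n, p = 3, seed = 1, classes = "unknown") {
  stopifnot(p >= 1)
  set.seed(seed)
  desc <- matrix(rnorm(n * p), nrow = n)
  colnames(desc) <- c("dft_nci", if (p > 1) paste0("x", seq_len(p - 1)))
  df <- data.frame(
    id = sprintf("d%03d", seq_len(n)),
    class = rep_len(classes, n),
    desc,
    ref_nci = rnorm(n),
    stringsAsFactors = FALSE
  )
  nci_dataset(df, colnames(desc))
}

# GRNN model on the raw scale (no normalization map), for kernel-math tests.
raw_grnn <- function(patterns, targets, sigma,
                     names = paste0("x", seq_len(ncol(patterns)))) {
  patterns <- as.matrix(patterns)
  colnames(patterns) <- names
  grnncorr:::new_grnn_model(patterns, targets, sigma,
                            descriptor_names = names)
}

# Naive double-loop evaluation of the GRNN prediction formula (independent
# oracle for the vectorized implementation).
grnn_oracle <- function(patterns, targets, sigma, queries) {
  patterns <- as.matrix(patterns)
  queries <- as.matrix(queries)
  out <- numeric(nrow(queries))
  for (q in seq_len(nrow(queries))) {
    num <- 0
    den <- 0
    for (i in seq_len(nrow(patterns))) {
      w <- exp(-sum((queries[q, ] - patterns[i, ])^2) / (2 * sigma^2))
      num <- num + targets[i] * w
      den <- den + w
    }
    out[q] <- num / den
  }
  out
}

# Brute-force SPXY / Kennard-Stone greedy selection on a distance matrix:
# rescans every candidate each step, ties to the lowest index.
greedy_oracle <- function(d, n_train) {
  n <- nrow(d)
  best <- c(1, 2)
  best_d <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (d[i, j] > best_d) {
        best_d <- d[i, j]
        best <- c(i, j)
      }
    }
  }
  sel <- best
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    score <- sapply(cand, function(k) min(d[k, sel]))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

write_xyz <- function(lines) {
  path <- tempfile(fileext = ".xyz")
  writeLines(lines, path)
  path
}

planted_subset <- c("dft_nci", "n_ve", "dipole", "e_lumo1")
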