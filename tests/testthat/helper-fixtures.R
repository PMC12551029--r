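# Fixtures are built in code at test time; nothing is stored on disk.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_beta_tsv <- function(values = c("0.1", "0.2", "0.3", "0.4", "0.5", "0.6")) {
  write_tsv(data.frame(cpg = c("cgA", "cgB", "cgC"),
                       s1 = values[1:3], s2 = values[4:6]))
}

random_bm <- function(n_probes = 20, n_samples = 10, seed = 1) {
  set.seed(seed)
  beta_matrix(matrix(runif(n_probes * n_samples, 0.05, 0.95),
                     n_probes, n_samples,
                     dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                                     paste0("s", seq_len(n_samples)))))
}

tiny_sheet <- function() {
  data.frame(person_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
             couple_id = rep(c("c1", "c1", "c2", "c2"), each = 2),
             wave = rep(c(5L, 6L), 4),
             age = rep(c(40, 42, 50, 48), each = 2),
             sex = rep(c(1L, 0L, 1L, 0L), each = 2),
             binge = rep(c(0, 2, 1, 3), each = 2),
             stringsAsFactors = FALSE)
}

# Draw a masked MVN sample with MCAR missingness.
masked_mvn <- function(n, Sigma, mu = rep(0, ncol(Sigma)), miss = 0.2,
                       seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  X <- matrix(rnorm(n * p), n, p) %*% chol(Sigma) +
    matrix(mu, n, p, byrow = TRUE)
  mask <- matrix(runif(n * p) < miss, n, p)
  # never blank out an entire row
  full <- rowSums(!mask) == 0
  mask[full, 1] <- FALSE
  X[mask] <- NA
  colnames(X) <- paste0("v", seq_len(p))
  X
}
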