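# Independent oracles used across tests.

# 3x3 rotation matrix of a unit quaternion (textbook direction-cosine form),
# independent of the package's quaternion algebra.
quat_to_matrix <- function(q) {
  w <- q[[1]]; x <- q[[2]]; y <- q[[3]]; z <- q[[4]]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# brute-force all-pairs Rand index
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + 1L
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / total
}

random_unit_quat <- function() {
  v <- stats::rnorm(4)
  skiseg::quat(v[1], v[2], v[3], v[4])
}

# least-squares amplitude of a sinusoid at known frequency
fitted_amplitude <- function(x, t, freq) {
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- stats::lm.fit(X, x - mean(x))$coefficients
  sqrt(sum(cf^2))
}

# wrap a plain matrix as the package's feature_matrix shape
make_fm <- function(m, starts = seq_len(nrow(m)) - 1,
                    ends = seq_len(nrow(m)), feature_set = "NFS") {
  structure(as.matrix(m), starts = starts, ends = ends,
            feature_set = feature_set,
            class = c("feature_matrix", "matrix", "array"))
}

# window_labeling with given spans and classes (bypasses clustering)
make_labeling <- function(starts, ends, classes) {
  structure(list(cluster = as.integer(classes == "Skiing") + 1L,
                 starts = starts, ends = ends,
                 class = classes, degenerate = FALSE),
            class = "window_labeling")
}
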