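# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except files the tests write first.

# A tiny hand-specified schema keeps unit tests readable and fast.
tiny_schema <- function(n = 4) {
  build_diffusion_schema("FA")[seq_len(n), , drop = FALSE] |>
    (\(df) structure(df, modality = "diffusion_FA", atlas = "JHU",
                     class = c("roi_schema", "data.frame")))()
}

# Deterministic toy cohort: values are row*100 + column so that any
# reordering or corruption is detectable by eye.
toy_cohort <- function(M = 10, schema = tiny_schema(), groups = NULL,
                       sites = NULL) {
  N <- nrow(schema)
  X <- outer(seq_len(M) * 100, seq_len(N), `+`)
  colnames(X) <- schema$name
  roi_cohort(
    data.frame(subject_id = sprintf("T%03d", seq_len(M)),
               group = groups %||% rep(c("HC", "TLE-HS-L"), length.out = M),
               site = sites %||% rep("siteA", M),
               age = seq(20, 60, length.out = M),
               sex = rep(0:1, length.out = M)),
    X, schema)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_cohort_csv <- function(cohort, path = tempfile(fileext = ".csv")) {
  write_cohort(cohort, path)
  path
}

# Quick two-class Gaussian clouds for classifier tests.
gaussian_clouds <- function(n = 50, p = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, mean = sep), n))
  list(X = X, y = rep(0:1, each = n))
}
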