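# Shared builders for small in-memory fixtures. Everything is generated in
# code at test time; nothing is read from disk.

# Small, fast session config for unit tests.
tiny_config <- function(..., seed = 11L) {
  args <- utils::modifyList(
    list(
      n_neurons_per_plane = 6,
      cell_class = "VIP",
      planes = data.frame(area = c("V1", "V1"), depth = c(100, 300)),
      session_duration = 90,
      seed = seed
    ),
    list(...)
  )
  do.call(generator_config, args)
}

# Exact CP tensor from given factor matrices (lambda = 1).
cp_tensor <- function(A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  X <- array(0, d)
  for (r in seq_len(ncol(A))) {
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  }
  X
}

# Random half-normal factor triple and its tensor.
random_cp_case <- function(n, t, k, rank, seed) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    A <- matrix(abs(rnorm(n * rank)), n, rank)
    B <- matrix(abs(rnorm(t * rank)), t, rank)
    C <- matrix(abs(rnorm(k * rank)), k, rank)
    list(A = A, B = B, C = C, X = cp_tensor(A, B, C))
  })
}

# Aligned tensor with iid noise and given condition labels.
noise_tensor <- function(n, t, k, n_omission = max(2L, round(k / 10)),
                         seed = 1L, sd = 1, identities = 4L) {
  set.seed(seed)
  cond <- c(rep("image", k - n_omission), rep("omission", n_omission))
  aligned_tensor(
    array(rnorm(n * t * k, sd = sd), c(n, t, k)),
    offsets = seq(-0.3, by = 0.1, length.out = t),
    trial_labels = data.frame(
      condition = cond,
      image_identity = ifelse(cond == "image",
                              rep_len(seq_len(identities), k), NA),
      onset_time = seq_len(k) * 0.75,
      wheel = runif(k, 0, 10),
      pupil = runif(k, 100, 400)
    )
  )
}

# Cosine similarity up to sign.
abs_cosine <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
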