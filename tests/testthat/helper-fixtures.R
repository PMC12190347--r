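# shared fixture builders (all data generated in code)

tiny_grid <- function() {
  time_grid(c("Before Surgery", "1 hour", "1 day", "4 days"),
            c(0, 1, 24, 96))
}

# genes x patients x time array from a list of per-patient matrices
tensor_from <- function(per_patient, scale = "raw", grid = tiny_grid(),
                        mask = NULL) {
  arr <- array(NA_real_, c(nrow(per_patient[[1]]), length(per_patient),
                           ncol(per_patient[[1]])))
  for (p in seq_along(per_patient)) arr[, p, ] <- per_patient[[p]]
  expression_tensor(arr, mask = mask, scale = scale, grid = grid)
}

# a hand-built trained_map that outputs a constant vector
const_map <- function(input_dim, output_dim, cvec, direction = "reverse") {
  structure(list(
    spec = net_spec(input_dim, output_dim, hidden_dims = 2, dropout_p = 0),
    layers = list(list(W = matrix(0, input_dim, 2), b = c(0, 0)),
                  list(W = matrix(0, 2, output_dim), b = cvec)),
    norm = list(x = list(mu = rep(0, input_dim), sd = rep(1, input_dim)),
                y = list(mu = rep(0, output_dim), sd = rep(1, output_dim))),
    training_log = numeric(0), direction = direction),
    class = "trained_map")
}

# brute-force topological overlap (independent triple-loop oracle)
tom_bruteforce <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}
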