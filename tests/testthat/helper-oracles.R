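# Independent oracle: Shapley value as the average marginal contribution
# over all k! feature orderings, with coalition values computed by a
# one-background-row-at-a-time masking loop (deliberately different code
# path from the package's batched coalition enumeration).
brute_force_shapley <- function(model, x_row, background, features) {
  k <- length(features)
  v <- function(S) {
    preds <- vapply(seq_len(nrow(background)), function(b) {
      z <- background[b, , drop = FALSE]
      for (f in S) z[[f]] <- x_row[[f]]
      as.numeric(predict(model, z))
    }, numeric(1))
    mean(preds)
  }
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  phi <- setNames(numeric(k), features)
  for (ord in all_perms(features)) {
    S <- character(0)
    v_prev <- v(S)
    for (f in ord) {
      S <- c(S, f)
      v_new <- v(S)
      phi[f] <- phi[f] + (v_new - v_prev)
      v_prev <- v_new
    }
  }
  phi / factorial(k)
}
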