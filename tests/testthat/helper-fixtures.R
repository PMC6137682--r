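# Shared fixture builders (everything generated in code; no binary files).

tiny_dataset <- function() {
  rtc_dataset(X = matrix(c(1, 0, 1, 0, 0, 1), 3, 2),
              T = matrix(1, 3, 2))
}

# explicit small item set for a given model kind
fixed_items <- function(model, K, M = 5L) {
  B <- rtcondep:::model_basis_dim(model, M)
  alpha <- cbind(seq(0.8, 1.4, length.out = K), matrix(0, K, B - 1L))
  beta <- cbind(seq(-0.8, 0.8, length.out = K), matrix(0, K, B - 1L))
  list(alpha = alpha, beta = beta,
       xi = seq(3.2, 4, length.out = K),
       sigma = seq(0.3, 0.5, length.out = K))
}

write_csv_pair <- function(d, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  xp <- file.path(dir, "x.csv"); tp <- file.path(dir, "t.csv")
  write_dataset(d, xp, tp)
  list(x = xp, t = tp)
}
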