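# Fixtures built in code.

# Small worked fixture used across method tests: 3 genes x 4 samples.
fixture_f1 <- function() {
  ct <- rbind(g1 = c(20.0, 20.5, 19.8, 20.2),
              g2 = c(22.0, 22.6, 21.7, 22.3),
              g3 = c(25.0, 24.0, 26.0, 24.5))
  make_ct(ct)
}

# Wrap a plain genes x samples matrix in a collapsed ct_matrix with
# minimal metadata.
make_ct <- function(ct, condition = NULL, timepoint = "0") {
  S <- ncol(ct)
  if (is.null(rownames(ct))) rownames(ct) <- paste0("g", seq_len(nrow(ct)))
  samples <- data.frame(
    sample_id = paste0("s", seq_len(S)),
    condition = condition %||% rep("ctrl", S),
    timepoint = rep(timepoint, length.out = S),
    bio_rep = seq_len(S), tech_rep = 1L,
    stringsAsFactors = FALSE)
  ct_matrix(ct, samples, collapsed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random complete Ct matrix with values safely inside [5, 45].
random_ct_matrix <- function(G = 5L, S = 8L, seed = 1L) {
  withr::with_seed(seed, {
    ct <- matrix(stats::runif(G * S, 15, 30), G, S,
                 dimnames = list(paste0("g", seq_len(G)), NULL))
    make_ct(ct)
  })
}
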