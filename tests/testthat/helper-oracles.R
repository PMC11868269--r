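# Independent brute-force oracles: direct formula enumeration with plain
# loops, sharing no code with the package internals.

oracle_delta_ct <- function(ct) {
  G <- nrow(ct)
  out <- numeric(G)
  for (i in seq_len(G)) {
    sds <- c()
    for (k in seq_len(G)) {
      if (k == i) next
      sds <- c(sds, stats::sd(ct[i, ] - ct[k, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(ct)
  out
}

oracle_q <- function(ct, eff = 1) {
  q <- ct
  for (i in seq_len(nrow(ct))) {
    q[i, ] <- (1 + eff)^(-(ct[i, ] - min(ct[i, ])))
  }
  q
}

oracle_genorm_m <- function(q) {
  G <- nrow(q)
  out <- numeric(G)
  for (i in seq_len(G)) {
    sds <- c()
    for (k in seq_len(G)) {
      if (k == i) next
      sds <- c(sds, stats::sd(log2(q[i, ] / q[k, ])))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(q)
  out
}

# Stepwise exclusion by brute-force M recomputation; returns the exclusion
# order (first removed first).
oracle_genorm_exclusion <- function(q) {
  remaining <- rownames(q)
  order_out <- character()
  while (length(remaining) > 2L) {
    M <- oracle_genorm_m(q[remaining, , drop = FALSE])
    worst <- names(which.max(M))
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(excluded = order_out, final_pair = remaining)
}

oracle_v_value <- function(q, top_n, top_n1) {
  nf_n <- apply(q[top_n, , drop = FALSE], 2, function(x) prod(x)^(1 / length(x)))
  nf_n1 <- apply(q[top_n1, , drop = FALSE], 2, function(x) prod(x)^(1 / length(x)))
  stats::sd(log2(nf_n / nf_n1))
}

# NormFinder by direct evaluation of the model formulas.
oracle_normfinder <- function(q, groups = NULL) {
  y <- log2(q)
  I <- nrow(y)
  S <- ncol(y)
  if (is.null(groups)) groups <- rep("all", S)
  groups <- as.character(groups)
  glev <- unique(groups)
  z <- y
  for (j in seq_len(S)) z[, j] <- y[, j] - mean(y[, j])
  ng <- sapply(glev, function(g) sum(groups == g))
  zbar <- sapply(glev, function(g) apply(z[, groups == g, drop = FALSE], 1, mean))
  s2 <- sapply(glev, function(g) apply(z[, groups == g, drop = FALSE], 1, stats::var))
  sigma2 <- s2
  for (g in seq_along(glev)) {
    Sg <- sum(s2[, g])
    for (i in seq_len(I)) {
      sigma2[i, g] <- max(0, (s2[i, g] - Sg / (I * (I - 1))) * I / (I - 2))
    }
  }
  if (length(glev) == 1L) {
    rho <- sqrt(sigma2[, 1])
    names(rho) <- rownames(y)
    return(list(rho = rho, d = NULL, gamma2 = NA))
  }
  overall <- numeric(I)
  for (i in seq_len(I)) overall[i] <- sum(zbar[i, ] * ng) / sum(ng)
  d <- zbar - overall
  gamma2 <- sum(d^2) / ((length(glev) - 1) * (I - 1)) -
    mean(sweep(sigma2, 2, ng, "/"))
  gamma2 <- max(0, gamma2)
  if (gamma2 == 0) {
    s2p <- apply(z, 1, stats::var)
    sig2p <- pmax(0, (s2p - sum(s2p) / (I * (I - 1))) * I / (I - 2))
    rho <- sqrt(sig2p)
    names(rho) <- rownames(y)
    return(list(rho = rho, d = d, gamma2 = 0))
  }
  rho <- numeric(I)
  for (i in seq_len(I)) {
    acc <- 0
    for (g in seq_along(glev)) {
      v <- sigma2[i, g] / ng[g]
      dt <- d[i, g] * gamma2 / (gamma2 + v)
      acc <- acc + abs(dt) + sqrt(v * gamma2 / (gamma2 + v))
    }
    rho[i] <- acc / length(glev)
  }
  names(rho) <- rownames(y)
  list(rho = rho, d = d, gamma2 = gamma2)
}

oracle_bestkeeper <- function(ct) {
  G <- nrow(ct)
  sd_ct <- cv <- r <- numeric(G)
  idx <- numeric(ncol(ct))
  for (j in seq_len(ncol(ct))) idx[j] <- prod(ct[, j])^(1 / G)
  for (i in seq_len(G)) {
    sd_ct[i] <- stats::sd(ct[i, ])
    cv[i] <- sd_ct[i] / mean(ct[i, ]) * 100
    r[i] <- stats::cor(ct[i, ], idx)
  }
  data.frame(gene_id = rownames(ct), sd_ct = sd_ct, cv_pct = cv,
             r_index = r, stringsAsFactors = FALSE)
}
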