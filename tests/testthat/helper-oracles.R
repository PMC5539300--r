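# Independent brute-force oracles, deliberately written with explicit loops
# and different numerical routes than the package implementations.

# Moderated t: explicit means/variances, moment equations on log s^2, and a
# uniroot-based trigamma inversion (the package uses a Newton iteration).
oracle_mod_t <- function(A, B, paired = FALSE) {
  if (paired) {
    D <- A - B
    m <- ncol(D)
    lfc <- apply(D, 1, mean)
    s2 <- apply(D, 1, var)
    df <- m - 1
    cn <- sqrt(1 / m)
  } else {
    lfc <- apply(A, 1, mean) - apply(B, 1, mean)
    na <- ncol(A); nb <- ncol(B)
    s2 <- ((na - 1) * apply(A, 1, var) + (nb - 1) * apply(B, 1, var)) /
      (na + nb - 2)
    df <- na + nb - 2
    cn <- sqrt(1 / na + 1 / nb)
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    half <- uniroot(function(x) trigamma(x) - evar,
                    lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * half
    s02 <- exp(mean(e) + digamma(half) - log(half))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  s2post <- if (is.finite(d0)) (d0 * s02 + df * s2) / (d0 + df) else rep(s02, length(s2))
  tmod <- lfc / (sqrt(s2post) * cn)
  p <- 2 * pt(-abs(tmod), df = if (is.finite(d0)) d0 + df else Inf)
  list(lfc = lfc, t = tmod, p = p, d0 = d0, s02 = s02)
}

# Benjamini-Hochberg step-up, written out rank by rank.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Type-7 quantile by hand: h = (n-1)p, linear interpolation of sorted values.
oracle_quantile7 <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  sapply(probs, function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    hi <- min(lo + 1, n)
    xs[lo] + (h - (lo - 1)) * (xs[hi] - xs[lo])
  })
}

# Small random count fixture with stable IDs.
random_counts <- function(nf = 50, ns = 6, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(nf * ns, lambda), nf, ns,
              dimnames = list(sprintf("F%03d", seq_len(nf)),
                              sprintf("S%02d", seq_len(ns))))
  expression_matrix(m, unit = "count")
}

# Annotation for a matrix: first n_rep rows are repeats cycling over types.
random_annotation <- function(x, n_rep, types = default_te_taxonomy(), seed = 1) {
  set.seed(seed)
  fid <- feature_ids(x)
  nf <- length(fid)
  kind <- c(rep("repeat", n_rep), rep("coding", nf - n_rep))
  tt <- character(nf)
  tc <- character(nf)
  if (n_rep) {
    idx <- (seq_len(n_rep) - 1L) %% nrow(types) + 1L
    tt[seq_len(n_rep)] <- types$te_type[idx]
    tc[seq_len(n_rep)] <- types$te_class[idx]
  }
  sym <- character(nf)
  if (nf > n_rep) sym[(n_rep + 1L):nf] <- sprintf("SYM%03d", seq_len(nf - n_rep))
  te_annotation(data.frame(
    feature_id = fid, kind = kind, te_type = tt, te_class = tc,
    gene_symbol = sym,
    effective_length = round(runif(nf, 200, 5000)),
    stringsAsFactors = FALSE))
}

# Metadata for an unpaired two-group layout over the samples of x.
two_group_meta <- function(x, n_a = NULL) {
  sid <- sample_ids(x)
  if (is.null(n_a)) n_a <- ceiling(length(sid) / 2)
  sample_metadata(data.frame(
    sample_id = sid,
    group = c(rep("A", n_a), rep("B", length(sid) - n_a)),
    patient_id = "", stringsAsFactors = FALSE))
}

# A te_de object built directly from a vector of statistics, for tests of
# downstream stages that only consume t_mod / p / fdr.
fake_de <- function(t_mod, feature_id = sprintf("F%04d", seq_along(t_mod)),
                    df = 10) {
  p <- 2 * pt(-abs(t_mod), df = df)
  res <- data.frame(feature_id = feature_id, logFC = t_mod, t_mod = t_mod,
                    p = p, fdr = p.adjust(p, "BH"), mean_expr = 5,
                    stringsAsFactors = FALSE)
  structure(res, class = c("te_de", "data.frame"),
            contrast = define_contrast("A", "B"), d0 = Inf, s0_2 = 1,
            df_resid = df, df_total = df, n_a = 5, n_b = 5)
}
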