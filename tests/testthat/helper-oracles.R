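# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, fixpoint iteration, closed form) kept separate
# from the code paths it checks.

# Hardy-Weinberg exact test by direct enumeration of all heterozygote counts
# compatible with the observed allele counts (factorials, no log tricks).
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  het <- seq(nr %% 2, nr, by = 2)
  mass <- vapply(het, function(h) {
    a <- (nr - h) / 2
    A <- n - h - a
    exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(A) +
          h * log(2))
  }, numeric(1))
  mass <- mass / sum(mass)
  obs <- mass[match(n_Aa, het)]
  sum(mass[mass <= obs * (1 + 1e-12)])
}

# Connected components by repeated pairwise merging until fixpoint.
components_fixpoint_oracle <- function(cs_sets) {
  comps <- lapply(names(cs_sets), function(id) {
    list(ids = id, vars = cs_sets[[id]])
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(comps)) {
      if (merged) break
      for (j in seq_along(comps)) {
        if (j <= i) next
        if (length(intersect(comps[[i]]$vars, comps[[j]]$vars)) > 0) {
          comps[[i]]$ids <- sort(union(comps[[i]]$ids, comps[[j]]$ids))
          comps[[i]]$vars <- union(comps[[i]]$vars, comps[[j]]$vars)
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  sets <- lapply(comps, function(c) sort(c$ids))
  sets[order(vapply(sets, `[`, "", 1))]
}

# Colocalisation posteriors by explicit summation over causal-variant
# configurations: H0 {}, H1 variant j in study 1 only, H2 k in study 2 only,
# H3 (j, k) with j != k, H4 shared j.
coloc_config_oracle <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  K <- length(a)
  w <- c(H0 = 1,
         H1 = p1 * sum(exp(a)),
         H2 = p2 * sum(exp(b)),
         H3 = p1 * p2 * (sum(outer(exp(a), exp(b)))
                         - sum(exp(a) * exp(b))),
         H4 = p12 * sum(exp(a) * exp(b)))
  if (K == 1) w["H3"] <- 0
  w / sum(w)
}

# Closed-form OLS coefficient and standard error for y ~ X (with intercept
# already included in X), via the normal equations.
ols_closed_form <- function(y, X) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(beta = drop(beta), se = sqrt(diag(XtX_inv) * sigma2), df = df)
}

# Small random credible-set instance generator for component tests.
random_cs_instance <- function(n_cs, n_var_pool, seed) {
  set.seed(seed)
  pool <- sprintf("chr1_%d_A_G", seq_len(n_var_pool) * 100)
  sets <- lapply(seq_len(n_cs), function(i) {
    sort(sample(pool, sample(1:4, 1)))
  })
  names(sets) <- sprintf("cs%02d", seq_len(n_cs))
  sets
}

cs_sets_to_df <- function(sets, trait = NULL) {
  do.call(rbind, lapply(names(sets), function(id) {
    data.frame(molecular_trait_id = if (is.null(trait)) id else trait,
               molecular_trait_object_id = "G",
               cs_id = id, variant = sets[[id]],
               pip = 0.5, z = 5, stringsAsFactors = FALSE)
  }))
}
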