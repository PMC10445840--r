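# Shared fixtures, memoized across test files (built on first use).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

# A mid-gestation phantom on the default grid.
fix_phantom <- function(seed = 3, ga_weeks = 26, severity = 0.5) {
  memo(sprintf("phantom_%d_%d_%g", seed, ga_weeks, severity),
       make_phantom(phantom_spec(ga_from_weeks_days(ga_weeks),
                                 severity = severity, seed = seed)))
}

# Small, fast phantom for registration-scale tests.
fix_phantom48 <- function(seed = 7, ga_weeks = 25) {
  memo(sprintf("phantom48_%d_%d", seed, ga_weeks),
       make_phantom(phantom_spec(ga_from_weeks_days(ga_weeks),
                                 severity = 0.5, seed = seed,
                                 grid_shape = c(48L, 48L, 48L),
                                 spacing = 1.0)))
}

# Cohort sized for full pipeline runs (48^3 grids, 22-29 weeks).
fix_cohort <- function() {
  memo("cohort48",
       make_cohort(8, ga_range = c(154L, 203L), seed = 5,
                   grid_shape = c(48L, 48L, 48L), spacing = 1.0))
}

# Tiny cohort for orchestration/IO tests.
fix_tiny_cohort <- function() {
  memo("cohort32",
       make_cohort(5, ga_range = c(154L, 189L), seed = 11,
                   operated_split = 0, longitudinal = TRUE,
                   grid_shape = c(36L, 36L, 36L), spacing = 1.4))
}

# One fully refined atlas time point (first retained group of fix_cohort).
fix_atlas <- function() {
  memo("atlas_tp", {
    cfg <- pipeline_config()
    groups <- build_groups(fix_cohort(), cfg)
    ag <- augment_group(groups[[1L]])
    refine_atlas(initialize_atlas(ag, cfg), ag, cfg)
  })
}

# ---------------------------------------------------------------------------
# Independent oracle for the weighted generalized Procrustes problem: a
# generic multi-restart quasi-Newton optimizer over all 6n + 3K variables,
# with the consensus parameterized on the constraint manifold and
# log-scales keeping the scalings positive.  It shares no code with
# solve_wgp().

wgp_oracle <- function(landmarks, weights, restarts = 20, seed = 99) {
  ids <- colnames(weights); n <- nrow(weights); K <- length(ids)
  X <- array(0, c(n, K, 3))
  for (i in seq_len(n)) {
    m <- unclass(landmarks[[i]])
    X[i, match(rownames(m), ids), ] <- ifelse(is.na(m), 0, m)
  }
  xbar <- t(sapply(seq_len(K), function(k) {
    w <- weights[, k]
    colSums(matrix(X[, k, ][w > 0, ], ncol = 3) * w[w > 0]) / sum(w)
  }))
  ctr <- colMeans(xbar)
  s2 <- mean(rowSums(sweep(xbar, 2, ctr, "-")^2)); rho <- sqrt(s2)
  unpack <- function(par) list(L = matrix(par[1:(3 * n)], n, 3),
                               Tt = matrix(par[3 * n + 1:(3 * n)], n, 3),
                               H = matrix(par[6 * n + 1:(3 * K)], K, 3))
  gfun <- function(H) {
    hc <- sweep(H, 2, colMeans(H), "-")
    nrm <- sqrt(sum(hc^2) / K)
    list(g = sweep(hc * rho / max(nrm, 1e-300), 2, ctr, "+"),
         hc = hc, nrm = nrm)
  }
  fn <- function(par) {
    p <- unpack(par); g <- gfun(p$H)$g
    tot <- 0
    for (i in seq_len(n)) {
      r <- sweep(X[i, , ] * matrix(exp(p$L[i, ]), K, 3, byrow = TRUE),
                 2, p$Tt[i, ], "+") - g
      tot <- tot + 0.5 * sum(weights[i, ] * rowSums(r^2))
    }
    tot
  }
  gr <- function(par) {
    p <- unpack(par); gg <- gfun(p$H); g <- gg$g
    gL <- matrix(0, n, 3); gT <- matrix(0, n, 3); G <- matrix(0, K, 3)
    for (i in seq_len(n)) {
      s <- exp(p$L[i, ])
      y <- sweep(X[i, , ] * matrix(s, K, 3, byrow = TRUE), 2, p$Tt[i, ], "+")
      r <- weights[i, ] * (y - g)
      gT[i, ] <- colSums(r)
      gL[i, ] <- colSums(r * X[i, , ]) * s
      G <- G - r
    }
    hc <- gg$hc; nrm <- max(gg$nrm, 1e-300)
    gH <- rho / nrm * (G - hc * sum(hc * G) / (K * nrm^2))
    gH <- sweep(gH, 2, colMeans(gH), "-")
    c(as.vector(gL), as.vector(gT), as.vector(gH))
  }
  set.seed(seed)
  span <- max(apply(xbar, 2, function(v) diff(range(v))), 1)
  best <- Inf; best_par <- NULL
  for (r in seq_len(restarts)) {
    p0 <- switch(1 + (r %% 4),
      c(rnorm(3 * n, 0, 0.05), rnorm(3 * n, 0, 0.5),
        as.vector(sweep(xbar, 2, ctr, "-")) + rnorm(3 * K, 0, 0.2)),
      c(rnorm(3 * n, 0, 0.4), rnorm(3 * n, 0, span / 2),
        rnorm(3 * K, 0, 2)),
      c(rnorm(3 * n, -2, 1), rnorm(3 * n, 0, span / 2),
        rnorm(3 * K, 0, 2)),
      { h <- matrix(0, K, 3); h[, sample(1:3, 1)] <- rnorm(K, 0, 2)
        c(rnorm(3 * n, 0, 0.3), rnorm(3 * n, 0, span / 2),
          as.vector(h)) })
    o <- stats::optim(p0, fn, gr, method = "BFGS",
                      control = list(maxit = 800, reltol = 1e-15))
    if (o$value < best) { best <- o$value; best_par <- o$par }
  }
  o <- stats::optim(best_par, fn, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-16))
  min(best, o$value)
}

# Random WGP instance: noisy anisotropically scaled + translated copies of a
# common 7-landmark configuration, with missing annotations.
wgp_instance <- function(seed, n = 3, miss_frac = 0.3, noise_sd = 0.8) {
  set.seed(seed)
  reg <- landmark_registry(); ids <- reg$id[reg$retained]
  base <- matrix(stats::rnorm(21, sd = 8), 7, 3, dimnames = list(ids, NULL))
  lms <- list(); W <- matrix(0, n, 7, dimnames = list(NULL, ids))
  repeat {
    miss <- matrix(stats::runif(n * 7) < miss_frac, n, 7)
    if (all(colSums(!miss) > 0) && all(rowSums(!miss) >= 3)) break
  }
  for (i in seq_len(n)) {
    sc <- exp(stats::rnorm(3, 0, 0.15)); tr <- stats::rnorm(3, 0, 4)
    m <- sweep(sweep(base, 2, sc, "*"), 2, tr, "+") +
      matrix(stats::rnorm(21, sd = noise_sd), 7, 3)
    m[miss[i, ], ] <- NA
    lms[[i]] <- landmark_set(m)
    W[i, !miss[i, ]] <- stats::runif(1, 0.2, 1)
  }
  list(landmarks = lms, weights = W)
}

# Naive double-loop objective recomputation (independent of the package's
# vectorized path).
wgp_objective_naive <- function(landmarks, weights, transforms, consensus) {
  ids <- colnames(weights)
  tot <- 0
  for (i in seq_len(nrow(weights))) {
    li <- unclass(landmarks[[i]])
    for (k in seq_along(ids)) {
      w <- weights[i, k]
      if (w == 0) next
      x <- li[ids[k], ]
      y <- transforms[[i]]$scale * x + transforms[[i]]$translation
      tot <- tot + 0.5 * w * sum((y - consensus[k, ])^2)
    }
  }
  as.numeric(tot)
}
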