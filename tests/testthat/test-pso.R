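# independent scalar transcription of one inertia-weighted update with
# clipping and reinitialization, mirroring the documented draw order
oracle_pso_run <- function(cfg, objective, n_iter) {
  set.seed(cfg$seed)
  sub <- init_subdomains(cfg$bounds, cfg$M)
  d <- cfg$dim; M <- cfg$M
  x <- matrix(NA_real_, M, d)
  for (j in 1:M) x[j, ] <- stats::runif(d, sub[[j]]["lo", ], sub[[j]]["hi", ])
  v <- matrix(0, M, d)
  p <- x
  pv <- apply(x, 1, objective)
  gi <- which.min(pv); g <- p[gi, ]; gv <- pv[gi]
  for (k in 0:(n_iter - 1)) {
    w <- cfg$w1 - cfg$w2 * k / cfg$I
    r1 <- matrix(stats::runif(M * d), M, d)
    r2 <- matrix(stats::runif(M * d), M, d)
    for (j in 1:M) {
      vb <- w * v[j, ] + cfg$c1 * r1[j, ] * (p[j, ] - x[j, ]) +
        cfg$c2 * r2[j, ] * (g - x[j, ])
      xb <- x[j, ] + vb
      xt <- ifelse(xb < 0, 0, xb)
      v[j, ] <- xt - x[j, ]
      x[j, ] <- xt
    }
    val <- apply(x, 1, objective)
    for (j in 1:M) if (val[j] < pv[j]) { pv[j] <- val[j]; p[j, ] <- x[j, ] }
    gi <- which.min(pv); g <- p[gi, ]; gv <- pv[gi]
    re <- stats::runif(M) < cfg$P
    for (j in which(re)) {
      x[j, ] <- stats::runif(d, sub[[j]]["lo", ], sub[[j]]["hi", ])
      v[j, ] <- 0
    }
  }
  list(g = g, gv = gv)
}

test_that("subdomains slice the box into disjoint slabs covering it", {
  b <- c(10, 3, 3)
  s1 <- init_subdomains(b, 1)
  expect_equal(s1[[1]]["lo", ], c(0, 0, 0))
  expect_equal(s1[[1]]["hi", ], b)
  s2 <- init_subdomains(b, 2)
  expect_equal(unname(s2[[1]]["hi", 1]), 5)
  expect_equal(unname(s2[[2]]["lo", 1]), 5)
  s5 <- init_subdomains(b, 5)
  los <- unname(sapply(s5, function(s) s["lo", 1]))
  his <- unname(sapply(s5, function(s) s["hi", 1]))
  expect_equal(los[-1], his[-5])            # half-open, pairwise disjoint
  expect_equal(his[5], 10)                  # union is the box
})

test_that("initialization places one zero-velocity particle per subdomain", {
  cfg <- swarm_config(dim = 3, M = 6, I = 10, bounds = c(6, 2, 2), seed = 3)
  obj <- function(x) sum(x^2)
  set.seed(cfg$seed)
  st <- init_swarm(cfg, obj)
  for (j in 1:6) {
    box <- st$subdomains[[j]]
    expect_true(all(st$x[j, ] >= box["lo", ] & st$x[j, ] <= box["hi", ]))
  }
  expect_true(all(st$v == 0))
  expect_equal(st$p, st$x)
  expect_equal(st$g_value, min(st$p_value))
  set.seed(cfg$seed)
  st2 <- init_swarm(cfg, obj)
  expect_identical(st$x, st2$x)
})

test_that("swarm updates match an independent transcription step for step", {
  cfg <- swarm_config(dim = 4, M = 5, I = 20, P = 0.3,
                      bounds = c(4, 1, 1, 1), seed = 11)
  obj <- function(x) sum((x - c(0.5, 0.2, 0.9, 0.1))^2)
  fit <- pso_optimize(swarm_config(dim = 4, M = 5, I = 7, P = 0.3,
                                   bounds = c(4, 1, 1, 1), seed = 11), obj)
  want <- oracle_pso_run(list(dim = 4, M = 5, I = 7, P = 0.3, w1 = 0.9,
                              w2 = 0.5, c1 = 1.49, c2 = 1.49,
                              bounds = c(4, 1, 1, 1), seed = 11), obj, 7)
  expect_equal(fit$par, want$g, tolerance = 1e-14)
  expect_equal(fit$value, want$gv, tolerance = 1e-14)
})

test_that("positions stay nonnegative and the best value never worsens", {
  # minimum outside the box pushes particles against the clipping boundary
  obj <- function(x) sum((x + 0.5)^2)
  cfg <- swarm_config(dim = 3, M = 8, I = 40, bounds = c(2, 2, 2), seed = 5)
  set.seed(cfg$seed)
  st <- init_swarm(cfg, obj)
  for (k in 1:40) {
    st <- pso_step(st, cfg, obj)
    expect_true(all(st$x >= 0))
  }
  expect_true(all(diff(st$history) <= 0))
  expect_equal(st$g, c(0, 0, 0), tolerance = 1e-6)
})

test_that("a constant objective keeps the initial personal bests (strict rule)", {
  obj <- function(x) 42
  cfg <- swarm_config(dim = 2, M = 4, I = 5, bounds = c(1, 1), seed = 9)
  set.seed(cfg$seed)
  st0 <- init_swarm(cfg, obj)
  st <- st0
  for (k in 1:5) st <- pso_step(st, cfg, obj)
  expect_identical(st$p, st0$p)
  expect_equal(st$g_value, 42)
})

test_that("sphere recovery works across seeds with reference constants", {
  target <- c(0.3, 0.7, 0.5, 0.2, 0.8, 0.4)
  obj <- function(x) sum((x - target)^2)
  for (s in 1:2) {
    fit <- pso_optimize(swarm_config(dim = 6, M = 16, I = 300,
                                     bounds = rep(1, 6), seed = s), obj)
    expect_lt(fit$value, 1e-3)
    expect_lt(max(abs(fit$par - target)), 1e-2)
    expect_length(fit$history, 301)
    expect_true(all(diff(fit$history) <= 0))
  }
})

test_that("the full run is determined by the seed", {
  obj <- function(x) sum(x^2)
  cfg <- swarm_config(dim = 3, M = 6, I = 25, bounds = c(3, 3, 3), seed = 17)
  a <- pso_optimize(cfg, obj)
  b <- pso_optimize(cfg, obj)
  expect_identical(a$par, b$par)
  expect_identical(a$history, b$history)
})

test_that("non-finite objectives are rejected", {
  cfg <- swarm_config(dim = 2, M = 2, I = 2, bounds = c(1, 1), seed = 1)
  expect_error(pso_optimize(cfg, function(x) NaN), "non-finite")
})
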