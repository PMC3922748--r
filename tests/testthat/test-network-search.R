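test_that("partial correlation: identity, first-order formula, recursion oracle", {
  ## no dependence under an identity covariance
  expect_equal(partial_correlation(diag(4), 1, 2, 3), 0)
  expect_equal(partial_correlation(diag(4), 1, 4), 0)

  ## equicorrelated 3x3 with rho = 0.5: rho(1,2|3) = (0.5 - 0.25)/0.75
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  expect_equal(partial_correlation(S, 1, 2, 3), 1 / 3, tolerance = 1e-12)

  ## inversion method equals the first-order recursion on random SPD
  ## matrices, growing the conditioning set one variable at a time
  set.seed(11)
  recursive_pc <- function(S, i, j, cond) {
    if (length(cond) == 0L)
      return(S[i, j] / sqrt(S[i, i] * S[j, j]))
    k <- cond[length(cond)]
    rest <- cond[-length(cond)]
    rij <- recursive_pc(S, i, j, rest)
    rik <- recursive_pc(S, i, k, rest)
    rjk <- recursive_pc(S, j, k, rest)
    (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
  }
  for (rep in 1:20) {
    t <- sample(4:6, 1L)
    L <- matrix(rnorm(t * t), t)
    S <- crossprod(L) + diag(t) * 0.5
    v <- sample(t, 4L)
    got <- partial_correlation(S, v[1L], v[2L], v[3:4])
    want <- recursive_pc(S, v[1L], v[2L], v[3:4])
    expect_equal(got, want, tolerance = 1e-10)
  }

  ## singular submatrix carries the condition number in the error
  Sing <- matrix(1, 3, 3)
  expect_error(partial_correlation(Sing, 1, 2, 3), "condition number")
})

test_that("IC test counts follow the pair/subset formulas", {
  expect_equal(count_ic_tests(14),
               list(n_pairs = 91, n_subsets_per_pair = 4096,
                    n_total = 372736))
  expect_equal(count_ic_tests(2),
               list(n_pairs = 1, n_subsets_per_pair = 1, n_total = 1))
  expect_equal(count_ic_tests(5),
               list(n_pairs = 10, n_subsets_per_pair = 8, n_total = 80))
  expect_error(count_ic_tests(1), ">= 2")

  ## the evaluated plan always has exactly n_total series
  for (t in 3:6) {
    arr <- array(diag(t), c(t, t, 40))
    ppc <- posterior_partial_correlations(arr)
    expect_equal(nrow(ppc$index), count_ic_tests(t)$n_total)
  }
})

test_that("posterior partial correlations: degenerate posterior is a point mass", {
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  arr <- array(S, c(4, 4, 50))
  ppc <- posterior_partial_correlations(arr)
  for (r in sample(nrow(ppc$index), 10L)) {
    want <- partial_correlation(S, ppc$index$i[r], ppc$index$j[r],
                                ppc$subsets[[r]])
    expect_equal(unique(ppc$draws[r, ]), want, tolerance = 1e-12)
  }
  expect_equal(ppc$n_excluded, 0L)
})

test_that("HPD interval: point mass, full content, analytic exponential", {
  expect_equal(hpd_interval(rep(3, 100), 0.95), c(3, 3))
  expect_equal(hpd_interval(rep(0, 100), 0.95), c(0, 0))
  x <- rnorm(100)
  expect_equal(hpd_interval(x, 1.0), range(x))
  expect_error(hpd_interval(1:5, 0.9), "at least 10")
  expect_error(hpd_interval(rnorm(100), 1.5), "content")

  ## monotone density: HPD of Exp(1) at 95% is (0, -log(0.05))
  set.seed(2)
  h <- hpd_interval(rexp(4e5), 0.95)
  expect_lt(h[1L], 0.02)
  expect_equal(h[2L], -log(0.05), tolerance = 0.02)
})

test_that("effective sample size: iid limit, AR(1) closed form, constant chain", {
  set.seed(3)
  ess_iid <- effective_sample_size(rnorm(1e4))
  expect_gt(ess_iid, 0.9e4)
  expect_lte(ess_iid, 1e4)

  rho <- 0.9
  n <- 1e5
  x <- as.numeric(arima.sim(list(ar = rho), n))
  want <- n * (1 - rho) / (1 + rho)
  expect_equal(effective_sample_size(x), want, tolerance = 0.15)

  expect_warning(z <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(z, 0)
})

test_that("skeleton and orientation on simulated chain and collider structures", {
  set.seed(17)
  ## 5-trait chain: skeleton is the path, no colliders, step 3 inert
  y <- simulate_reduced_form(chain_lambda(5, 0.9), 5000)
  arr <- covariance_posterior_draws(y, 300)
  sk <- ic_skeleton(posterior_partial_correlations(arr), 0.95)
  expect_equal(pdag_adjacency(sk$graph), dag_skeleton(chain_lambda(5)))
  g2 <- orient_colliders(sk)
  expect_equal(sum(g2$edges$mark == "directed"), 0L)
  g3 <- propagate_orientations(g2)
  expect_equal(g3$edges, g2$edges)

  ## collider 1 -> 2 <- 3: only the marginal set separates (1,3)
  lamc <- matrix(0, 3, 3); lamc[2, 1] <- 0.8; lamc[2, 3] <- 0.8
  yc <- simulate_reduced_form(lamc, 5000)
  arrc <- covariance_posterior_draws(yc, 300)
  skc <- ic_skeleton(posterior_partial_correlations(arrc), 0.95)
  expect_equal(pdag_adjacency(skc$graph), dag_skeleton(lamc))
  gc2 <- orient_colliders(skc)
  expect_setequal(pdag_directed_edges(gc2), c("1->2", "3->2"))

  ## mutually independent traits: edge set empty in the large majority of
  ## runs (each pair has ~the HPD miscoverage probability of a false edge)
  n_edges <- vapply(1:10, function(s) {
    set.seed(100 + s)
    y0 <- matrix(rnorm(3000 * 3), ncol = 3)
    arr0 <- covariance_posterior_draws(y0, 200)
    nrow(ic_skeleton(posterior_partial_correlations(arr0), 0.95)$graph$edges)
  }, 0L)
  expect_gte(sum(n_edges == 0L), 7L)
  expect_lte(mean(n_edges), 0.5)
})

test_that("orientation propagation rules R1 and R2 reach the closed graph", {
  ## a -> b - c, a and c non-adjacent: R1 forces b -> c
  g <- pdag(3, data.frame(from = c(1L, 2L), to = c(2L, 3L),
                          mark = c("directed", "undirected")))
  out <- propagate_orientations(g)
  expect_setequal(pdag_directed_edges(out), c("1->2", "2->3"))

  ## a -> b -> c with a - c undirected: R2 forces a -> c
  g2 <- pdag(3, data.frame(from = c(1L, 2L, 1L), to = c(2L, 3L, 3L),
                           mark = c("directed", "directed", "undirected")))
  out2 <- propagate_orientations(g2)
  expect_setequal(pdag_directed_edges(out2), c("1->2", "2->3", "1->3"))

  ## nothing to do on a fully undirected graph
  g3 <- pdag(3, data.frame(from = c(1L, 2L), to = c(2L, 3L),
                           mark = c("undirected", "undirected")))
  expect_equal(propagate_orientations(g3)$edges, g3$edges)

  ## empty graph unchanged by collider orientation
  ge <- pdag(4)
  expect_equal(orient_colliders(ge, list())$edges, ge$edges)
})

test_that("PDAG container enforces its invariants", {
  expect_error(pdag(3, data.frame(from = 1L, to = 1L, mark = "undirected")),
               "self-edges")
  expect_error(pdag(3, data.frame(from = c(1L, 2L), to = c(2L, 1L),
                                  mark = c("undirected", "directed"))),
               "one edge")
  expect_error(pdag(3, data.frame(from = c(1L, 2L, 3L), to = c(2L, 3L, 1L),
                                  mark = rep("directed", 3L))),
               "cycle")
})

test_that("IC decisions are invariant to posterior sample order and monotone in content", {
  set.seed(23)
  y <- simulate_reduced_form(chain_lambda(4, 0.7), 1500)
  arr <- covariance_posterior_draws(y, 200)
  nets <- ic_search(arr, contents = c(0.95, 0.90, 0.85, 0.80))

  perm <- sample(dim(arr)[3L])
  nets_p <- ic_search(arr[, , perm], contents = c(0.95, 0.90, 0.85, 0.80))
  for (nm in names(nets))
    expect_equal(pdag_adjacency(nets[[nm]]), pdag_adjacency(nets_p[[nm]]))

  ## lowering the content can only add edges
  edges_at <- lapply(nets, function(g) {
    apply(g$edges[, c("from", "to")], 1L, function(z)
      paste(sort(z), collapse = "-"))
  })
  for (q in seq_len(length(edges_at) - 1L))
    expect_true(all(edges_at[[q]] %in% edges_at[[q + 1L]]))

  expect_error(ic_search(arr, contents = c(0.8, 0.9)), "decreasing")
})
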