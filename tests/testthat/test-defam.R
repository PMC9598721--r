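# small helper: a FAM network of point categories at given 1-D positions
point_network <- function(positions, labels, alpha = 0.001) {
  W <- do.call(rbind, lapply(positions, function(v) complement_code(v)))
  fam_network(W, labels, alpha = alpha)
}

test_that("encode/decode is a prediction-preserving round trip with slot capacity", {
  ov <- overlap_clusters(n_per_class = 10, seed = 41)
  net <- fam_train(ov$x, ov$labels, fam_params(rho = 0.7))
  Na <- n_categories(net)
  enc <- fam_encode(net, catmax = Na + 5)
  expect_length(enc, (Na + 5) * (2 * 4 + 2))
  dec <- fam_decode(enc)
  expect_equal(n_categories(dec), Na)

  set.seed(42)
  probes <- matrix(runif(200), 50, 4)
  expect_identical(fam_predict(dec, probes), fam_predict(net, probes))

  # inactive slots are zeroed
  slot <- 2 * 4 + 2
  expect_equal(unname(enc[(Na * slot + 1):length(enc)]),
               rep(0, 5 * slot))
  expect_error(fam_encode(net, catmax = Na - 1), "capacity|categories")
})

test_that("decoding clips perturbed weights into [0, 1]", {
  net <- point_network(list(0.4, 0.8), c("a", "b"))
  enc <- fam_encode(net, catmax = 2)
  enc[1] <- 1.3   # first weight gene pushed out of range by DE arithmetic
  enc[2] <- -0.2
  dec <- fam_decode(enc)
  expect_equal(unname(dec$W[1, 1]), 1)
  expect_equal(unname(dec$W[1, 2]), 0)
})

test_that("classic mutation strategies reduce to their degenerate forms", {
  v0 <- c(0.2, 0.6)
  net <- point_network(list(v0[1]), "a")
  base <- fam_encode(net, catmax = 1)
  pop <- lapply(1:6, function(i) base)      # identical members
  fit <- c(3, 1, 2, 5, 4, 6)                # member 2 is best

  set.seed(1)
  expect_equal(as.numeric(de_mutate_classic(pop, 1, fit, "rand/1")),
               as.numeric(base))            # x_r2 = x_r3 cancels
  p0 <- de_params(F = 0)
  set.seed(2)
  expect_equal(as.numeric(de_mutate_classic(pop, 1, fit, "best/1", p0)),
               as.numeric(base))            # F = 0 leaves x_best
  set.seed(3)
  expect_equal(as.numeric(de_mutate_classic(pop, 1, fit, "rand/2")),
               as.numeric(base))
  expect_error(de_mutate_classic(pop[1:3], 1, fit[1:3], "rand/2"), "small")
})

test_that("rand-to-best/1 matches hand arithmetic on replayed donor draws", {
  mk <- function(v) structure(v, d = 1L, catmax = 1L, classes = "a",
                              alpha = 0.001, class = "fam_encoding")
  pop <- lapply(list(c(0, 0, 0, 0), c(1, 2, 0.5, 1), c(2, 0, 1, 1),
                     c(4, 4, 1, 1), c(0.5, 1, 1, 1)), mk)
  fit <- c(5, 1, 4, 3, 2)   # best = member 2
  prm <- de_params(F = 0.5)
  set.seed(77)
  v <- de_mutate_classic(pop, 1, fit, "rand-to-best/1", prm)
  set.seed(77)
  r <- sample(setdiff(1:5, 1), 2)  # replay the generator
  expected <- pop[[1]] + 0.5 * (pop[[2]] - pop[[1]]) +
    0.5 * (pop[[r[1]]] - pop[[r[2]]])
  expect_equal(as.numeric(v), as.numeric(expected))
})

test_that("neighborhood-to-best mutation draws donors from the top-ranked pool", {
  mk <- function(v) structure(v, d = 1L, catmax = 1L, classes = "a",
                              alpha = 0.001, class = "fam_encoding")
  # best member distinct; the three pool members identical
  pop <- lapply(list(c(10, 10), c(2, 2), c(2, 2), c(2, 2), c(50, 50), c(60, 60)), mk)
  fit <- c(1, 2, 3, 4, 9, 10)
  # F1 = F2 = 0: V = x_r3, one of the pool members
  prm0 <- de_params(F1 = 0, F2 = 0, neigh_frac = 0.5)
  set.seed(5)
  v0 <- de_mutate_neigh_to_best(pop, fit, prm0)
  expect_true(any(vapply(1:3, function(i) isTRUE(all.equal(as.numeric(v0), as.numeric(pop[[i]]))), TRUE)))

  # pool members 2..4 equal: difference term vanishes whenever r1, r2 there;
  # with F1 = 0.5 and x_r3 in the pool tail the mutant is the midpoint
  prm <- de_params(F1 = 0.5, F2 = 1, neigh_frac = 0.5)
  set.seed(6)
  v <- de_mutate_neigh_to_best(pop, fit, prm)
  set.seed(6)
  r <- sample(order(fit)[1:3], 3)
  expected <- pop[[r[3]]] + 0.5 * (pop[[1]] - pop[[r[3]]]) +
    1 * (pop[[r[1]]] - pop[[r[2]]])
  expect_equal(as.numeric(v), as.numeric(expected))

  expect_error(de_mutate_neigh_to_best(pop[1:2], fit[1:2], prm), "at least 3")
})

test_that("binomial crossover honors CR limits, jrand and both dialects", {
  x <- structure(rep(0, 6), d = 1L, catmax = 1L, classes = "a",
                 alpha = 0.001, class = "fam_encoding")
  v <- structure(rep(1, 6), d = 1L, catmax = 1L, classes = "a",
                 alpha = 0.001, class = "fam_encoding")
  set.seed(9)
  expect_equal(as.numeric(de_crossover(x, v, CR = 1)), rep(1, 6))
  set.seed(9)
  u0 <- de_crossover(x, v, CR = 0)
  expect_equal(sum(u0 == 1), 1)   # only jrand comes from the mutant
  # printed dialect inverts the inequality: CR = 1 keeps the target except jrand
  set.seed(9)
  up <- de_crossover(x, v, CR = 1, dialect = "printed")
  expect_equal(sum(up == 1), 1)

  # component pattern replays the generator draw for 0 < CR < 1
  set.seed(13)
  u <- de_crossover(x, v, CR = 0.7)
  set.seed(13)
  jrand <- sample.int(6, 1)
  rnd <- runif(6)
  take <- rnd <= 0.7; take[jrand] <- TRUE
  expect_equal(as.numeric(u), as.numeric(ifelse(take, 1, 0)))

  expect_error(de_crossover(x, v, CR = 1.2), "CR")
})

test_that("guarded fitness matches direct arithmetic and penalizes boundary cases", {
  prm <- de_params(catmin = 4, catmax = 20, fitness_form = "guarded")

  # Na = 4 categories, perfect accuracy: global optimum 0
  net4 <- point_network(list(0.1, 0.35, 0.65, 0.9), c("a", "b", "c", "d"))
  enc4 <- fam_encode(net4, catmax = 20, classes = c("a", "b", "c", "d"))
  xe <- matrix(c(0.1, 0.35, 0.65, 0.9), ncol = 1)
  f4 <- defam_fitness(enc4, xe, c("a", "b", "c", "d"), prm)
  expect_equal(f4$Na, 4)
  expect_equal(f4$pcc, 100)
  expect_equal(f4$value, 0)

  # Na = 5, pcc = 90: |400 - 450| / (15 * 8100)
  net5 <- point_network(list(0.05, 0.25, 0.45, 0.7, 0.95),
                        c("a", "b", "c", "d", "d"))
  enc5 <- fam_encode(net5, catmax = 20, classes = c("a", "b", "c", "d"))
  xq <- matrix(c(0.05, 0.05, 0.25, 0.25, 0.45, 0.45, 0.7, 0.7, 0.95, 0.95), ncol = 1)
  yq <- c("a", "a", "b", "b", "c", "c", "d", "d", "d", "a")  # one of ten wrong
  f5 <- defam_fitness(enc5, xq, yq, prm)
  expect_equal(f5$pcc, 90)
  expect_equal(f5$Na, 5)
  expect_equal(f5$value, 50 / 121500)

  # Na = catmax: the denominator would vanish; penalized, not an error
  prm2 <- de_params(catmin = 2, catmax = 4, fitness_form = "guarded")
  f_cap <- defam_fitness(fam_encode(net4, 4, c("a", "b", "c", "d")),
                         xe, c("a", "b", "c", "d"), prm2)
  expect_gte(f_cap$value, prm2$penalty)

  # zero accuracy in range: penalty, not a division error
  f0 <- defam_fitness(enc5, xq, rep("zzz", 10), prm)
  expect_equal(f0$pcc, 0)
  expect_gte(f0$value, prm$penalty)

  # the raw printed form diverges in sign near catmax, which is why it is
  # only exposed for inspection
  expect_lt(defam_fitness_raw(pcc = 99, Na = 19, catmin = 4, catmax = 20), 0)
})

test_that("the balanced numerator removes the spurious zero set of the bare guard", {
  # pcc * Na = 100 * catmin with pcc far below 100: bare guard scores ~0
  prm_g <- de_params(catmin = 3, catmax = 25, fitness_form = "guarded")
  prm_b <- de_params(catmin = 3, catmax = 25, fitness_form = "balanced")
  # network with 9 categories, and an eval set it gets 30/90 correct on
  pos <- as.list(seq(0.05, 0.95, length.out = 9))
  net9 <- point_network(pos, rep(c("a", "b", "c"), 3))
  enc9 <- fam_encode(net9, 25, classes = c("a", "b", "c"))
  xe <- matrix(rep(unlist(pos), each = 10), ncol = 1)
  true_lab <- fam_predict(net9, xe)
  # corrupt labels so exactly 30 of 90 are right
  yq <- true_lab
  yq[31:90] <- ifelse(true_lab[31:90] == "a", "b", "a")
  fg <- defam_fitness(enc9, xe, yq, prm_g)
  fb <- defam_fitness(enc9, xe, yq, prm_b)
  expect_equal(fg$pcc, 100 / 3)
  expect_lt(fg$value, 1e-12)          # the defect
  expect_gt(fb$value, 1e-4)           # the repair
})

test_that("selection keeps the smaller fitness and ties keep the target", {
  x <- structure(c(0, 0), class = "fam_encoding")
  u <- structure(c(1, 1), class = "fam_encoding")
  fa <- structure(list(pcc = 90, Na = 4, value = 0.2), class = "fitness_record")
  fb <- structure(list(pcc = 95, Na = 4, value = 0.1), class = "fitness_record")
  expect_true(de_select(x, u, fa, fb)$replaced)
  expect_false(de_select(x, u, fb, fa)$replaced)
  expect_false(de_select(x, u, fa, fa)$replaced)

  # batch: survivor always the argmin
  set.seed(31)
  for (k in 1:10) {
    va <- runif(1); vb <- runif(1)
    ra <- structure(list(pcc = 1, Na = 1, value = va), class = "fitness_record")
    rb <- structure(list(pcc = 1, Na = 1, value = vb), class = "fitness_record")
    s <- de_select(x, u, ra, rb)
    expect_equal(s$fitness$value, min(va, vb))
  }
})

test_that("evolution is elitist, reproducible and respects category bounds", {
  ov <- overlap_clusters(n_per_class = 20, sd = 0.2, seed = 51)
  nets <- fam_population(ov$x, ov$labels, n = 8,
                         params = fam_params(rho = 0.8, beta = 0.9, epochs = 1),
                         rho_range = c(0.55, 0.88), seed = 4)
  prm <- de_params(catmin = 3, catmax = 40, generations = 12, seed = 17)

  # generations = 0 returns the best initial member unchanged
  prm0 <- de_params(catmin = 3, catmax = 40, generations = 0, seed = 17)
  fit0 <- defam_evolve(nets, ov$x, ov$labels, prm0)
  init_vals <- vapply(seq_along(nets), function(i) {
    defam_fitness(fam_encode(nets[[i]], 40,
                             classes = sort(unique(ov$labels))),
                  ov$x, ov$labels, prm0)$value
  }, numeric(1))
  expect_equal(fit0$best_fitness$value, min(init_vals))

  fit <- defam_evolve(nets, ov$x, ov$labels, prm)
  expect_true(all(diff(fit$trace$best_value) <= 1e-12))
  expect_gte(fit$best_fitness$Na, prm$catmin)
  expect_lt(fit$best_fitness$Na, prm$catmax)

  fit2 <- defam_evolve(nets, ov$x, ov$labels, prm)
  expect_identical(fit2$trace, fit$trace)
  expect_identical(fit2$best_network, fit$best_network)

  # encoding soundness across the final population
  for (m in fit$population) {
    dec <- fam_decode(m)
    expect_true(all(dec$W >= 0 & dec$W <= 1))
    rt <- fam_decode(fam_encode(dec, prm$catmax, classes = attr(m, "classes")))
    expect_identical(fam_predict(rt, ov$x), fam_predict(dec, ov$x))
  }

  expect_error(defam_evolve(nets[1:4], ov$x, ov$labels, prm), "at least 6")
})

test_that("tidy, glance and autoplot expose the evolution trace", {
  ov <- overlap_clusters(n_per_class = 10, seed = 2)
  nets <- fam_population(ov$x, ov$labels, n = 6,
                         params = fam_params(rho = 0.7, epochs = 1),
                         rho_range = c(0.5, 0.8), seed = 1)
  fit <- defam_evolve(nets, ov$x, ov$labels,
                      de_params(catmin = 3, catmax = 30, generations = 3, seed = 2))
  expect_identical(generics::tidy(fit), fit$trace)
  gl <- generics::glance(fit)
  expect_equal(gl$best_na, fit$best_fitness$Na)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
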