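rse_table <- function() {
  data.frame(genotype = c("00", "10", "01", "11"),
             fitness = c(1.0, 1.2, 1.3, 0.8))
}

test_that("landscape construction validates and flags completeness", {
  ls <- build_landscape(rse_table())
  expect_true(ls$complete)
  expect_equal(ls$n_loci, 2)
  expect_equal(ls$fitness[["10"]], 1.2)

  partial <- build_landscape(rse_table()[1:3, ])
  expect_false(partial$complete)
  expect_equal(partial$missing, "11")

  dup_ok <- rbind(rse_table(), rse_table()[2, ])
  expect_equal(length(build_landscape(dup_ok)$fitness), 4)
  dup_bad <- rbind(rse_table(), data.frame(genotype = "10", fitness = 9))
  expect_error(build_landscape(dup_bad), "conflicting")

  expect_error(build_landscape(data.frame(genotype = c("10", "11"),
                                          fitness = c(1, 2))),
               "wild-type")
  expect_error(build_landscape(data.frame(genotype = c("00", "1"),
                                          fitness = c(1, 2))),
               "same length")

  # three loci: every genotype has exactly three Hamming-1 neighbors
  g3 <- expand.grid(rep(list(0:1), 3))
  tab3 <- data.frame(genotype = apply(g3, 1, paste, collapse = ""),
                     fitness = 1 + rowSums(g3) * 0.1)
  ls3 <- build_landscape(tab3)
  expect_true(ls3$complete)
  for (g in names(ls3$fitness)) {
    nb <- evoscape:::hamming_neighbors(g)
    expect_equal(length(nb), 3)
    expect_true(all(nb %in% names(ls3$fitness)))
  }
})

test_that("reciprocal sign epistasis creates two peaks with a valley", {
  ls <- build_landscape(rse_table())
  opt <- local_optima(ls)
  expect_setequal(opt$local, c("10", "01"))
  expect_equal(opt$global, "01")
  # the valley: no selectively accessible path wild type -> double mutant
  expect_equal(accessible_paths(ls, "00", "11")$count, 0)
  # but each single mutant is reached directly
  p <- accessible_paths(ls, "00", "01")
  expect_equal(p$count, 1)
  expect_equal(p$paths[[1]], c("00", "01"))
  # identity path
  expect_equal(accessible_paths(ls, "00", "00")$count, 1)
})

test_that("optima and paths agree with brute force on larger landscapes", {
  # monotone additive landscape: single optimum at all-ones, all geodesic
  # paths accessible
  g3 <- expand.grid(rep(list(0:1), 3))
  tab3 <- data.frame(genotype = apply(g3, 1, paste, collapse = ""),
                     fitness = 1 + rowSums(g3) * 0.1)
  ls3 <- build_landscape(tab3)
  opt <- local_optima(ls3)
  expect_equal(opt$local, "111")
  expect_equal(opt$global, "111")
  expect_equal(accessible_paths(ls3, "000", "111")$count, 6)  # 3! orderings

  # random landscapes against the permutation oracle
  for (seed in 1:5) {
    set.seed(seed)
    n_loci <- sample(2:4, 1)
    gg <- expand.grid(rep(list(0:1), n_loci))
    tab <- data.frame(genotype = apply(gg, 1, paste, collapse = ""),
                      fitness = round(runif(2^n_loci, 0.5, 1.5), 3))
    ls <- build_landscape(tab)
    start <- strrep("0", n_loci)
    end <- strrep("1", n_loci)
    expect_equal(accessible_paths(ls, start, end)$count,
                 oracle_paths(ls, start, end))
    # brute-force optimum check
    f <- ls$fitness
    oracle_opt <- names(f)[vapply(names(f), function(g) {
      all(f[g] > f[evoscape:::hamming_neighbors(g)])
    }, TRUE)]
    expect_setequal(local_optima(ls)$local, oracle_opt)
  }
})

test_that("exact fitness ties disqualify strict optima and are reported", {
  tab <- data.frame(genotype = c("00", "10", "01", "11"),
                    fitness = c(1, 1.2, 1.2, 1.2))
  opt <- local_optima(build_landscape(tab))
  expect_false("10" %in% opt$local)
  expect_gt(nrow(opt$ties), 0)
})

test_that("selection dynamics conserve frequency and increase mean fitness", {
  ls <- build_landscape(rse_table())
  # no mutation from a monomorphic wild type: absorbing
  tr0 <- selection_dynamics(ls, mu = 0, init = "00", n_generations = 20)
  expect_equal(unique(tr0[["00"]]), 1)

  # mu = 0 from a mixed start: frequencies always sum to 1, mean fitness
  # never decreases (Fisher-type property of the replicator step)
  init <- c("00" = 0.7, "10" = 0.1, "01" = 0.1, "11" = 0.1)
  tr <- selection_dynamics(ls, mu = 0, init = init, n_generations = 50)
  freqs <- as.matrix(tr[, -1])
  expect_equal(unname(rowSums(freqs)), rep(1, nrow(freqs)))
  wbar <- freqs %*% ls$fitness[colnames(freqs)]
  expect_true(all(diff(as.vector(wbar)) > -1e-12))

  # additive beneficial landscape with small mu: the all-ones genotype
  # sweeps to majority
  add <- build_landscape(gen_landscape_scenario("additive"))
  tra <- selection_dynamics(add, mu = 1e-5, init = "00",
                            n_generations = 400)
  expect_gt(tra[["11"]][nrow(tra)], 0.5)
})

test_that("RSE dynamics reproduce mutual exclusivity of the two mutations", {
  ls <- build_landscape(gen_landscape_scenario("reciprocal_sign"))
  mu <- 1e-5
  tr <- selection_dynamics(ls, mu = mu, init = "00", n_generations = 450)
  # the fitter single mutant takes over ...
  expect_gt(tr[["01"]][nrow(tr)], 0.5)
  # ... while the double mutant never escapes mutation-selection balance
  expect_lt(max(tr[["11"]]), 10 * mu)
})

test_that("dynamics and path enumeration reject invalid inputs", {
  ls <- build_landscape(rse_table())
  expect_error(selection_dynamics(ls, mu = 0.6, init = "00", 10), "mu")
  bad_init <- c("00" = 0.5, "10" = 0.2, "01" = 0.2, "11" = 0.2)
  expect_error(selection_dynamics(ls, 0, bad_init, 10), "sum to 1")
  expect_error(accessible_paths(ls, "00", "22"), "genotypes")
  partial <- build_landscape(rse_table()[1:3, ])
  expect_error(local_optima(partial), "complete")
})
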