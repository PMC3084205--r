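test_that("coverage ratio normalizes means and never divides by zero", {
  anc <- data.frame(chrom = "chr4", pos = 1:100, depth = rep(30, 100))
  # identical profiles: ratio 1 everywhere
  expect_equal(coverage_ratio(anc, anc)$ratio, rep(1, 100))
  # global scaling cancels
  clone3 <- transform(anc, depth = depth * 3)
  expect_equal(coverage_ratio(clone3, anc)$ratio, rep(1, 100))
  anc_half <- transform(anc, depth = depth / 2)
  expect_equal(coverage_ratio(clone3, anc_half)$ratio, rep(1, 100))
  # zero ancestral depth gives NA, not Inf
  anc0 <- anc
  anc0$depth[10] <- 0
  r <- coverage_ratio(clone3, anc0)
  expect_true(is.na(r$ratio[10]))
  expect_false(any(is.infinite(r$ratio), na.rm = TRUE))
  expect_error(coverage_ratio(clone3, anc[1:50, ]), "identical positions")

  # closed form on a noise-free amplified fixture: the plateau ratio is
  # amp_copies divided by the clone's mean-coverage inflation
  p <- gen_coverage_profiles(1000, 30, 101, 200, 10, noise = FALSE)
  rr <- coverage_ratio(p$clone, p$ancestor)
  infl <- mean(p$clone$depth) / mean(p$ancestor$depth)
  expect_equal(unique(rr$ratio[101:200]), 10 / infl)
  expect_equal(unique(rr$ratio[-(101:200)]), 1 / infl)
})

test_that("running median smooths, bounds, and leaves plateaus alone", {
  expect_equal(running_median(c(5, 1, 9, 3), 1), c(5, 1, 9, 3))
  expect_equal(running_median(rep(2, 10), 5), rep(2, 10))
  # an isolated spike of width 1 disappears under a window of 5
  x <- rep(1, 21)
  x[11] <- 50
  expect_equal(running_median(x, 5), rep(1, 21))
  # output bounded by the local window extremes
  set.seed(8)
  y <- rnorm(200)
  sm <- running_median(y, 7)
  for (i in seq_along(y)) {
    win <- y[max(1, i - 3):min(200, i + 3)]
    expect_gte(sm[i], min(win))
    expect_lte(sm[i], max(win))
  }
  # idempotent on a plateau signal
  plateau <- c(rep(1, 50), rep(10, 50), rep(1, 50))
  once <- running_median(plateau, 9)
  expect_equal(running_median(once, 9), once)
  expect_error(running_median(y, 4), "odd")
  expect_error(running_median(y, 301), "exceeds")
})

test_that("segment copy number recovers a plateau against its baseline", {
  ratio <- data.frame(pos = 1:300,
                      ratio = c(rep(1, 99), rep(9, 102), rep(1, 99)))
  est <- segment_copy_number(ratio, c(100, 201))
  expect_equal(est$estimate, 9)
  expect_equal(est$baseline, 1)
  expect_equal(est$n_inside, 102)
  whole <- segment_copy_number(data.frame(pos = 1:50, ratio = rep(1, 50)),
                               c(1, 50))
  expect_equal(whole$estimate, 1)
  expect_true(is.na(whole$baseline))
  expect_error(segment_copy_number(ratio, c(400, 500)), "no positions")
})

test_that("qPCR delta-delta-Ct recovers copy number with its CI", {
  # calibrator identity: ddCt = 0 in every replicate
  m0 <- qpcr_measurement(c(21, 21, 21), c(21, 21, 21), 24, 24,
                         calibrator_copies = 3)
  r0 <- qpcr_copy_number(m0)
  expect_equal(r0$estimate, 3)
  expect_equal(r0$se, 0)

  # ddCt = -3 exactly: 2^3 = 8 copies
  m8 <- qpcr_measurement(20, 23, 23, 23)
  r8 <- qpcr_copy_number(m8)
  expect_equal(r8$estimate, 8)
  expect_true(r8$single_replicate)
  expect_true(all(is.na(r8$ci95)))

  # replicates engineered to give copies 8.8, 9.0, 9.2
  ct_t <- 20 - log2(c(8.8, 9.0, 9.2))
  m9 <- qpcr_measurement(ct_t, c(20, 20, 20), 20, 20)
  r9 <- qpcr_copy_number(m9)
  expect_equal(r9$estimate, 9)
  expect_equal(r9$se, sd(c(8.8, 9.0, 9.2)) / sqrt(3))
  expect_equal(r9$ci95, 9 + c(-1.96, 1.96) * 0.2 / sqrt(3))

  # linearity: doubling the calibrator copies doubles the estimate
  m2x <- qpcr_measurement(ct_t, c(20, 20, 20), 20, 20,
                          calibrator_copies = 2)
  expect_equal(qpcr_copy_number(m2x)$estimate, 18)

  # efficiency knob
  expect_equal(qpcr_copy_number(m8, efficiency = 1.9)$estimate, 1.9^3)
})

test_that("minimum recombination events follow the doubling model", {
  expect_equal(min_recombination_events(9), 4)
  expect_equal(min_recombination_events(7), 3)
  expect_equal(min_recombination_events(1), 0)

  # BFS oracle over the at-most-doubling process, all n <= 64
  bfs_min_events <- function(n) {
    depth <- 0
    frontier <- 1
    while (max(frontier) < n) {
      frontier <- unique(unlist(lapply(frontier, function(c) c:(2 * c))))
      depth <- depth + 1
    }
    depth
  }
  for (n in 1:64) {
    e <- min_recombination_events(n)
    expect_equal(e, bfs_min_events(n))
    if (n >= 2) expect_true(2^e >= n && n > 2^(e - 1))
  }
  # monotone in copy number
  evals <- vapply(1:64, min_recombination_events, integer(1))
  expect_true(all(diff(evals) >= 0))

  # array-structure check: ORFs must be promoters + 1
  expect_warning(min_recombination_events(9, orf_copies = 11),
                 "array model violated")
  expect_silent(min_recombination_events(9, orf_copies = 10))
})

test_that("depth profiles round-trip through BedGraph in both conventions", {
  prof <- gen_coverage_profiles(200, 20, 50, 80, 5, seed = 6)$clone
  path <- tempfile(fileext = ".bg")
  write_bedgraph(prof, path)
  back <- read_bedgraph(path)
  expect_equal(back$pos, prof$pos)
  expect_equal(back$depth, prof$depth)
  # external representation is 0-based half-open: first interval starts at
  # 0 and interval lengths sum to the profile length
  bg <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "depth"))
  expect_equal(min(bg$start), 0)
  expect_equal(sum(bg$end - bg$start), 200)

  # full pipeline on a plateau fixture: 10-fold amplification recovered
  p <- gen_coverage_profiles(2e4, 30, 9001, 10000, 10, seed = 13)
  rat <- coverage_ratio(p$clone, p$ancestor)
  sm <- running_median(rat$ratio, 501)
  est <- segment_copy_number(data.frame(pos = rat$pos, ratio = sm),
                             c(9001, 10000))
  # the clone's mean coverage is inflated by the amplified 5% of the
  # profile, so the plateau reads ~10/1.45; compare against that closed
  # form rather than the nominal 10
  infl <- 1 + 0.05 * 9
  expect_equal(est$estimate, 10 / infl, tolerance = 0.05)
})

test_that("tables and parameter sidecars round-trip as text", {
  cfg <- sim_config(seed = 19)
  ser <- gen_competition_series(0.15, cfg)
  path <- tempfile(fileext = ".tsv")
  write_table_tsv(ser, path)
  back <- read_table_tsv(path)
  expect_equal(back$count_mutant, ser$count_mutant)
  expect_equal(back$generations, ser$generations, tolerance = 1e-9)

  jp <- tempfile(fileext = ".json")
  write_params_json(list(s_true = 0.15, seed = 19, kind = "competition"), jp)
  expect_equal(read_params_json(jp),
               list(s_true = 0.15, seed = 19, kind = "competition"))
})
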