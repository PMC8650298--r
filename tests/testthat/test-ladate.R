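test_that("tract tables validate contiguity and survive a file round-trip", {
  good <- data.frame(individual = "a", hap = 1L, chrom = "1",
                     start_cM = c(0, 10), end_cM = c(10, 50),
                     ancestry = c("A", "B"))
  tr <- tract_set(good)
  path <- tempfile(fileext = ".tsv")
  write_tracts(tr, path)
  back <- read_tracts(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  bad <- good; bad$start_cM[2] <- 12
  expect_error(tract_set(bad), "contiguous")
  bad2 <- good; bad2$end_cM[1] <- 0
  expect_error(tract_set(bad2), "empty or inverted")
})

test_that("coancestry values match exhaustive enumeration on toy tracts", {
  tr <- tract_set(data.frame(
    individual = rep(c("a", "b"), c(3, 2)),
    hap = 1L, chrom = "1",
    start_cM = c(0, 12, 30, 0, 25),
    end_cM = c(12, 30, 60, 25, 60),
    ancestry = c("A", "B", "A", "B", "A")))
  grid <- 0.5; d_min <- 1; d_max <- 10; bin <- 1
  cv <- coancestry_curve(tr, c("A", "B"), bin_cM = bin, d_min = d_min,
                         d_max = d_max, grid_cM = grid)
  # independent enumeration over all grid-point pairs
  lab_at <- function(ind, x) {
    rows <- tr[tr$individual == ind, ]
    rows$ancestry[findInterval(x, rows$start_cM)]
  }
  pts <- seq(0, 60 - 1e-9, by = grid)
  joint <- total <- setNames(numeric(10), 1:10)
  marg <- c(A = 0, B = 0)
  bin_edges <- seq(d_min, d_max, by = bin)
  for (ind in c("a", "b")) {
    labs <- lab_at(ind, pts)
    marg["A"] <- marg["A"] + sum(labs == "A")
    marg["B"] <- marg["B"] + sum(labs == "B")
    for (i in seq_along(pts)) for (j in seq_along(pts)) {
      d <- (j - i) * grid
      if (d < d_min || d > d_max) next
      bn <- findInterval(d, bin_edges, rightmost.closed = TRUE)
      total[bn] <- total[bn] + 1
      if (labs[i] == "A" && labs[j] == "B") joint[bn] <- joint[bn] + 1
    }
  }
  pa <- marg["A"] / (2 * length(pts)); pb <- marg["B"] / (2 * length(pts))
  manual <- unname((joint / total) / (pa * pb))
  expect_equal(cv$values, manual[seq_along(cv$values)], tolerance = 1e-12)
  expect_equal(cv$pair_counts, unname(total)[seq_along(cv$values)])
})

test_that("independently shuffled tract labels give a flat curve near one", {
  set.seed(3)
  n_seg <- 1500  # ~0.1 cM segments: no label correlation beyond d_min
  segs <- lapply(sprintf("i%02d", 1:30), function(id) {
    br <- sort(runif(n_seg - 1, 0, 150))
    data.frame(individual = id, hap = 1L, chrom = "1",
               start_cM = c(0, br), end_cM = c(br, 150),
               ancestry = sample(c("A", "B"), n_seg, TRUE, prob = c(0.6, 0.4)))
  })
  tr <- tract_set(do.call(rbind, segs))
  cv <- coancestry_curve(tr, c("A", "B"))
  expect_lt(max(abs(cv$values - 1)), 0.1)
  expect_identical(diagnose_curve_shape(cv), "flat")
})

test_that("error names an ancestry missing from the tracts", {
  tr <- tract_set(data.frame(individual = "a", hap = 1L, chrom = "1",
                             start_cM = 0, end_cM = 100, ancestry = "A"))
  expect_error(coancestry_curve(tr, c("A", "Z")), "Z")
})

test_that("exponential fit recovers noise-free parameters exactly", {
  d <- seq(0.75, 29.75, by = 0.5)
  u <- -log1p(-(1 - exp(-2 * d / 100)) / 2)
  cv <- structure(list(pair = c("A", "B"), bins_cM = d,
                       values = -0.5 * exp(-30 * u) + 1,
                       pair_counts = rep(1000, length(d))),
                  class = "coancestry_curve")
  fit <- fit_exponential(cv)
  expect_equal(fit$a, -0.5, tolerance = 1e-6)
  expect_equal(fit$lambda, 30, tolerance = 1e-4)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_identical(fit$flag, "ok")
  expect_equal(fit$generations, fit$lambda + 1)
  # the linear map coordinate recovers its own generating model too
  cv2 <- cv
  cv2$values <- -0.5 * exp(-30 * d / 100) + 1
  fit2 <- fit_exponential(cv2, map_function = "linear", meiosis_offset = 0)
  expect_equal(fit2$lambda, 30, tolerance = 1e-4)
  expect_equal(fit2$generations, 30, tolerance = 1e-4)
  # a flat curve yields an undefined date
  cv3 <- cv
  cv3$values <- rep(0.8, length(d))
  fit3 <- fit_exponential(cv3)
  expect_identical(fit3$flag, "flat")
  expect_true(is.na(fit3$generations))
})

test_that("date fitting recovers the pulse age from simulated tracts", {
  sch <- single_pulse_schedule(30, 0.3, 0.3, labels = c("SAN", "EAF"))
  src <- make_source_freqs(10, 2, 0.15, seed = 1, labels = c("SAN", "EAF"))
  map <- setNames(rep(180, 12), paste0("c", 1:12))
  co <- simulate_admixture(src, sch, 80, map, seed = 5, pool_size = 600)
  cv <- coancestry_curve(co$tracts, c("SAN", "EAF"))
  expect_identical(diagnose_curve_shape(cv), "classic-decay")
  fit <- fit_exponential(cv)
  expect_gt(fit$generations, 24)
  expect_lt(fit$generations, 36)
})

test_that("date estimates are invariant to chromosome relabeling", {
  sch <- single_pulse_schedule(20, 0.3, 0.3)
  src <- make_source_freqs(10, 2, 0.15, seed = 2, labels = c("BASE", "PULSE"))
  map <- setNames(rep(150, 8), paste0("c", 1:8))
  co <- simulate_admixture(src, sch, 60, map, seed = 6, pool_size = 400)
  f1 <- fit_exponential(coancestry_curve(co$tracts, c("BASE", "PULSE")))
  tr2 <- co$tracts
  tr2$chrom <- paste0("chr_", tr2$chrom)
  f2 <- fit_exponential(coancestry_curve(tract_set(tr2), c("BASE", "PULSE")))
  expect_equal(f1$lambda, f2$lambda)
  expect_equal(f1$a, f2$a)
})

test_that("bootstrap dating collapses at n_boot = 1 and covers the truth", {
  sch <- single_pulse_schedule(25, 0.3, 0.3)
  src <- make_source_freqs(10, 2, 0.15, seed = 3, labels = c("BASE", "PULSE"))
  map <- setNames(rep(180, 10), paste0("c", 1:10))
  co <- simulate_admixture(src, sch, 80, map, seed = 7, pool_size = 600)
  b1 <- bootstrap_dates(co$tracts, c("BASE", "PULSE"), n_boot = 1, seed = 1)
  expect_equal(b1$ci_lower, b1$ci_upper)
  expect_equal(b1$ci_lower, b1$boot_generations[1])
  b2 <- bootstrap_dates(co$tracts, c("BASE", "PULSE"), n_boot = 40, seed = 2)
  expect_lt(b2$ci_lower, 32)
  expect_gt(b2$ci_upper, 18)
})

test_that("generation-to-year conversion uses 30 years per generation", {
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(10), 300)
  expect_equal(generations_to_years(31.7), 951)
  expect_equal(generations_to_years(10, years_per_generation = 25), 250)
})

test_that("curve-shape diagnosis separates decay, hump and flat", {
  d <- seq(0.75, 29.75, 0.5)
  mk <- function(v) structure(list(pair = c("A", "B"), bins_cM = d,
                                   values = v,
                                   pair_counts = rep(100, length(d))),
                              class = "coancestry_curve")
  expect_identical(diagnose_curve_shape(mk(1 - 0.5 * exp(-0.3 * d))),
                   "classic-decay")
  hump <- exp(-0.08 * d) - exp(-0.4 * d)
  expect_identical(diagnose_curve_shape(mk(hump)), "non-monotone")
  expect_identical(diagnose_curve_shape(mk(rep(1, length(d)))), "flat")
})

test_that("window caller recovers local ancestry from phased haplotypes", {
  # unadmixed haplotype with well-separated panels: one clean tract
  M <- 300
  vt <- variant_table(sprintf("s%03d", 1:M), rep("1", M),
                      seq_len(M) * 1000L, seq(0.1, 100, length.out = M),
                      rep("A", M), rep("G", M))
  f <- rbind(SRC1 = rep(0.95, M), SRC2 = rep(0.05, M))
  set.seed(4)
  hap <- matrix(rbinom(M, 1, f["SRC1", ]), 1)
  idx <- data.frame(individual = "i1", hap = 1L)
  tr <- call_local_ancestry(hap, idx, vt, f, window_cM = 5,
                            smoothing_passes = 0)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$ancestry, "SRC1")
  expect_equal(tr$start_cM, 0)
  expect_equal(tr$end_cM, 100)
})

test_that("window calls are accurate on a simulated pulse and date like truth", {
  sch <- single_pulse_schedule(15, 0.35, 0.35)
  map <- setNames(rep(120, 8), paste0("c", 1:8))
  vt <- make_map_variants(map, round(map * 10), seed = 8)
  src <- make_source_freqs(nrow(vt), 2, 0.4, seed = 9,
                           labels = c("BASE", "PULSE"))
  co <- simulate_admixture(src, sch, 60, map, seed = 10, pool_size = 300)
  em <- emit_genotypes(co, src, vt, seed = 11, haplotypes = TRUE)
  f <- src$freqs; colnames(f) <- vt$snp_id
  rownames(f) <- src$labels
  called <- call_local_ancestry(em$haps, em$hap_index, vt, f,
                                window_cM = 1, smoothing_passes = 1,
                                chrom_lengths = map)
  # per-window accuracy against the truth tracts on a fine grid
  grid <- seq(0.5, 119.5, by = 1)
  lab_of <- function(tr, ind, hp, ch) {
    rows <- tr[tr$individual == ind & tr$hap == hp & tr$chrom == ch, ]
    rows$ancestry[findInterval(grid, rows$start_cM)]
  }
  hits <- tot <- 0
  for (r in sample(nrow(em$hap_index), 30)) {
    ind <- em$hap_index$individual[r]; hp <- em$hap_index$hap[r]
    for (ch in names(map)[1:3]) {
      truth <- lab_of(co$tracts, ind, hp, ch)
      est <- lab_of(called, ind, hp, ch)
      hits <- hits + sum(truth == est); tot <- tot + length(grid)
    }
  }
  acc <- hits / tot
  expect_gt(acc, 0.9)
  # dating from called tracts agrees with truth-tract dating within 20%
  f_true <- fit_exponential(coancestry_curve(co$tracts, c("BASE", "PULSE")))
  f_call <- fit_exponential(coancestry_curve(called, c("BASE", "PULSE")))
  expect_lt(abs(f_call$lambda - f_true$lambda) / f_true$lambda, 0.2)
})
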