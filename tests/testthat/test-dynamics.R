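# Interpreted outputs: B-factor agreement, domains and hinges, fast peaks,
# shape statistics, and the result bundle.

test_that("B-factor correlation is affine-invariant and matches the textbook formula", {
  x <- gnmkit:::with_seed(1, runif(20))
  expect_equal(bfactor_correlation(x, 2 * x + 5), 1, tolerance = 1e-12)
  expect_equal(bfactor_correlation(x, -x), -1, tolerance = 1e-12)
  expect_equal(bfactor_correlation(x, -3 * x + 1), -1, tolerance = 1e-12)
  y <- gnmkit:::with_seed(2, x + rnorm(20, sd = 0.3))
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(bfactor_correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(bfactor_correlation(x, rep(1, 20)), "zero-variance")
  # pairwise exclusion of missing experimental values
  y2 <- y; y2[c(3, 7)] <- NA
  expect_equal(bfactor_correlation(x, y2),
               cor(x[-c(3, 7)], y[-c(3, 7)]), tolerance = 1e-12)
})

test_that("synthetic B-factors from the model correlate perfectly without noise", {
  f <- fixture_path("helix", n = 40, b_model = list(noise_sd = 0), seed = 3)
  r <- run_gnm_on(f)
  expect_gt(bfactor_correlation(r$profile$msf, r$nodes$b), 1 - 1e-6)
})

test_that("domain separation on the 3-path gives signs (+, 0, -) and crossover {2}", {
  f <- fixture_path("linear_chain", n = 3)
  r <- run_gnm_on(f)
  d <- domain_separation(r$modes, 1, r$nodes)
  expect_equal(d$sign, c(1L, 0L, -1L))
  expect_equal(d$crossover, 2L)
})

test_that("single-signed modes give one domain and no crossover", {
  nodes <- run_gnm_on(fixture_path("helix", n = 12))$nodes
  m <- fake_modes(values = c(0, 1), n_zero = 1L,
                  vectors = cbind(rep(1 / sqrt(12), 12),
                                  (1:12) / sqrt(sum((1:12)^2))))
  d <- domain_separation(m, 1, nodes)
  expect_true(all(d$sign == 1L))
  expect_length(d$crossover, 0)
})

test_that("opposite-signed chains give two domains but no crossover nodes", {
  # compact enough that the softest mode is the inter-chain motion
  f <- fixture_path("dimer_biomt", n = 12)
  a <- build_assembly(read_structure(f), "first_assembly")
  nodes <- select_nodes(a)
  m <- gnm_modes(build_kirchhoff(nodes))
  d <- domain_separation(m, 1, nodes)
  ch <- nodes$label$chain
  s1 <- unique(d$sign[ch == "A" & d$sign != 0])
  s2 <- unique(d$sign[ch != "A" & d$sign != 0])
  expect_length(s1, 1); expect_length(s2, 1)
  expect_equal(s1 * s2, -1L)
  # each chain is single-signed, so no within-chain crossovers exist; the
  # sign flip between the last A node and the first B node is not one
  # either (chains are not sequence-adjacent)
  expect_equal(d$crossover, which(d$sign == 0L))
})

test_that("slow-mode minima find the vertex of a V-shaped profile and reject plateaus", {
  nodes <- run_gnm_on(fixture_path("linear_chain", n = 11))$nodes
  v_prof <- abs(seq(-5, 5))
  p <- structure(list(msf = v_prof, shapes = rbind(v_prof), n = 11),
                 class = "gnm_profile")
  expect_equal(slow_mode_minima(p, nodes, 1), 6L)
  flat <- structure(list(msf = rep(1, 11), shapes = rbind(rep(1, 11)),
                         n = 11), class = "gnm_profile")
  expect_length(slow_mode_minima(flat, nodes, 1), 0)
})

test_that("slow-mode minima agree with an exhaustive windowed scan", {
  for (seed in 1:5) {
    prof <- gnmkit:::with_seed(seed, runif(30))
    nodes <- run_gnm_on(fixture_path("helix", n = 30))$nodes
    p <- structure(list(msf = prof, shapes = rbind(prof), n = 30),
                   class = "gnm_profile")
    got <- slow_mode_minima(p, nodes, 1, window = 5)
    # oracle: exhaustive scan, strict minimum over both-sided neighbors
    expected <- integer(0)
    for (i in 1:30) {
      nb <- setdiff(max(1, i - 2):min(30, i + 2), i)
      if (any(nb < i) && any(nb > i) && all(prof[i] < prof[nb]))
        expected <- c(expected, i)
    }
    expect_setequal(got, expected)
    expect_equal(got, expected[order(prof[expected])])
  }
})

test_that("dumbbell fixtures recover the planted hinge and domains", {
  for (seed in 1:6) {
    fx_file <- tempfile(fileext = ".pdb")
    fx <- gnm_fixture("dumbbell", n = 25, path = fx_file, noise = 0.2,
                      seed = seed)
    seg <- fx$info$segments
    r <- run_gnm_on(fx_file)
    d <- domain_separation(r$modes, 1, r$nodes)
    expect_length(unique(d$sign[seg$cluster1]), 1)
    expect_length(unique(d$sign[seg$cluster2]), 1)
    expect_equal(d$sign[seg$cluster1][1] * d$sign[seg$cluster2][1], -1L)
    mins <- slow_mode_minima(r$profile, r$nodes, 1)
    expect_gt(length(mins), 0)
    expect_true(all(mins %in% seg$linker))
  }
})

test_that("fast-mode peaks recover a planted localized spike", {
  nodes <- run_gnm_on(fixture_path("helix", n = 20))$nodes
  shapes <- matrix(0.01, nrow = 5, ncol = 20)
  shapes[5, 13] <- 5   # planted spike in the stiffest mode
  p <- structure(list(msf = colSums(shapes), shapes = shapes, n = 20),
                 class = "gnm_profile")
  peaks <- fast_mode_peaks(p, n_fast = 2, top_q = 0.95)
  expect_equal(peaks[1], 13L)
  # top_q = 0 returns all nodes in descending order
  all_nodes <- fast_mode_peaks(p, n_fast = 2, top_q = 0)
  expect_length(all_nodes, 20)
  expect_equal(all_nodes[1], 13L)
})

test_that("fast modes are less collective than slow modes on a compact structure", {
  r <- run_gnm_on(fixture_path("dumbbell", n = 31, noise = 0.1, seed = 2))
  kap <- collectivity(r$modes)
  nz <- length(kap)
  expect_gt(mean(kap[1:3]), mean(kap[(nz - 9):nz]))
})

test_that("axial ratio is 1 for a cube, recovers planted ellipsoids, flags collinear", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  sh <- axial_ratio(cube)
  expect_equal(sh$axial_ratio, 1, tolerance = 1e-10)
  f <- fixture_path("ellipsoid_cloud", n = 800, axis_ratio = 10, seed = 5)
  sh2 <- axial_ratio(select_nodes(read_structure(f)))
  expect_equal(sh2$axial_ratio, 10, tolerance = 0.05 * 10)
  line <- cbind(1:10, 0, 0)
  sh3 <- axial_ratio(line)
  expect_true(sh3$degenerate)
  expect_equal(sh3$axial_ratio, Inf)
})

test_that("dimer-derived B-factors prefer the dimer model over the monomer", {
  for (seed in 1:5) {
    f <- tempfile(fileext = ".pdb")
    gnm_fixture("dimer_biomt", n = 30, path = f, noise = 0.25, seed = seed,
                b_model = list(model = "assembly"))
    s <- read_structure(f)
    b <- select_nodes(s)$b
    mono <- gnm_profile(gnm_modes(build_kirchhoff(select_nodes(s))))
    dim_nodes <- select_nodes(build_assembly(s, "first_assembly"))
    dimer <- gnm_profile(gnm_modes(build_kirchhoff(dim_nodes)))
    r_mono <- bfactor_correlation(mono$msf, b)
    r_dimer <- bfactor_correlation(dimer$msf[1:30], b)
    expect_gt(r_dimer, r_mono)
  }
})

test_that("the result bundle contains the documented files and is deterministic", {
  f <- fixture_path("helix", n = 26, b_model = list(noise_sd = 2), seed = 6)
  r <- run_gnm_on(f)
  s <- read_structure(f)
  d1 <- file.path(tempfile(), "bundle1"); d2 <- file.path(tempfile(), "bundle2")
  dir.create(dirname(d1), recursive = TRUE); dir.create(dirname(d2), recursive = TRUE)
  sm <- write_report(d1, s, r$nodes, r$k, r$modes, r$profile)
  write_report(d2, s, r$nodes, r$k, r$modes, r$profile)

  expect_equal(sm$n_soft_stored, ceiling(0.4 * 25))
  base <- c("eigenvalues.tsv", "modes_soft.tsv", "modes_fast.tsv",
            "msf.tsv", "bfactor_compare.tsv", "crosscorr.tsv",
            "collectivity.tsv", "summary.json", "domains_mode1.tsv",
            "colored_mode1.pdb")
  expect_true(all(file.exists(file.path(d1, base))))
  # byte-identical across runs
  for (fn in list.files(d1)) {
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
  }
  # the header r matches a recomputation
  hdr <- readLines(file.path(d1, "bfactor_compare.tsv"), n = 1)
  r_hdr <- as.numeric(sub(".*pearson_r = ([-0-9.e]+).*", "\\1", hdr))
  expect_equal(r_hdr, bfactor_correlation(r$profile$msf, r$nodes$b),
               tolerance = 1e-8)
  # refusing to overwrite an existing bundle
  expect_error(write_report(d1, s, r$nodes, r$k, r$modes, r$profile),
               "exists")
})
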