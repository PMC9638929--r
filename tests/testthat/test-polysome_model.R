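# Count table -> translation states -> peak masses -> completed profile.

test_that("symmetric two-gene table splits copies and ribosomes evenly", {
  counts <- data.frame(gene_id = c("a", "b"), length_nt = c(1000, 1000),
                       fp_count = c(1, 1), rna_count = c(1, 1))
  p <- cell_params("yeast", total_mrna = 100, total_ribosomes = 200,
                   active_fraction = 1)
  st <- compute_states(counts, p)
  expect_equal(st$rna_copies, c(50, 50))
  expect_equal(st$ribosomes_bound, c(100, 100))
  expect_equal(st$density, c(2, 2))
})

test_that("a single gene absorbs the whole cellular budget", {
  counts <- data.frame(gene_id = "only", length_nt = 1500,
                       fp_count = 10, rna_count = 7)
  p <- cell_params("yeast")
  st <- compute_states(counts, p)
  expect_equal(st$rna_copies, p$total_mrna)
  expect_equal(st$ribosomes_bound, p$total_ribosomes * p$active_fraction)
})

test_that("RPK length-normalisation drives copy numbers", {
  # same counts, double length -> half the RPK -> half the copies
  counts <- data.frame(gene_id = c("short", "long"),
                       length_nt = c(1000, 2000),
                       fp_count = c(1, 1), rna_count = c(10, 10))
  st <- compute_states(counts, cell_params("yeast", total_mrna = 300))
  expect_equal(st$rna_copies, c(200, 100))
})

test_that("densities are recovered from deep synthetic counts", {
  spec <- fixture_spec(seed = 31, n_genes = 50, depth_fp = 4e7,
                       depth_rna = 4e7)
  fx <- make_count_table(spec)
  st <- compute_states(fx$counts, fixture_params(fx$truth))
  m <- match(st$gene_id, fx$truth$gene_id)
  rel <- abs(st$density - fx$truth$density[m]) / fx$truth$density[m]
  expect_lt(max(rel), 0.02)
})

test_that("genes without RNA evidence are excluded and reported", {
  counts <- data.frame(gene_id = c("a", "b", "c"),
                       length_nt = c(1000, 1000, 1000),
                       fp_count = c(5, 5, 10), rna_count = c(10, 10, 0))
  st <- compute_states(counts, cell_params("yeast"))
  expect_equal(nrow(st), 2)
  expect_equal(attr(st, "excluded_genes"), "c")
  expect_equal(attr(st, "excluded_fp_fraction"), 0.5)
  allz <- data.frame(gene_id = "a", length_nt = 1000,
                     fp_count = 0, rna_count = 3)
  expect_error(compute_states(allz, cell_params("yeast")),
               class = "polyprof_degenerate")
})

test_that("the straddling-integer rule splits the worked example 20/80", {
  st <- data.frame(gene_id = "ex", rna_copies = 10, density = 5.8,
                   ribosomes_bound = 58)
  m <- assign_to_peaks(st)
  expect_equal(unname(m["5"]), 11.6, tolerance = 1e-12)
  expect_equal(unname(m["6"]), 46.4, tolerance = 1e-12)
  expect_equal(sum(m), 58)
})

test_that("integer densities put all mass on one peak", {
  st <- data.frame(gene_id = "i", rna_copies = 10, density = 3,
                   ribosomes_bound = 30)
  m <- assign_to_peaks(st)
  expect_equal(unname(m["3"]), 30)
  expect_equal(sum(m != 0), 1)
})

test_that("sub-monosomal densities park mass on peak 0", {
  st <- data.frame(gene_id = "s", rna_copies = 100, density = 0.25,
                   ribosomes_bound = 25)
  m <- assign_to_peaks(st)
  expect_equal(unname(m["0"]), 25 * 0.75)
  expect_equal(unname(m["1"]), 25 * 0.25)
})

test_that("mass above n_max is pooled into the terminal peak", {
  st <- data.frame(gene_id = c("h", "l"), rna_copies = c(1, 1),
                   density = c(25.5, 2), ribosomes_bound = c(10, 4))
  m <- assign_to_peaks(st, n_max = 20)
  expect_equal(unname(m["20"]), 10)
  expect_equal(attr(m, "pooled_mass"), 10)
  expect_equal(unname(m["2"]), 4)
})

test_that("ribosomes are conserved across random gene sets", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 100
    st <- data.frame(gene_id = sprintf("g%d", 1:n),
                     rna_copies = runif(n, 1, 50),
                     density = runif(n, 0.05, 25),
                     ribosomes_bound = runif(n, 0, 500))
    m <- assign_to_peaks(st)
    expect_lt(abs(sum(m) - sum(st$ribosomes_bound)) /
                sum(st$ribosomes_bound), 1e-9)
  }
})

test_that("shifting a density by one moves its mass one peak up", {
  st <- data.frame(gene_id = "g", rna_copies = 5, density = 4.3,
                   ribosomes_bound = 21.5)
  m1 <- assign_to_peaks(st)
  st$density <- st$density + 1
  m2 <- assign_to_peaks(st)
  expect_equal(unname(m2[as.character(2:20)]),
               unname(m1[as.character(1:19)]))
})

test_that("inactive ribosomes complete the subunit and monosome peaks", {
  masses <- setNames(numeric(21), as.character(0:20))
  v <- add_inactive(masses, cell_params("yeast"))
  expect_equal(unname(v["40S"]), 0.105, tolerance = 1e-12)
  expect_equal(unname(v["60S"]), 0.195, tolerance = 1e-12)
  expect_equal(unname(v["1"]), 0.700, tolerance = 1e-12)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("include_idle = FALSE normalises the n-some masses alone", {
  st <- data.frame(gene_id = c("a", "b"), rna_copies = c(1, 1),
                   density = c(2, 4), ribosomes_bound = c(30, 10))
  m <- assign_to_peaks(st)
  v <- add_inactive(m, cell_params("yeast"), include_idle = FALSE)
  expect_equal(unname(v["40S"]), 0)
  expect_equal(unname(v["60S"]), 0)
  expect_equal(unname(v["2"]), 0.75)
  expect_equal(unname(v["4"]), 0.25)
})

test_that("idle completion matches a brute-force re-derivation", {
  spec <- fixture_spec(seed = 13, n_genes = 100)
  fx <- make_count_table(spec)
  p <- fixture_params(fx$truth)
  st <- compute_states(fx$counts, p)
  m <- assign_to_peaks(st)
  v <- add_inactive(m, p)
  # oracle: rebuild the completed masses from first principles
  inactive <- p$total_ribosomes * (1 - p$active_fraction)
  oracle <- c("40S" = inactive * p$split_fraction * p$small_subunit_fraction,
              "60S" = inactive * p$split_fraction *
                (1 - p$small_subunit_fraction),
              m[names(m) != "0"])
  oracle["1"] <- oracle["1"] + inactive * (1 - p$split_fraction)
  oracle <- oracle / sum(oracle)
  expect_equal(v, oracle, tolerance = 1e-12)
  # subunit + idle-80S share of the completed profile equals the
  # inactive fraction of all profile-visible ribosomes
  visible <- sum(m[names(m) != "0"]) + inactive
  expect_equal(unname(v["40S"] + v["60S"]) +
                 inactive * (1 - p$split_fraction) / visible,
               inactive / visible, tolerance = 1e-12)
})

test_that("doubling all counts changes nothing downstream", {
  spec <- fixture_spec(seed = 17, n_genes = 80)
  fx <- make_count_table(spec)
  p <- fixture_params(fx$truth)
  v1 <- model_polysome(fx$counts, p)
  doubled <- fx$counts
  doubled$fp_count <- doubled$fp_count * 2
  doubled$rna_count <- doubled$rna_count * 2
  v2 <- model_polysome(doubled, p)
  expect_equal(unclass(v1), unclass(v2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rendered modelled profiles integrate to their total volume", {
  loc <- fit_location_model(30 + 20 * log(1:6), 1:6)
  v1 <- c("1" = 1)
  tr <- render_modelled_profile(v1, loc)
  area <- sum(diff(tr$position) *
                (tr$absorbance[-1] + tr$absorbance[-nrow(tr)]) / 2)
  expect_lt(abs(area - 1), 1e-3)
  # two equal peaks render with equal maxima when well separated
  v2 <- c("1" = 0.5, "6" = 0.5)
  tr2 <- render_modelled_profile(v2, loc, width_factor = 0.1)
  y <- tr2$absorbance
  ix <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(ix, 2)
  expect_lt(abs(y[ix[1]] - y[ix[2]]) / y[ix[1]], 1e-3)
})

test_that("rendered profiles re-fit to the volumes that generated them", {
  spec <- fixture_spec(seed = 23, n_genes = 200)
  fx <- make_count_table(spec)
  vol <- model_polysome(fx$counts, fixture_params(fx$truth))
  loc <- fit_location_model(30 + 20 * log(1:8), 1:8)
  tr <- render_modelled_profile(vol, loc, n_grid = 1500)
  gen <- attr(tr, "model")
  fit <- fit_profile(tr, setNames(gen$peaks$mu, gen$peaks$label))
  got <- peak_volumes(fit)
  expect_lt(max(abs(got[names(vol[vol > 0])] - vol[vol > 0])), 1e-3)
})

test_that("the full model pipeline reproduces a prescribed volume vector", {
  presc <- setNames(c(0.18, 0.25, 0.2, 0.15, 0.1, 0.07, 0.05),
                    as.character(1:7))
  spec <- fixture_spec(seed = 41, n_genes = 200, depth_fp = 1e6,
                       depth_rna = 1e6)
  fx <- make_count_table(spec, volumes = presc)
  vol <- model_polysome(fx$counts, fixture_params(fx$truth),
                        include_idle = FALSE)
  got <- vol[names(presc)]
  expect_lt(max(abs(got - presc)), 0.01)
})
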