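test_that("arcsinh transform matches its closed form and is monotone", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(1), log(1 + sqrt(2)))
  x <- withr::with_seed(1, runif(50, 0, 1e6))
  expect_equal(arcsinh_transform(x), log(x + sqrt(x^2 + 1)))
  pairs <- withr::with_seed(2, matrix(runif(200, 0, 100), ncol = 2))
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2]) + 1e-9
  expect_true(all(arcsinh_transform(lo) < arcsinh_transform(hi)))
  expect_error(arcsinh_transform(-1), ">= 0")
  expect_error(arcsinh_transform(NaN), "finite")
})

test_that("anova_p handles degenerate layouts by convention", {
  expect_equal(anova_p(rep(c(1, 2, 3), 3), gl(3, 3)), 1)
  expect_equal(anova_p(rep(5, 9), gl(3, 3)), 1)
  expect_equal(anova_p(rep(c(1, 2, 3), each = 3), gl(3, 3)), 0)
})

test_that("anova_p matches the sum-of-squares oracle and oneway.test", {
  g <- gl(3, 4)
  v <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6)
  expect_equal(anova_p(v, g), oracle_anova_p(v, g), tolerance = 1e-10)

  withr::with_seed(99, {
    for (i in 1:300) {
      sizes <- sample(2:5, 3, replace = TRUE)
      grp <- factor(rep(1:3, sizes))
      vals <- rnorm(sum(sizes), mean = rep(runif(3, 0, 3), sizes))
      p_pkg <- anova_p(vals, grp)
      expect_equal(p_pkg, oracle_anova_p(vals, grp), tolerance = 1e-10)
      expect_equal(
        p_pkg,
        oneway.test(vals ~ grp, var.equal = TRUE)$p.value,
        tolerance = 1e-10
      )
    }
  })
})

test_that("anova_power is alpha under the null and increases with effect", {
  g <- gl(3, 3)
  expect_equal(anova_power(rep(c(1, 2, 3), 3), g, alpha = 0.05), 0.05)
  base <- c(0, 0, 0)
  noise <- withr::with_seed(5, rnorm(9, sd = 1))
  powers <- sapply(c(0.5, 1, 2, 4), function(eff) {
    anova_power(rep(c(0, eff, 2 * eff), each = 3) + noise, g)
  })
  expect_true(all(diff(powers) > 0))
  # zero within-variance conventions
  expect_equal(anova_power(rep(c(1, 2, 3), each = 3), g), 1)
  expect_equal(anova_power(rep(2, 9), g, alpha = 0.1), 0.1)
})

test_that("max_fold_change matches brute-force pairwise ratios", {
  expect_equal(max_fold_change(c(100, 110, 125)), 1.25)
  expect_equal(max_fold_change(c(7, 7, 7)), 1)
  withr::with_seed(3, {
    for (i in 1:50) {
      m <- runif(3, 1, 100)
      brute <- max(outer(m, m, "/"))
      expect_equal(max_fold_change(m), brute)
    }
  })
  expect_error(max_fold_change(c(1, -2, 3)), "positive")
})

random_stats_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    protein_id = sprintf("P%03d", 1:n),
    compartment = factor("synaptic",
                         levels = c("synaptic", "non_synaptic")),
    anova_p = sample(c(runif(n - 2), 0.05, 0.051), n),
    power = sample(c(runif(n - 2), 0.8, 0.79), n),
    max_fold_change = 1 + sample(c(rexp(n - 2), 0.2, 0.19), n),
    unique_peptides = sample(1:5, n, replace = TRUE)
  ))
}

test_that("filter_features matches a brute-force triple-condition scan", {
  cfg <- pipeline_config()
  stats <- random_stats_table(100, seed = 10)
  got <- filter_features(stats, cfg)
  keep <- logical(nrow(stats))
  for (i in seq_len(nrow(stats))) {
    keep[i] <- stats$power[i] >= 0.8 && stats$max_fold_change[i] >= 1.2 &&
      stats$anova_p[i] <= 0.05
  }
  expect_identical(got$protein_id, stats$protein_id[keep])
  # boundaries are inclusive on the keep side
  boundary <- tibble::tibble(
    protein_id = "B", compartment = factor("synaptic"),
    anova_p = 0.05, power = 0.8, max_fold_change = 1.2,
    unique_peptides = 2L
  )
  expect_equal(nrow(filter_features(boundary, cfg)), 1)
  expect_equal(nrow(filter_features(
    dplyr::mutate(boundary, power = 0.79), cfg)), 0)
  # idempotent
  expect_identical(filter_features(got, cfg), got)
})

test_that("filter_proteins matches a brute-force scan with boundaries", {
  cfg <- pipeline_config()
  stats <- random_stats_table(100, seed = 11)
  got <- filter_proteins(stats, cfg)
  keep <- stats$unique_peptides >= 2 & stats$anova_p <= 0.05
  expect_identical(got$protein_id, stats$protein_id[keep])
  one_pep <- tibble::tibble(
    protein_id = "X", compartment = factor("synaptic"),
    anova_p = 0.001, power = 1, max_fold_change = 3, unique_peptides = 1L
  )
  expect_equal(nrow(filter_proteins(one_pep, cfg)), 0)
  expect_equal(nrow(filter_proteins(
    dplyr::mutate(one_pep, unique_peptides = 2L, anova_p = 0.05), cfg)), 1)
  expect_identical(filter_proteins(got, cfg), got)
})

test_that("feature_stats agrees with per-protein scalar computation", {
  ab <- abundance_from_means(
    function(p, cmp, a) {
      100 * p * ifelse(a == "old" & p %% 2 == 0, 1.8, 1)
    },
    n_proteins = 6, reps = 3, noise_sd = 0.1, seed = 31
  )
  st <- feature_stats(ab)
  syn <- ab[ab$compartment == "synaptic", ]
  for (id in unique(syn$protein_id)) {
    v <- asinh(syn$abundance[syn$protein_id == id])
    g <- syn$age[syn$protein_id == id]
    row <- st[st$protein_id == id & st$compartment == "synaptic", ]
    expect_equal(row$anova_p, anova_p(v, g), tolerance = 1e-12)
    expect_equal(row$power, anova_power(v, g), tolerance = 1e-12)
    means <- tapply(syn$abundance[syn$protein_id == id], droplevels(g), mean)
    expect_equal(row$max_fold_change, max(means) / min(means))
  }
})

test_that("common_proteins behaves as set intersection in first order", {
  expect_equal(common_proteins(c("a", "b", "c"), c("a", "b", "c")),
               c("a", "b", "c"))
  expect_equal(common_proteins(c("a", "b"), c("x", "y")), character(0))
  x <- c("d", "b", "a", "c")
  y <- c("c", "q", "b")
  expect_equal(common_proteins(x, y), x[x %in% y])
})

test_that("count_altered counts proteins beyond the 20% ratio", {
  ab <- abundance_from_matrix(
    rbind(c(100, 100, 121), c(100, 100, 119), c(100, 100, 100)),
    compartment = rep("synaptic", 3),
    age = c("young", "mid", "old"), replicate = c(1, 1, 1)
  )
  expect_equal(count_altered(ab)$n_altered, 1)
})

test_that("zero-noise generator yields the planted altered count", {
  cfg <- sim_config(
    n_proteins = 100, noise_sd = 0, effect_size = 1.5,
    class_fractions = c(flat = 0.7, steady_up = 0.3, steady_down = 0,
                        late_up = 0, late_down = 0, divergent_old = 0),
    seed = 8
  )
  sim <- simulate_proteome(cfg)
  out <- count_altered(sim$abundance)
  expect_equal(out$n_altered, c(30, 30))
})

test_that("zero-noise filters retain exactly the non-flat classes", {
  cfg <- sim_config(n_proteins = 120, noise_sd = 0,
                    frac_single_peptide = 0, seed = 17)
  sim <- simulate_proteome(cfg)
  st <- feature_stats(sim$abundance)
  syn <- filter_features(st[st$compartment == "synaptic", ])
  non_flat <- sim$truth$protein_id[sim$truth$class != "flat"]
  expect_setequal(syn$protein_id, non_flat)
})
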