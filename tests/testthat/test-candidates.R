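oracle_trend <- function(young, mid, old, eps = 0.2) {
  r1 <- mid / young
  r2 <- old / mid
  hi <- 1 + eps
  lo <- 1 / hi
  if (r1 >= hi && r2 >= hi) return("steady_up")
  if (r1 <= lo && r2 <= lo) return("steady_down")
  if (r1 > lo && r1 < hi && r2 >= hi) return("late_up")
  if (r1 > lo && r1 < hi && r2 <= lo) return("late_down")
  "other"
}

test_that("classify_trend matches the rule table", {
  expect_equal(classify_trend(100, 130, 169), "steady_up")
  expect_equal(classify_trend(100, 105, 140), "late_up")
  expect_equal(classify_trend(100, 100, 100), "other")
  expect_equal(classify_trend(100, 80, 60), "steady_down")
  expect_equal(classify_trend(100, 101, 80), "late_down")
  expect_error(classify_trend(0, 1, 1), "positive")
  expect_error(classify_trend(1, 1, 1, epsilon = 0), "> 0")

  withr::with_seed(70, {
    young <- runif(10000, 10, 200)
    mid <- young * exp(rnorm(10000, 0, 0.4))
    old <- mid * exp(rnorm(10000, 0, 0.4))
    got <- classify_trend(young, mid, old)
    want <- mapply(oracle_trend, young, mid, old)
    expect_equal(got, unname(want))
  })
})

test_that("trend_candidates unions exactly the matching clusters' members", {
  membership <- tibble::tibble(
    node = sprintf("P%02d", 1:9),
    cluster = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L)
  )
  cl <- structure(list(membership = membership, n_clusters = 4L),
                  class = "mcl_clusters")
  trends <- tibble::tibble(
    cluster = 1:4,
    trend = c("steady_up", "other", "late_down", "steady_up"),
    n_members = c(3L, 2L, 3L, 1L)
  )
  got <- trend_candidates(cl, trends)
  want <- rbind(
    data.frame(trend = "steady_up", protein_id = sprintf("P%02d", 1:3)),
    data.frame(trend = "late_down", protein_id = sprintf("P%02d", 6:8)),
    data.frame(trend = "steady_up", protein_id = "P09")
  )
  expect_setequal(paste(got$trend, got$protein_id),
                  paste(want$trend, want$protein_id))
  none <- trend_candidates(cl, trends, classes = "late_up")
  expect_equal(nrow(none), 0)
  only <- trend_candidates(cl, trends, classes = "late_down")
  expect_setequal(only$protein_id, sprintf("P%02d", 6:8))
})

test_that("subtract_common removes per-class intersections only", {
  syn <- tibble::tibble(
    trend = c("steady_up", "steady_up", "late_up"),
    protein_id = c("A", "B", "C")
  )
  same <- subtract_common(syn, syn)
  expect_equal(nrow(same), 0)

  nonsyn <- tibble::tibble(
    trend = c("steady_up", "late_up"),
    protein_id = c("D", "E")
  )
  disjoint <- subtract_common(syn, nonsyn)
  expect_setequal(disjoint$protein_id, c("A", "B", "C", "D", "E"))

  # same protein, different class in each compartment -> kept
  cross <- subtract_common(
    tibble::tibble(trend = "steady_up", protein_id = "X"),
    tibble::tibble(trend = "late_up", protein_id = "X")
  )
  expect_equal(sort(cross$trend), c("late_up", "steady_up"))

  withr::with_seed(80, {
    for (i in 1:20) {
      classes <- c("steady_up", "steady_down", "late_up", "late_down")
      mk <- function() tibble::tibble(
        trend = sample(classes, 15, replace = TRUE),
        protein_id = sample(LETTERS[1:10], 15, replace = TRUE)
      ) |> dplyr::distinct()
      s <- mk()
      n <- mk()
      got <- subtract_common(s, n)
      want <- character(0)
      for (cl in classes) {
        a <- s$protein_id[s$trend == cl]
        b <- n$protein_id[n$trend == cl]
        want <- c(want, paste(cl, setdiff(union(a, b), intersect(a, b))))
      }
      expect_setequal(paste(got$trend, got$protein_id), want)
    }
  })
})

test_that("ratio_to_young divides each age mean by the young mean", {
  ab <- abundance_from_matrix(
    rbind(c(50, 100, 25), c(10, 10, 10)),
    compartment = rep("synaptic", 3),
    age = c("young", "mid", "old"), replicate = c(1, 1, 1)
  )
  r <- ratio_to_young(ab, compartment = "synaptic")
  expect_equal(r$ratio[r$protein_id == "P001"], c(1, 2, 0.5))
  expect_equal(r$ratio[r$protein_id == "P002"], c(1, 1, 1))

  ab2 <- abundance_from_means(function(p, cmp, a) 10 * p, 4, reps = 3,
                              noise_sd = 0.3, seed = 81)
  got <- ratio_to_young(ab2)
  gm <- group_means(ab2)
  for (i in sample(nrow(got), 8)) {
    row <- got[i, ]
    y <- gm$mean_abundance[gm$protein_id == row$protein_id &
                             gm$compartment == as.character(row$compartment) &
                             gm$age == "young"]
    v <- gm$mean_abundance[gm$protein_id == row$protein_id &
                             gm$compartment == as.character(row$compartment) &
                             gm$age == as.character(row$age)]
    expect_equal(row$ratio, v / y)
  }
})

make_ratios <- function(profiles) {
  # profiles: list(protein_id = list(syn = c(y,m,o), nonsyn = c(y,m,o)))
  purrr::imap_dfr(profiles, function(pr, id) {
    tibble::tibble(
      protein_id = id,
      compartment = rep(c("synaptic", "non_synaptic"), each = 3),
      age = rep(c("young", "mid", "old"), 2),
      ratio = c(pr$syn, pr$nonsyn)
    )
  })
}

test_that("archetypal filter keeps concordant-then-demarcated profiles", {
  ratios <- make_ratios(list(
    A = list(syn = c(1, 1, 3), nonsyn = c(1, 1, 1)),     # archetypal
    B = list(syn = c(1, 1, 1), nonsyn = c(1, 1, 1)),     # no demarcation
    C = list(syn = c(1, 2, 3), nonsyn = c(1, 1, 1)),     # mid discordant
    D = list(syn = c(1, 1.2, 0.4), nonsyn = c(1, 1, 1))  # down-demarcation
  ))
  got <- archetypal_filter(c("A", "B", "C", "D"), ratios)
  expect_setequal(got$protein_id, c("A", "D"))
  expect_equal(got$old_log2_ratio[got$protein_id == "A"], log2(3))
  expect_error(archetypal_filter("Z", ratios), "Missing profile")

  withr::with_seed(90, {
    tau <- log2(1.5)
    for (i in 1:200) {
      pr <- list(X = list(syn = c(1, exp(rnorm(2, 0, 0.6))),
                          nonsyn = c(1, exp(rnorm(2, 0, 0.6)))))
      r <- make_ratios(pr)
      keep <- nrow(archetypal_filter("X", r)) == 1
      mid <- abs(log2(pr$X$syn[2] / pr$X$nonsyn[2]))
      old <- abs(log2(pr$X$syn[3] / pr$X$nonsyn[3]))
      expect_equal(keep, mid <= tau && old > tau)
    }
  })
})

test_that("fold-change filter applies the |log2| >= log2(fold) rule", {
  tab <- tibble::tibble(
    protein_id = c("A", "B", "C"),
    mid_log2_ratio = 0,
    old_log2_ratio = log2(c(2.5, 1.9, 1 / 2.2))
  )
  got <- fold_change_filter(tab, divergence_fold = 2)
  expect_setequal(got$protein_id, c("A", "C"))

  withr::with_seed(91, {
    x <- tibble::tibble(protein_id = sprintf("P%03d", 1:100),
                        mid_log2_ratio = 0,
                        old_log2_ratio = rnorm(100, 0, 1.5))
    got <- fold_change_filter(x, 2)
    expect_setequal(got$protein_id,
                    x$protein_id[abs(x$old_log2_ratio) >= 1])
  })
})

test_that("zero-noise funnel returns exactly the planted divergent set", {
  cfg <- sim_config(n_proteins = 150, noise_sd = 0, divergent_fold = 2.5,
                    frac_single_peptide = 0, seed = 92)
  sim <- simulate_proteome(cfg)
  f <- run_funnel(sim$abundance)
  div <- sim$truth$protein_id[sim$truth$class == "divergent_old"]
  expect_setequal(f$final_ids, div)
  # flag implications hold
  tab <- tidy(f)
  expect_true(all(!tab$pass_2fold | tab$archetypal))
  expect_true(all(!tab$archetypal | tab$in_trend_set))
})

test_that("a dataset without divergence yields no final candidates", {
  cfg <- sim_config(
    n_proteins = 80, noise_sd = 0, frac_single_peptide = 0,
    class_fractions = c(flat = 0.5, steady_up = 0.2, steady_down = 0.1,
                        late_up = 0.1, late_down = 0.1, divergent_old = 0),
    seed = 93
  )
  f <- run_funnel(simulate_proteome(cfg)$abundance)
  expect_length(f$final_ids, 0)
})

test_that("the funnel is deterministic and monotone", {
  sim <- simulate_proteome(sim_config(n_proteins = 150, seed = 94))
  f1 <- run_funnel(sim$abundance)
  f2 <- run_funnel(sim$abundance)
  expect_identical(tidy(f1), tidy(f2))
  n <- glance(f1)
  expect_true(n$trend_set >= n$archetypal)
  expect_true(n$archetypal >= n$final_candidates)
  expect_true(n$common_proteins >= n$trend_set)
})

test_that("swapping compartment labels maps the candidate set to itself", {
  sim <- simulate_proteome(sim_config(n_proteins = 150, seed = 95))
  ab <- sim$abundance
  swapped <- dplyr::mutate(
    ab,
    compartment = factor(
      ifelse(compartment == "synaptic", "non_synaptic", "synaptic"),
      levels = levels(compartment)
    )
  )
  f1 <- run_funnel(ab)
  f2 <- run_funnel(swapped)
  expect_setequal(f1$final_ids, f2$final_ids)
})

test_that("protein-level trend mode matches per-protein classification", {
  sim <- simulate_proteome(sim_config(n_proteins = 100, noise_sd = 0,
                                      frac_single_peptide = 0, seed = 96))
  f <- run_funnel(sim$abundance, trend_level = "protein")
  div <- sim$truth$protein_id[sim$truth$class == "divergent_old"]
  expect_setequal(f$final_ids, div)
})
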