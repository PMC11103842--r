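test_that("spearman_rho handles monotone, antitone and tied inputs", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_rho(1:4, c(4, 3, 2, 1))$rho, -1)

  # tied example, hand-rankable: x-ranks (1, 2.5, 2.5, 4), y-ranks (1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  hand_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(res$rho, hand_rho)
  # cross-check against the standard implementation's coefficient
  expect_equal(res$rho,
               unname(suppressWarnings(
                 stats::cor.test(c(1, 2, 2, 4), c(1, 3, 2, 4),
                                 method = "spearman")$estimate)))

  expect_error(spearman_rho(rep(1, 5), 1:5), class = "bilatacc_degenerate_error")
  expect_error(spearman_rho(1:2, 1:2), class = "bilatacc_too_short_error")
})

test_that("exact permutation p at n=5 equals full 120-permutation enumeration", {
  set.seed(51)
  for (rep in 1:3) {
    x <- rnorm(5); y <- rnorm(5)
    res <- spearman_rho(x, y)
    expect_equal(res$method, "exact-permutation")
    rx <- rank(x); ry <- rank(y)
    rho_of <- function(a, b) {
      sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    }
    rho_obs <- rho_of(rx, ry)
    perms <- oracle_perms(5L)
    rho_all <- vapply(perms, function(p) rho_of(rx, ry[p]), numeric(1))
    p_brute <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
    expect_equal(res$p_value, p_brute)
  }
  # and against the reference exact distribution for untied data
  x <- c(3, 1, 4, 2, 5); y <- c(2, 1, 5, 3, 4)
  expect_equal(spearman_rho(x, y)$p_value,
               stats::cor.test(x, y, method = "spearman")$p.value)
})

test_that("rho is invariant under monotone transforms, flips with reflection", {
  set.seed(52)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, y^3 + 2 * y)$rho, r0)  # strictly increasing
  expect_equal(spearman_rho(y, x)$rho, r0)
  expect_equal(spearman_rho(x, -y)$rho, -r0)
})

test_that("t-approximation controls type-I error at n=18", {
  set.seed(53)
  rej <- mean(replicate(2000, spearman_rho(rnorm(18), rnorm(18))$p_value < 0.05))
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), ci_half)
})

test_that("descriptives follow the linear-interpolation quantile rule", {
  tbl <- data.frame(session = "T1", mas = 1:5, mal_aou = 1:5 / 2,
                    mal_qom = 1:5 / 3, mean_affected = c(1, 2, 3, 4, 5))
  d <- cohort_descriptives(tbl)
  acc <- d[d$variable == "mean_affected", ]
  expect_equal(acc$median, 3); expect_equal(acc$q1, 2); expect_equal(acc$q3, 4)

  one <- cohort_descriptives(data.frame(session = "T1", mas = 7L, mal_aou = 1,
                                        mal_qom = 1, mean_affected = 1.3))
  expect_true(all(one[one$variable == "mas", c("median", "q1", "q3")] == 7))

  set.seed(54)
  vals <- runif(18)
  tbl2 <- data.frame(session = "T2", mas = sample(0:15, 18, TRUE),
                     mal_aou = runif(18, 0, 5), mal_qom = runif(18, 0, 5),
                     mean_affected = vals)
  d2 <- cohort_descriptives(tbl2)
  expect_equal(d2[d2$variable == "mean_affected", "median"],
               unname(stats::quantile(vals, 0.5, type = 7)))
})

test_that("delta table is T2 minus T1 with incomplete patients excluded", {
  tbl <- data.frame(
    patient_id = c("A", "A", "B", "B", "C"),
    session = c("T1", "T2", "T1", "T2", "T1"),
    mean_affected = c(1.0, 1.5, 2.0, 1.8, 0.7),
    mas = c(3L, 8L, 5L, 5L, 1L),
    mal_aou = c(0.5, 1.0, 2.0, 2.0, 0.1),
    mal_qom = c(0.4, 0.9, 2.0, 1.5, 0.1))
  expect_warning(d <- delta_table(tbl), "without both sessions")
  expect_equal(nrow(d), 2L)
  expect_equal(d$d_mas[d$patient_id == "A"], 5)
  expect_equal(d$d_accel_affected[d$patient_id == "A"], 0.5)
  expect_equal(d$d_mal_qom[d$patient_id == "B"], -0.5)

  same <- tbl[tbl$patient_id == "A", ]
  same$session <- c("T1", "T2")
  same[2, c("mean_affected", "mas", "mal_aou", "mal_qom")] <-
    same[1, c("mean_affected", "mas", "mal_aou", "mal_qom")]
  d0 <- delta_table(same)
  expect_true(all(d0[, -1] == 0))
})

test_that("the correlation grid has 9 cells and recovers perfect monotonicity", {
  set.seed(55)
  n <- 12
  mas <- sample(0:15, n, replace = FALSE)
  tbl <- rbind(
    data.frame(patient_id = paste0("P", 1:n), session = "T1",
               mean_affected = 0.1 + 0.2 * mas, mas = mas,
               mal_aou = runif(n, 0, 5), mal_qom = runif(n, 0, 5)),
    data.frame(patient_id = paste0("P", 1:n), session = "T2",
               mean_affected = runif(n, 0.5, 3), mas = sample(0:15, n, TRUE),
               mal_aou = runif(n, 0, 5), mal_qom = runif(n, 0, 5)))
  g <- run_correlation_analysis(tbl)
  expect_equal(nrow(g), 9L)
  expect_setequal(unique(g$contrast), c("T1", "T2", "delta"))
  expect_equal(g$rho[g$score == "mas" & g$contrast == "T1"], 1)
  expect_true(all(g$n == n))
})
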