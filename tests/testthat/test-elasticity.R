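test_that("exact power laws return their exponents to machine precision", {
  psi <- rep(seq(-0.3, -1.8, by = -0.15), 3)
  day <- rep(c("d1", "d2", "d3"), each = 11)
  for (ex in c(-0.73, -0.26, 0, 0.4)) {
    e <- elasticity(2.5 * (-psi)^ex, psi, day)
    expect_equal(e$eta, ex, tolerance = 1e-8)
  }
  # invariance under multiplicative rescaling
  e1 <- elasticity(3 * (-psi)^(-0.5), psi, day)
  e2 <- elasticity(300 * (-psi)^(-0.5), psi, day)
  expect_equal(e1$eta, e2$eta, tolerance = 1e-10)
})

test_that("balanced equal-slope two-day data match the pooled OLS slope", {
  psi <- rep(seq(-0.3, -1.5, by = -0.2), 2)
  day <- rep(c("a", "b"), each = 7)
  set.seed(3)
  ly <- -0.4 * log(-psi) + rep(c(0.2, -0.2), each = 7)  # day intercepts
  vals <- exp(ly)
  e <- elasticity(vals, psi, day)
  ols <- unname(coef(lm(ly ~ log(-psi)))[2])
  expect_equal(e$eta, ols, tolerance = 1e-6)
})

test_that("domain violations are reported", {
  psi <- rep(seq(-0.3, -1.5, by = -0.2), 2)
  day <- rep(c("a", "b"), each = 7)
  v <- (-psi)^-0.3; v[4] <- -1
  expect_error(elasticity(v, psi, day), "step\\(s\\) 4")
  expect_error(elasticity((-psi)^-0.3, psi, rep("a", 14)), ">= 2 days")
})

test_that("paired SED is zero for identical variables and exact otherwise", {
  a <- c(d1 = -0.30, d2 = -0.25, d3 = -0.35)
  expect_equal(paired_sed(a, a), 0)
  b <- a + c(0.1, 0.1, 0.1)
  expect_equal(paired_sed(b, a), 0)           # constant difference
  cvar <- a + c(0.05, -0.05, 0.15)
  expect_equal(paired_sed(cvar, a), sd(c(0.05, -0.05, 0.15)) / sqrt(3))
  expect_error(paired_sed(a["d1"], a["d1"]), "paired days")
})

test_that("one-sided t-test on k matches the t distribution", {
  out <- one_sided_t_k(c(1, 2, 3))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$p, pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  expect_gt(one_sided_t_k(c(-1, -2, -1.5))$p, 0.5)
  expect_error(one_sided_t_k(c(0, 0, 0)), "zero variance")
  expect_error(one_sided_t_k(1), ">= 2")
})

test_that("elasticity table reproduces generating exponents and ranks", {
  psi1 <- seq(-0.3, -1.5, by = -0.12)
  exps <- c(A = -0.26, C_BS = 0.75, g_BS = -0.73, J_ATP = -0.21)
  mk <- function(sp, dayoff) {
    do.call(rbind, lapply(1:2, function(d) {
      out <- data.frame(psi_L = psi1, species = sp,
                        day_id = paste0(sp, d + dayoff))
      for (v in names(exps)) out[[v]] <- (1 + d / 10) * (-psi1)^exps[[v]]
      out
    }))
  }
  steps <- rbind(mk("maize", 0), mk("sorghum", 10))
  tab <- elasticity_table(steps, variables = names(exps))
  for (v in names(exps)) {
    row <- tab[tab$variable == v, ]
    expect_equal(row$eta_maize, exps[[v]], tolerance = 1e-8)
    expect_equal(row$eta_sorghum, exps[[v]], tolerance = 1e-8)
    expect_equal(row$eta_avg, exps[[v]], tolerance = 1e-8)
  }
  # rank 1 = most negative average elasticity
  expect_equal(tab$rank[order(tab$eta_avg)], 1:4)
  expect_equal(tab$variable[tab$rank == 1], "g_BS")
  expect_equal(tab$variable[tab$rank == 4], "C_BS")
  # SED of the paired comparison with assimilation: exact power laws share
  # identical per-day slopes, so all paired differences are constant
  expect_equal(tab$sed_vs_A[tab$variable == "g_BS"], 0, tolerance = 1e-8)
  expect_true(is.na(tab$sed_vs_A[tab$variable == "A"]))
})

test_that("robustness ANOVA runs on a fits table", {
  set.seed(1)
  tab <- expand.grid(method = c("all", "drop1", "drop2"),
                     species = c("maize", "sorghum"),
                     quantity = c("g_BS0", "k"),
                     rep = 1:4)
  tab$value <- rnorm(nrow(tab), 0.002, 0.0004)
  av <- robustness_anova(tab)
  expect_s3_class(av, "aov")
  expect_true("method" %in% attr(terms(av), "term.labels"))
})
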