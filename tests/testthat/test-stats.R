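test_that("arcsine transform hits its anchor points and is monotone", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(50), pi / 4)
  expect_equal(arcsine_transform(100), pi / 2)
  expect_equal(arcsine_transform(25), asin(0.5))
  p <- seq(0, 100, by = 0.5)
  expect_true(all(diff(arcsine_transform(p)) > 0))
  expect_error(arcsine_transform(-1), "\\[0, 100\\]")
  expect_error(arcsine_transform(101), "\\[0, 100\\]")
})

test_that("assumption checks agree with the reference implementations", {
  withr::with_seed(21, {
    values <- c(rnorm(20, 10), rnorm(20, 12), rnorm(20, 11))
    groups <- rep(c("a", "b", "c"), each = 20)
  })
  tab <- check_assumptions(values, groups)
  centred <- values - ave(values, groups)
  sw <- shapiro.test(centred)
  lv <- car::leveneTest(values ~ factor(groups), center = median)
  expect_equal(tab$p_value[tab$test == "shapiro_wilk"], sw$p.value)
  expect_equal(tab$p_value[tab$test == "levene"], lv[1, "Pr(>F)"])
  expect_equal(tab$n_groups, c(3, 3))
  expect_error(check_assumptions(c(1, 2, 1.5, 2.5), rep(c("a", "b"), 2)),
               ">= 3")
  expect_error(check_assumptions(c(1, 1, 1, 2, 3, 4),
                                 rep(c("a", "b"), each = 3)),
               "zero variance")
})

test_that("normal data pass and skewed data fail the normality screen", {
  withr::with_seed(88, {
    good <- rnorm(500)
    bad <- rexp(500)
  })
  g <- rep(c("a", "b"), each = 250)
  expect_gt(check_assumptions(good, g)$p_value[1], 0.01)
  expect_lt(check_assumptions(bad, g)$p_value[1], 1e-6)
})

test_that("Levene p-values are near-uniform under the null", {
  withr::with_seed(500, {
    ps <- replicate(200, {
      v <- rnorm(60)
      check_assumptions(v, rep(c("a", "b", "c"), each = 20))$p_value[2]
    })
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("one-way ANOVA with two groups reproduces the pooled t test", {
  withr::with_seed(14, {
    d <- data.frame(y = c(rnorm(15, 0), rnorm(15, 0.8)),
                    g = rep(c("a", "b"), each = 15))
  })
  res <- ht_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(res$anova$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$anova$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$anova$df, 1)
})

test_that("two-factor additive model matches aov term by term", {
  withr::with_seed(31, {
    d <- expand.grid(donor = factor(1:4), extender = c("A", "B", "C"))
    d <- d[rep(seq_len(nrow(d)), each = 3), ]
    d$y <- rnorm(nrow(d), as.numeric(d$donor))
  })
  res <- ht_anova(d, "y", c("donor", "extender"))
  ref <- anova(aov(y ~ donor + extender, data = d))
  expect_equal(res$anova$term, c("donor", "extender"))
  expect_equal(res$anova$statistic, ref$`F value`[1:2])
  expect_equal(res$anova$p_value, ref$`Pr(>F)`[1:2])
  # interaction adds a term
  res_i <- ht_anova(d, "y", c("donor", "extender"), interaction = TRUE)
  expect_equal(res_i$anova$term, c("donor", "extender", "donor:extender"))
})

test_that("arcsine transform is applied before fitting when requested", {
  withr::with_seed(77, {
    d <- data.frame(p = runif(40, 20, 90), g = rep(c("a", "b"), 20))
  })
  res <- ht_anova(d, "p", "g", transform = "arcsine")
  d2 <- d; d2$p <- asin(sqrt(d2$p / 100))
  ref <- ht_anova(d2, "p", "g")
  expect_equal(res$anova$statistic, ref$anova$statistic)
  expect_equal(res$transform, "arcsine")
})

test_that("Bonferroni p-values dominate the raw ones and cap at 1", {
  withr::with_seed(42, {
    d <- data.frame(y = rnorm(40), g = rep(letters[1:4], each = 10))
  })
  res <- ht_anova(d, "y", "g", pairwise = "g")
  pw <- res$pairwise
  expect_equal(nrow(pw), 6)  # choose(4, 2)
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(pw$p_raw * 6, 1))
  # a raw p of 0.2 with k = 6 comparisons must cap at exactly 1
  expect_equal(min(0.2 * 6, 1), 1)
  expect_true(any(pw$p_raw * 6 > 1))  # the cap is actually exercised here
})

test_that("pairwise table matches pooled-SD t tests computed directly", {
  withr::with_seed(65, {
    d <- data.frame(y = c(rnorm(12, 0), rnorm(12, 1), rnorm(12, 2)),
                    g = rep(c("a", "b", "c"), each = 12))
  })
  pw <- ht_anova(d, "y", "g", pairwise = "g")$pairwise
  raw <- pairwise.t.test(d$y, d$g, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  expect_equal(pw$p_raw[pw$group1 == "b" & pw$group2 == "a"], raw["b", "a"])
  expect_equal(pw$p_raw[pw$group1 == "c" & pw$group2 == "b"], raw["c", "b"])
})

test_that("the ANOVA holds its nominal type-I error rate", {
  withr::with_seed(1234, {
    hits <- replicate(400, {
      d <- data.frame(y = rnorm(30), g = rep(c("a", "b", "c"), each = 10))
      ht_anova(d, "y", "g")$anova$p_value < 0.05
    })
  })
  # 400 null replicates: the rejection rate must sit near 5%
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("the ANOVA detects a 30% shrinkage difference with high power", {
  withr::with_seed(4321, {
    hits <- replicate(200, {
      d <- data.frame(fi = c(rnorm(40, 100, 10), rnorm(40, 70, 10)),
                      g = rep(c("fresh", "frozen"), each = 40))
      ht_anova(d, "fi", "g")$anova$p_value < 0.05
    })
  })
  expect_gt(mean(hits), 0.95)
})

test_that("model guards reject unusable inputs", {
  d <- data.frame(y = rnorm(10), g = rep("a", 10))
  expect_error(ht_anova(d, "z", "g"), "response column")
  expect_error(ht_anova(d, "y", "h"), "factor column")
  expect_error(ht_anova(d, "y", "g"), ">= 2 levels")
  expect_error(ht_anova(d, "y", c("g", "g", "g")), "one or two")
})

test_that("the report tables are deterministic and order the medians with
           the generative effect sizes", {
  eff <- list(Mild = list(mean = c(nucleus = 0.98, midpiece = 0.85,
                                   tail = 0.9),
                          sd = c(nucleus = 0.02, midpiece = 0.04,
                                 tail = 0.04)),
              Harsh = list(mean = c(nucleus = 0.95, midpiece = 0.55,
                                    tail = 0.75),
                           sd = c(nucleus = 0.02, midpiece = 0.04,
                                  tail = 0.04)))
  d <- study_design(n_donors = 6, extenders = c("INRA96", "Mild", "Harsh"),
                    cells_per_sample = 30, extender_effects = eff,
                    good_coolers = integer(0), seed = 77)
  morph <- dplyr::rename(simulate_study(d)$truth,
                         volume = "true_volume_um3")
  rec <- aggregate_freezability(morph)
  r1 <- freezability_report(rec)
  r2 <- freezability_report(rec)
  expect_identical(r1, r2)
  med <- r1$fi_by_extender
  mid <- med[med$region == "midpiece", ]
  expect_lt(mid$median[mid$extender == "Harsh"],
            mid$median[mid$extender == "Mild"])
  expect_equal(nrow(r1$fi_by_donor), 4 * 6)  # four regions x six donors
  # CSV side effects land in the requested directory
  out <- withr::local_tempdir()
  freezability_report(rec, out_dir = out)
  expect_true(file.exists(file.path(out, "fi_by_extender.csv")))
})

test_that("a single-record report degenerates gracefully", {
  rec <- tibble::tibble(donor = 1, extender = "A", region = "whole",
                        v_fresh = 10, v_frozen = 9, fi_ht = 90,
                        n_cells_fresh = 40, n_cells_frozen = 40)
  rep1 <- freezability_report(rec)
  expect_equal(rep1$fi_by_donor$median, 90)
  expect_equal(rep1$fi_by_donor$q1, 90)
  expect_error(freezability_report(rec[0, ]), "no freezability")
})
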